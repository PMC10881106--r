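#' Ordered ancestral primate lineages leading to human
#'
#' The eight nested ancestral lineages on the path from *Homo sapiens* back
#' to the haplorrhine ancestor, ordered from youngest (terminal human branch)
#' to oldest.  Each lineage carries its own per-gene dN/dS in a
#' [gene_evo_table()].
#'
#' @return character vector of length 8
#' @export
#' @examples
#' primate_lineages()
primate_lineages <- function() {
  c("H. sapiens", "Hominini", "Homininae", "Hominidae",
    "Hominoidea", "Catarrhini", "Simiiformes", "Haplorrhini")
}

#' Default dated primate species tree
#'
#' A pectinate, ultrametric eight-taxon tree whose internal nodes on the
#' human path correspond one-to-one to the non-terminal lineages of
#' [primate_lineages()].  Branch lengths are in million years (Mya) and node
#' ages are round TimeTree-style divergence estimates: Hominini 6.7,
#' Homininae 9.1, Hominidae 15.8, Hominoidea 20.2, Catarrhini 29.4,
#' Simiiformes 43.2, Haplorrhini 64.0.
#'
#' @return an [ape::read.tree()] `phylo` object with node labels naming the
#'   ancestral lineages; the focal species is `"Homo_sapiens"`.
#' @export
#' @examples
#' tr <- default_species_tree()
#' node_ages_from_tree(tr)
default_species_tree <- function() {
  nwk <- paste0(
    "(((((((Homo_sapiens:6.7,Pan_troglodytes:6.7)Hominini:2.4,",
    "Gorilla_gorilla:9.1)Homininae:6.7,Pongo_abelii:15.8)Hominidae:4.4,",
    "Nomascus_leucogenys:20.2)Hominoidea:9.2,Macaca_mulatta:29.4)",
    "Catarrhini:13.8,Callithrix_jacchus:43.2)Simiiformes:20.8,",
    "Tarsius_syrichta:64.0)Haplorrhini;")
  ape::read.tree(text = nwk)
}

#' Default focal species of the package's species tree
#' @return `"Homo_sapiens"`
#' @export
default_focal_species <- function() "Homo_sapiens"

#' Brain-region presets
#'
#' Region label / region class tables emulating the two study designs the
#' indices are typically applied to: a 45-area macaque-style atlas
#' (25 cortical + 20 non-cortical areas, standard area abbreviations) and a
#' 12-area GTEx-style human brain panel.  `region_class` separates cerebral
#' cortex areas from everything else (basal ganglia, diencephalon, brainstem,
#' cerebellum, hypophysis, pineal gland, ...).
#'
#' @param preset `"macaque45"` or `"gtex12"`
#' @return data.frame with columns `region`, `region_class`
#' @export
#' @examples
#' table(region_preset("macaque45")$region_class)
region_preset <- function(preset = c("macaque45", "gtex12")) {
  preset <- match.arg(preset)
  if (preset == "macaque45") {
    non_cortical <- c("CN", "PTM", "GP", "AMY", "HIP", "TH", "HTH", "SC",
                      "IC", "pons", "CV", "HYP", "ACB", "CC", "VTA", "OB",
                      "MED", "PG", "SN", "CBC")
    cortical <- c("CGS", "SU", "IPS", "LF", "PEC", "AMG", "AG", "LSTG",
                  "TPG", "DLPFC", "VLPFC", "ASPD", "V1C", "V2C", "V4C",
                  "SFG", "VMPFC", "AIC", "PIC", "OFC", "PSPD", "SAR",
                  "PS", "ASD", "ARSP")
  } else {
    non_cortical <- c("AMY", "CN", "CBH", "HIP", "HTH", "ACB", "PTM",
                      "SN", "SPC")
    cortical <- c("ACC", "CTX", "FC")
  }
  data.frame(
    region = c(non_cortical, cortical),
    region_class = rep(c("non_cortical", "cortical"),
                       c(length(non_cortical), length(cortical))),
    stringsAsFactors = FALSE)
}

#' Developmental window preset
#'
#' Eight ordered developmental windows spanning 12 post-conception weeks
#' (pcw) to 64 post-natal years (py).  The late windows carry the standard
#' spans (w5: 35 pcw to 0.3 py, late fetal/neonatal; w6: 0.5 to 2.5 py, late
#' infancy to early childhood; w7: 2.8 to 10.7 py, childhood; w8: 13 py
#' onward, adolescence and adulthood); the prenatal spans w1-w4 tile the
#' remaining 12-34 pcw range.  Spans are descriptive labels only; analyses
#' use the window order.
#'
#' @return data.frame with columns `window`, `span`
#' @export
developmental_windows <- function() {
  data.frame(
    window = paste0("w", 1:8),
    span = c("12-15 pcw", "16-21 pcw", "22-27 pcw", "28-34 pcw",
             "35 pcw-0.3 py", "0.5-2.5 py", "2.8-10.7 py", "13-64 py"),
    stringsAsFactors = FALSE)
}
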