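# Core containers: expression matrix, gene evolutionary table, sample
# metadata, index table.  Light S3 wrappers over base structures so they
# compose with the rest of the R ecosystem.

#' Construct a validated expression matrix
#'
#' A genes x samples numeric matrix plus a units flag.  Values must be
#' non-negative and gene/sample identifiers unique.  For `units = "TPM"`
#' every non-zero column must sum to 1e6 within relative 1e-6; all-zero
#' columns are tolerated and recorded in the `"zero_columns"` attribute.
#'
#' @param values numeric matrix with unique rownames (gene ids) and unique
#'   colnames (sample or group ids)
#' @param units one of `"counts"`, `"TPM"`, `"normalized"`
#' @return an object of class `expression_matrix` (a matrix with a `units`
#'   attribute)
#' @export
#' @examples
#' m <- matrix(1:6, 3, 2, dimnames = list(paste0("g", 1:3), c("s1", "s2")))
#' expression_matrix(m, "counts")
expression_matrix <- function(values, units = c("counts", "TPM", "normalized")) {
  units <- match.arg(units)
  if (!is.matrix(values) || !is.numeric(values)) {
    invalid_parameter("expression values must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    invalid_parameter("expression matrix needs gene rownames and sample colnames")
  }
  dup_g <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup_g)) {
    stop_evoindex("evoindex_validation",
                  "duplicate gene ids: %s", paste(dup_g, collapse = ", "))
  }
  dup_s <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dup_s)) {
    stop_evoindex("evoindex_validation",
                  "duplicate sample ids: %s", paste(dup_s, collapse = ", "))
  }
  if (anyNA(values)) {
    stop_evoindex("evoindex_validation", "expression matrix contains NA values")
  }
  if (any(values < 0)) {
    stop_evoindex("evoindex_validation",
                  "expression matrix contains negative values (first offender: %s)",
                  paste(which(values < 0, arr.ind = TRUE)[1, ], collapse = ","))
  }
  zero_cols <- colnames(values)[colSums(values) == 0]
  if (units == "TPM" && ncol(values)) {
    cs <- colSums(values)
    ok <- cs == 0 | abs(cs - 1e6) <= 1e-6 * 1e6
    if (!all(ok)) {
      stop_evoindex("evoindex_validation",
                    "TPM columns must sum to 1e6 (off: %s)",
                    paste(colnames(values)[!ok], collapse = ", "))
    }
  }
  structure(values, units = units, zero_columns = zero_cols,
            class = c("expression_matrix", class(values)))
}

#' Units of an expression matrix
#' @param x an `expression_matrix`
#' @return the units string
#' @export
expr_units <- function(x) attr(x, "units") %||% "normalized"

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d genes x %d samples, units = %s\n",
              nrow(x), ncol(x), expr_units(x)))
  invisible(x)
}

# subsetting keeps class and units
#' @export
`[.expression_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out)) {
    out <- structure(out, units = expr_units(x),
                     zero_columns = colnames(out)[colSums(out) == 0],
                     class = class(x))
  }
  out
}

#' Construct a validated per-gene evolutionary table
#'
#' One row per gene: `gene_id`, one dN/dS column per ancestral lineage
#' (missing values allowed, kept as NA), and `age`, the gene's evolutionary
#' age in time units before present (larger = older).
#'
#' @param df data.frame with columns `gene_id`, `age` and one numeric column
#'   per entry of `lineages`
#' @param lineages ordered lineage labels; defaults to [primate_lineages()]
#' @return data.frame of class `gene_evo_table` with a `"lineages"` attribute
#' @export
gene_evo_table <- function(df, lineages = primate_lineages()) {
  if (anyDuplicated(lineages)) invalid_parameter("lineage labels must be unique")
  need <- c("gene_id", lineages, "age")
  missing_cols <- setdiff(c("gene_id", "age"), names(df))
  if (length(missing_cols)) {
    stop_evoindex("evoindex_validation",
                  "gene evo table lacks column(s): %s",
                  paste(missing_cols, collapse = ", "))
  }
  extra <- setdiff(names(df), need)
  if (length(extra)) {
    stop_evoindex("evoindex_validation",
                  "unknown lineage column(s) %s; expected lineages: %s",
                  paste(extra, collapse = ", "),
                  paste(lineages, collapse = ", "))
  }
  absent <- setdiff(lineages, names(df))
  if (length(absent)) {
    stop_evoindex("evoindex_validation",
                  "gene evo table lacks lineage column(s): %s",
                  paste(absent, collapse = ", "))
  }
  if (anyDuplicated(df$gene_id)) {
    stop_evoindex("evoindex_validation", "duplicate gene_id in gene evo table")
  }
  for (ln in lineages) {
    v <- df[[ln]]
    if (!is.numeric(v)) df[[ln]] <- v <- as.numeric(v)
    if (any(v < 0, na.rm = TRUE)) {
      stop_evoindex("evoindex_validation",
                    "negative dN/dS in lineage %s", ln)
    }
  }
  if (any(df$age < 0 | !is.finite(df$age), na.rm = TRUE)) {
    stop_evoindex("evoindex_validation", "gene ages must be finite and >= 0")
  }
  df <- df[, need]
  structure(df, lineages = lineages,
            class = c("gene_evo_table", "data.frame"))
}

#' Lineages of a gene evolutionary table
#' @param x a `gene_evo_table`
#' @return ordered character vector of lineage labels
#' @export
evo_lineages <- function(x) attr(x, "lineages") %||% primate_lineages()

#' Validate a sample metadata table
#'
#' Required columns: `sample_id`, `region`, `region_class` (one of
#' `cortical`, `non_cortical`, `other`), `uniquely_mapped_reads`,
#' `total_reads`.  Optional: `window`, `cell_type`.  Enforces
#' `uniquely_mapped_reads <= total_reads` and uniqueness of sample ids.
#'
#' @param df data.frame of per-sample metadata
#' @return the validated data.frame (class `sample_metadata`)
#' @export
sample_metadata <- function(df) {
  need <- c("sample_id", "region", "region_class",
            "uniquely_mapped_reads", "total_reads")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop_evoindex("evoindex_validation",
                  "sample metadata lacks column(s): %s",
                  paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(df$sample_id)) {
    stop_evoindex("evoindex_validation", "duplicate sample_id in metadata")
  }
  bad_class <- setdiff(unique(df$region_class),
                       c("cortical", "non_cortical", "other"))
  if (length(bad_class)) {
    stop_evoindex("evoindex_validation",
                  "unknown region_class value(s): %s",
                  paste(bad_class, collapse = ", "))
  }
  ok <- !is.na(df$uniquely_mapped_reads) & !is.na(df$total_reads)
  if (any(ok & (df$uniquely_mapped_reads > df$total_reads |
                df$uniquely_mapped_reads < 0 | df$total_reads <= 0))) {
    stop_evoindex("evoindex_validation",
                  "mapping stats must satisfy 0 <= uniquely_mapped_reads <= total_reads, total_reads > 0")
  }
  if (!"window" %in% names(df)) df$window <- NA_character_
  if (!"cell_type" %in% names(df)) df$cell_type <- NA_character_
  class(df) <- unique(c("sample_metadata", class(df)))
  df
}

#' Assemble an index table
#'
#' Long-format container for computed indices: one row per
#' (group, lineage, index kind) with the index value and the number of genes
#' actually used after pairwise removal of missing values.
#'
#' @param group character group labels
#' @param lineage lineage labels (NA for TAI rows)
#' @param index_kind `"ERI"` or `"TAI"`
#' @param value numeric index values (must be finite)
#' @param n_genes_used integer counts of genes entering each value (>= 1)
#' @return data.frame of class `index_table`
#' @export
index_table <- function(group, lineage, index_kind, value, n_genes_used) {
  df <- data.frame(group = as.character(group),
                   lineage = as.character(lineage),
                   index_kind = as.character(index_kind),
                   value = as.numeric(value),
                   n_genes_used = as.integer(n_genes_used),
                   stringsAsFactors = FALSE)
  if (any(!is.finite(df$value))) {
    stop_evoindex("evoindex_validation", "index values must be finite")
  }
  if (any(df$n_genes_used < 1L)) {
    stop_evoindex("evoindex_validation", "n_genes_used must be >= 1")
  }
  key <- paste(df$group, df$lineage, df$index_kind, sep = "\r")
  if (anyDuplicated(key)) {
    stop_evoindex("evoindex_validation",
                  "(group, lineage, index_kind) rows must be unique")
  }
  class(df) <- c("index_table", "data.frame")
  df
}
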