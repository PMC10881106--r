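# Readers and writers for the tabular interchange formats: expression TSV
# (gene_id first column), GCT v1.2 (read-only), gene evolutionary table TSV,
# sample metadata TSV, presence/absence TSV.  All writers emit UTF-8 with
# LF line endings.

#' Read an expression matrix from TSV or GCT
#'
#' TSV: header row, `gene_id` first column, one column per sample.
#' GCT v1.2: first line `#1.2`, second line `<n_genes>\t<n_samples>`, then a
#' header `Name`, `Description`, samples...; the Description column is
#' dropped.  Duplicate gene ids and negative values are rejected.
#'
#' @param path input file
#' @param format `"tsv"` or `"gct"`
#' @param units units of the stored values (`"counts"`, `"TPM"`,
#'   `"normalized"`); GTEx-style GCT files are typically TPM
#' @return an [expression_matrix()]
#' @export
read_expression_matrix <- function(path, format = c("tsv", "gct"),
                                   units = "normalized") {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop_evoindex("evoindex_missing_input", "input file not found: %s", path)
  }
  if (format == "tsv") {
    df <- read_tsv_raw(path)
    if (names(df)[1] != "gene_id") {
      stop_evoindex("evoindex_parse",
                    "%s line 1: expected first column 'gene_id', found '%s'",
                    path, names(df)[1])
    }
  } else {
    lines <- readLines(path, n = 2L)
    if (length(lines) < 2L || !identical(lines[1], "#1.2")) {
      stop_evoindex("evoindex_parse",
                    "%s line 1: not a GCT v1.2 file (expected '#1.2')", path)
    }
    dims <- suppressWarnings(as.integer(strsplit(lines[2], "\t")[[1]]))
    if (length(dims) < 2L || anyNA(dims)) {
      stop_evoindex("evoindex_parse",
                    "%s line 2: expected '<n_genes>\\t<n_samples>'", path)
    }
    df <- read.delim(path, skip = 2L, check.names = FALSE,
                     stringsAsFactors = FALSE)
    if (ncol(df) < 3L) {
      stop_evoindex("evoindex_parse", "%s line 3: GCT header too short", path)
    }
    names(df)[1] <- "gene_id"
    df[[2]] <- NULL  # Description
    if (nrow(df) != dims[1] || ncol(df) - 1L != dims[2]) {
      stop_evoindex("evoindex_parse",
                    "%s: declared dims %dx%d do not match data (%dx%d)",
                    path, dims[1], dims[2], nrow(df), ncol(df) - 1L)
    }
  }
  dup <- unique(df$gene_id[duplicated(df$gene_id)])
  if (length(dup)) {
    stop_evoindex("evoindex_validation",
                  "duplicate gene ids in %s: %s", path,
                  paste(head(dup, 10), collapse = ", "))
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    stop_evoindex("evoindex_parse", "%s: non-numeric expression values", path)
  }
  rownames(m) <- df$gene_id
  expression_matrix(m, units = units)
}

#' Write an expression matrix as TSV
#' @param x an [expression_matrix()] (or plain matrix with dimnames)
#' @param path output file
#' @return `path`, invisibly
#' @export
write_expression_matrix <- function(x, path) {
  df <- data.frame(gene_id = rownames(x), as.data.frame(unclass(x)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Read a per-gene evolutionary table from TSV
#'
#' Expected columns: `gene_id`, one per lineage, `age`.  Empty dN/dS cells
#' are preserved as missing, never coerced to zero; unknown columns raise an
#' error listing the expected lineage labels.
#'
#' @param path input TSV
#' @param lineages expected ordered lineage labels
#' @return a [gene_evo_table()]
#' @export
read_gene_evo_table <- function(path, lineages = primate_lineages()) {
  gene_evo_table(read_tsv_raw(path), lineages = lineages)
}

#' Write a gene evolutionary table as TSV
#' @param x a [gene_evo_table()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_gene_evo_table <- function(x, path) {
  write_tsv(as.data.frame(x), path)
}

#' Read sample metadata from TSV
#' @param path input TSV
#' @return a validated [sample_metadata()] table
#' @export
read_sample_metadata <- function(path) {
  sample_metadata(read_tsv_raw(path))
}

#' Write sample metadata as TSV
#' @param x a metadata data.frame
#' @param path output file
#' @return `path`, invisibly
#' @export
write_sample_metadata <- function(x, path) {
  write_tsv(as.data.frame(x), path)
}

#' Read an ortholog presence/absence matrix from TSV
#'
#' Genes x species, 0/1 values, `gene_id` first column.
#'
#' @param path input TSV
#' @return logical matrix with gene rownames and species colnames
#' @export
read_presence_absence <- function(path) {
  df <- read_tsv_raw(path)
  if (names(df)[1] != "gene_id") {
    stop_evoindex("evoindex_parse",
                  "%s line 1: expected first column 'gene_id'", path)
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!all(m %in% c(0, 1))) {
    stop_evoindex("evoindex_validation",
                  "%s: presence/absence values must be 0 or 1", path)
  }
  mode(m) <- "logical"
  rownames(m) <- df$gene_id
  m
}

#' Write a presence/absence matrix as 0/1 TSV
#' @param pa logical or 0/1 matrix, genes x species
#' @param path output file
#' @return `path`, invisibly
#' @export
write_presence_absence <- function(pa, path) {
  m <- pa * 1L
  df <- data.frame(gene_id = rownames(pa), as.data.frame(m),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Write an index table as long-format TSV
#' @param x an [index_table()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_index_table <- function(x, path) {
  write_tsv(as.data.frame(x), path)
}

#' Read an index table written by [write_index_table()]
#' @param path input TSV
#' @return an [index_table()]
#' @export
read_index_table <- function(path) {
  df <- read_tsv_raw(path)
  index_table(df$group, df$lineage, df$index_kind, df$value, df$n_genes_used)
}
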