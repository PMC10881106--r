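# internal helpers: error conditions and deterministic TSV I/O

stop_evoindex <- function(class, fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c(class, "evoindex_error")))
}

invalid_parameter <- function(fmt, ...) {
  stop_evoindex("evoindex_invalid_parameter", fmt, ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a data frame as a UTF-8, LF-terminated TSV
#'
#' Header row, tab separators, no quoting, no row names.  Numeric columns are
#' written at full double precision (15 significant digits) so write/read
#' round trips are stable to ~1e-15 relative error.
#'
#' @param df data frame to write
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_tsv <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  df2 <- df
  for (j in seq_along(df2)) {
    if (is.numeric(df2[[j]])) {
      v <- df2[[j]]
      s <- sprintf("%.15g", v)
      s[is.na(v)] <- NA_character_
      df2[[j]] <- s
    }
  }
  write.table(df2, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, na = "", eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}

read_tsv_raw <- function(path) {
  if (!file.exists(path)) {
    stop_evoindex("evoindex_missing_input", "input file not found: %s", path)
  }
  read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
             na.strings = c("", "NA"), stringsAsFactors = FALSE)
}

# group id separator used for composite groupings (region x window etc.)
GROUP_SEP <- "|"
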