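# Shared small helpers. All tabular output is tab-separated with a header row
# and floats fixed to 6 decimals so that repeated runs diff byte-identically.

fmt6 <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.6f", x))
}

#' Write a data frame as a tab-separated table with 6-decimal floats
#'
#' @param df data frame
#' @param path output file
#' @return invisibly, the path
#' @keywords internal
write_tsv6 <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- fmt6(out[[j]])
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE, ...)
}

stop_format <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
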