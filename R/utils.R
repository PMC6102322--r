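# Internal helpers shared across modules.

# Order chromosome labels numerically where possible ("2" < "10"), with
# non-numeric labels (e.g. "X", "MT") after all numeric ones, alphabetically.
chrom_rank <- function(chr) {
  chr <- as.character(chr)
  u <- unique(chr)
  num <- suppressWarnings(as.numeric(u))
  match(chr, u[order(ifelse(is.na(num), Inf, num), u)])
}

# Sort a marker map (and return the permutation) by (chromosome, position).
marker_order <- function(map) {
  order(chrom_rank(map$chromosome), map$position_bp)
}

#' Write a data frame as a tab-separated file
#'
#' Plain TSV writer used for all tabular pipeline outputs: header line,
#' no quoting, no row names, `NA` for missing values.
#'
#' @param x A data frame.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
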