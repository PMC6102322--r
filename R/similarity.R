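# Pairwise identity-by-state genomic similarity.
#
# For individuals i and j at marker k, all four ordered allele pairs are
# compared; the indicator sum over a B-allele dosage pair (g_i, g_j) is
#   g_i * g_j + (2 - g_i) * (2 - g_j),
# which makes the whole matrix a pair of cross-products. Self-pairs are
# included, so the average similarity within a group equals its expected
# homozygosity.

#' Pairwise IBS genomic-similarity matrix
#'
#' Computes, for every ordered pair of individuals (including self-pairs),
#' the fraction of identical-by-state ordered allele pairs, averaged over
#' markers where both individuals have a call. Values lie in `[0, 1]`; the
#' self-similarity of an individual equals `0.5 + 0.5 *` (its homozygous
#' fraction).
#'
#' @param dataset A [genotype_dataset()].
#' @param denominator `"pairwise"` (default) divides each pair's indicator
#'   sum by the number of markers where both members are called, keeping
#'   the value a proper proportion under missingness; `"all"` divides by
#'   the total marker count (the literal textbook formula).
#' @return An object of class `similarity_matrix`: list with `sim`
#'   (dense symmetric matrix with sample-id dimnames), `n_shared`
#'   (pairwise non-missing marker counts) and `markers_used`. Pairs with
#'   zero shared markers are `NA` and flagged with a warning.
#' @export
sim_matrix <- function(dataset, denominator = c("pairwise", "all")) {
  denominator <- match.arg(denominator)
  g <- dataset$calls
  if (ncol(g) < 1L) stopf("similarity needs at least one marker")
  v <- !is.na(g)
  gb <- g; gb[!v] <- 0L
  ga <- 2L - g; ga[!v] <- 0L
  storage.mode(gb) <- "double"; storage.mode(ga) <- "double"
  match_sum <- tcrossprod(gb) + tcrossprod(ga)   # sum over k of IBS pairs
  n_shared <- tcrossprod(v * 1)
  denom <- if (denominator == "pairwise") 4 * n_shared else 4 * ncol(g)
  sim <- match_sum / denom
  if (denominator == "pairwise" && any(n_shared == 0)) {
    warnf("%d sample pair(s) share no non-missing marker; similarity NA",
          sum(n_shared[upper.tri(n_shared, diag = TRUE)] == 0))
    sim[n_shared == 0] <- NA_real_
  }
  dimnames(sim) <- dimnames(n_shared) <-
    list(dataset$samples$sample_id, dataset$samples$sample_id)
  structure(list(sim = sim, n_shared = n_shared, markers_used = ncol(g),
                 denominator = denominator),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("similarity_matrix: %d samples, %d markers (%s denominator)\n",
              nrow(x$sim), x$markers_used, x$denominator))
  cat(sprintf("  mean self-similarity: %.4f\n", mean(diag(x$sim), na.rm = TRUE)))
  invisible(x)
}

#' Within- and between-breed mean similarity
#'
#' Averages the similarity matrix within and between breeds. Within-breed
#' means are taken over *all ordered pairs including self-pairs*, which is
#' the convention under which the within-breed mean equals the breed's
#' expected homozygosity (mean over markers of the sum of squared allele
#' frequencies) for complete data.
#'
#' @param sim A `similarity_matrix` from [sim_matrix()].
#' @param breeds Character vector of breed labels, one per sample (in the
#'   sample order of `sim`), or a [genotype_dataset()] to take them from.
#' @return Symmetric breed-by-breed matrix of mean similarities
#'   (diagonal = within-breed).
#' @export
breed_summary <- function(sim, breeds) {
  if (inherits(breeds, "genotype_dataset")) breeds <- breeds$samples$breed
  s <- sim$sim
  if (length(breeds) != nrow(s))
    stopf("%d breed labels for %d samples", length(breeds), nrow(s))
  bl <- unique(breeds)
  out <- matrix(NA_real_, length(bl), length(bl), dimnames = list(bl, bl))
  for (i in seq_along(bl)) {
    for (j in seq_len(i)) {
      block <- s[breeds == bl[i], breeds == bl[j], drop = FALSE]
      out[i, j] <- out[j, i] <- mean(block, na.rm = TRUE)
    }
  }
  out
}
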