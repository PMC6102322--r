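#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact test of HWE genotype proportions conditional on the
#' observed allele counts (Wigginton, Cutler & Abecasis 2005; the PLINK
#' default, without the mid-p correction). The p-value is the summed
#' probability of all heterozygote counts whose conditional probability
#' does not exceed that of the observed count.
#'
#' Probabilities are built with the standard ratio recurrence from the
#' modal heterozygote count, which is numerically stable for array-scale
#' sample sizes.
#'
#' @param n_aa,n_ab,n_bb Genotype counts (hom A, het, hom B); vectors are
#'   recycled to a common length.
#' @return Vector of p-values in (0, 1].
#' @export
hwe_exact_test <- function(n_aa, n_ab, n_bb) {
  len <- max(length(n_aa), length(n_ab), length(n_bb))
  n_aa <- rep_len(as.integer(n_aa), len)
  n_ab <- rep_len(as.integer(n_ab), len)
  n_bb <- rep_len(as.integer(n_bb), len)
  vapply(seq_len(len), function(i) {
    hwe_exact_one(n_aa[i], n_ab[i], n_bb[i])
  }, numeric(1))
}

hwe_exact_one <- function(n_aa, n_ab, n_bb) {
  if (any(c(n_aa, n_ab, n_bb) < 0L)) stopf("negative genotype count")
  n <- n_aa + n_ab + n_bb
  if (n == 0L) return(1)
  rare <- 2L * min(n_aa, n_bb) + n_ab   # minor allele count
  # feasible het counts share the parity of the minor allele count
  hets <- seq.int(rare %% 2L, rare, by = 2L)
  if (length(hets) == 1L) return(1)

  # P(h) ratio: P(h+2)/P(h) = hom_r(h) * hom_c(h) * 4 / ((h+2)(h+1)),
  # where hom_r(h) = (rare - h)/2, hom_c(h) = (2n - rare - h)/2.
  # Start at the modal count and sweep outward in both directions.
  probs <- numeric(length(hets))
  mid <- round(rare * (2 * n - rare) / (2 * n))
  if (mid %% 2L != rare %% 2L) mid <- mid + 1L
  mid_i <- match(mid, hets)
  probs[mid_i] <- 1
  if (mid_i < length(hets)) {
    for (i in mid_i:(length(hets) - 1L)) {
      h <- hets[i]
      probs[i + 1L] <- probs[i] *
        ((rare - h) / 2) * ((2 * n - rare - h) / 2) * 4 / ((h + 2) * (h + 1))
    }
  }
  if (mid_i > 1L) {
    for (i in mid_i:2L) {
      h <- hets[i]
      probs[i - 1L] <- probs[i] *
        h * (h - 1) / (4 * ((rare - h) / 2 + 1) * ((2 * n - rare - h) / 2 + 1))
    }
  }
  probs <- probs / sum(probs)
  p_obs <- probs[match(n_ab, hets)]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-12)]))
}
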