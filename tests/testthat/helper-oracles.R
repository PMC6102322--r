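# Independent brute-force oracles. Each recomputes a quantity from first
# principles by a different route than the package implementation
# (explicit enumeration, quadratic scans, direct factorial formulas), so
# that implementation and oracle share no code path.

# --- IBS similarity: explicit 4-allele-pair enumeration ----------------------
# g: B-allele dosages of the two individuals (0/1/2/NA). Builds the actual
# allele pairs ("A","B") and compares all four ordered combinations.
oracle_sim_pair <- function(g_i, g_j) {
  alleles <- function(g) switch(as.character(g),
                                "0" = c("A", "A"), "1" = c("A", "B"),
                                "2" = c("B", "B"), c(NA, NA))
  total <- 0L; n_used <- 0L
  for (k in seq_along(g_i)) {
    if (is.na(g_i[k]) || is.na(g_j[k])) next
    ai <- alleles(g_i[k]); aj <- alleles(g_j[k])
    for (x in 1:2) for (y in 1:2)
      total <- total + as.integer(ai[x] == aj[y])
    n_used <- n_used + 1L
  }
  if (n_used == 0L) return(NA_real_)
  total / (4 * n_used)
}

# --- two-population Weir-Cockerham theta from genotype counts ----------------
# counts: c(n_AA, n_AB, n_BB) per group. Scalar arithmetic straight from
# the published variance-component definitions.
oracle_wc_theta <- function(counts1, counts2, return_components = FALSE) {
  n1 <- sum(counts1); n2 <- sum(counts2)
  p1 <- (2 * counts1[3] + counts1[2]) / (2 * n1)
  p2 <- (2 * counts2[3] + counts2[2]) / (2 * n2)
  h1 <- counts1[2] / n1
  h2 <- counts2[2] / n2
  r <- 2
  n_bar <- (n1 + n2) / r
  n_c <- (r * n_bar - (n1^2 + n2^2) / (r * n_bar)) / (r - 1)
  p_bar <- (n1 * p1 + n2 * p2) / (r * n_bar)
  s2 <- (n1 * (p1 - p_bar)^2 + n2 * (p2 - p_bar)^2) / ((r - 1) * n_bar)
  h_bar <- (n1 * h1 + n2 * h2) / (r * n_bar)
  a <- (n_bar / n_c) *
    (s2 - (1 / (n_bar - 1)) *
       (p_bar * (1 - p_bar) - ((r - 1) / r) * s2 - h_bar / 4))
  b <- (n_bar / (n_bar - 1)) *
    (p_bar * (1 - p_bar) - ((r - 1) / r) * s2 -
       ((2 * n_bar - 1) / (4 * n_bar)) * h_bar)
  cc <- h_bar / 2
  if (return_components) return(c(a = a, b = b, c = cc))
  unname(a / (a + b + cc))
}

# --- brute-force centred moving average --------------------------------------
oracle_ma <- function(clamped, chromosome, window) {
  half <- (window - 1) / 2
  out <- rep(NA_real_, length(clamped))
  for (m in seq_along(clamped)) {
    lo <- m - half; hi <- m + half
    if (lo < 1 || hi > length(clamped)) next
    if (any(chromosome[lo:hi] != chromosome[m])) next
    vals <- clamped[lo:hi]
    if (all(is.na(vals))) next
    out[m] <- mean(vals, na.rm = TRUE)
  }
  out
}

# --- exhaustive O(n^2) ROH enumeration ---------------------------------------
# Enumerates every marker sub-interval, keeps those satisfying all
# criteria (hom non-missing endpoints, budgets, gap, count, length), and
# reduces to the leftmost-longest non-overlapping set.
oracle_roh <- function(g, pos, min_snps = 20, min_length_bp = 2e6,
                       max_gap_bp = 5e5, max_missing = 2, max_het = 0) {
  n <- length(g)
  hom <- !is.na(g) & g != 1
  cmiss <- c(0, cumsum(is.na(g)))
  chet <- c(0, cumsum(!is.na(g) & g == 1))
  gapseg <- cumsum(c(0, diff(pos) > max_gap_bp))
  cand_list <- list()
  for (i in seq_len(n)) {
    if (!hom[i]) next
    js <- i:n
    ok <- hom[js] &
      (cmiss[js + 1] - cmiss[i]) <= max_missing &
      (chet[js + 1] - chet[i]) <= max_het &
      (js - i + 1) >= min_snps &
      (pos[js] - pos[i]) >= min_length_bp &
      gapseg[js] == gapseg[i]
    if (any(ok))
      cand_list[[length(cand_list) + 1L]] <- cbind(i = i, j = js[ok])
  }
  cand <- if (length(cand_list)) do.call(rbind, cand_list) else NULL
  kept <- NULL
  while (!is.null(cand) && nrow(cand) > 0) {
    o <- order(cand[, "i"], -cand[, "j"])
    pick <- cand[o[1], , drop = FALSE]
    kept <- rbind(kept, pick)
    cand <- cand[cand[, "i"] > pick[, "j"], , drop = FALSE]
  }
  if (is.null(kept)) return(NULL)
  kept <- kept[order(kept[, "i"]), , drop = FALSE]
  data.frame(start_bp = pos[kept[, "i"]], end_bp = pos[kept[, "j"]],
             n_snps = kept[, "j"] - kept[, "i"] + 1)
}

# --- quadratic all-pairs interval overlap ------------------------------------
oracle_overlap <- function(regions, genes) {
  out <- NULL
  for (r in seq_len(nrow(regions))) {
    for (g in seq_len(nrow(genes))) {
      if (regions$chromosome[r] != genes$chromosome[g]) next
      if (regions$start_bp[r] <= genes$end_bp[g] &&
          genes$start_bp[g] <= regions$end_bp[r])
        out <- rbind(out, data.frame(region_index = r,
                                     gene_id = genes$gene_id[g]))
    }
  }
  out
}

# --- HWE exact test by direct enumeration ------------------------------------
# Conditional probability of each feasible heterozygote count from the
# closed-form expression via log-factorials; p = summed probability of
# all configurations no more likely than the observed one.
oracle_hwe <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  na_ <- 2 * n_aa + n_ab   # allele A count
  hets <- seq(na_ %% 2, min(na_, 2 * n - na_), by = 2)
  logp <- vapply(hets, function(h) {
    haa <- (na_ - h) / 2
    hbb <- n - haa - h
    h * log(2) + lgamma(n + 1) - lgamma(haa + 1) - lgamma(h + 1) -
      lgamma(hbb + 1) - (lgamma(2 * n + 1) - lgamma(na_ + 1) -
                           lgamma(2 * n - na_ + 1))
  }, numeric(1))
  p <- exp(logp)
  p <- p / sum(p)
  p_obs <- p[match(n_ab, hets)]
  min(1, sum(p[p <= p_obs * (1 + 1e-12)]))
}
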