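# Small in-code fixtures shared across test files.

# A dataset built directly from a dosage matrix (one chromosome unless
# chromosomes given). Positions default to a 100 kb grid.
make_dataset <- function(calls, positions = NULL, chromosomes = "1",
                         breeds = NULL) {
  calls <- as.matrix(calls)
  m <- ncol(calls); n <- nrow(calls)
  positions <- positions %||% (seq_len(m) * 100000L)
  chromosomes <- rep_len(chromosomes, m)
  map <- data.frame(marker_id = sprintf("m%03d", seq_len(m)),
                    chromosome = chromosomes, position_bp = positions,
                    allele_a = "A", allele_b = "C")
  samples <- data.frame(sample_id = sprintf("s%02d", seq_len(n)),
                        breed = breeds %||% rep("B1", n))
  genotype_dataset(calls, map, samples)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random genotype matrix with controlled missingness, for oracle sweeps.
random_calls <- function(n, m, p_het = 0.3, p_miss = 0.05) {
  g <- sample(c(0L, 1L, 2L), n * m, replace = TRUE,
              prob = c((1 - p_het) / 2, p_het, (1 - p_het) / 2))
  g[stats::runif(n * m) < p_miss] <- NA_integer_
  matrix(g, n, m)
}

# Two-chromosome desk-scale simulation used by several suites.
small_sim <- function(seed = 1, ...) {
  simulate_dataset(sim_config(
    seed = seed,
    chrom_lengths_bp = stats::setNames(c(8e7, 6e7), c("1", "2")),
    markers_per_chrom = 400L,
    breed_names = c("P1", "P2"), samples_per_breed = c(12L, 15L),
    drift = c(0.1, 0.1), autozygosity_f = c(0.1, 0),
    autozygosity_g = c(5, 5), sweep = NULL, missing_rate = 0.02, ...))
}
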