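roh_one <- function(g, pos, ...) {
  gd <- make_dataset(matrix(g, nrow = 1), positions = pos)
  detect_roh(gd, ...)
}

test_that("the four calling criteria are enforced", {
  # 25 consecutive homozygous SNPs spanning 3 Mb: one ROH
  pos <- as.integer(seq(1e6, 4e6, length.out = 25))
  segs <- roh_one(rep(0L, 25), pos)
  expect_equal(nrow(segs), 1)
  expect_equal(segs$n_snps, 25L)
  expect_equal(segs$start_bp, pos[1])
  expect_equal(segs$end_bp, pos[25])

  # same stretch squeezed into 1.5 Mb: too short
  pos2 <- as.integer(seq(1e6, 2.5e6, length.out = 25))
  expect_equal(nrow(roh_one(rep(0L, 25), pos2)), 0)

  # 19 SNPs over 3 Mb: too few markers
  pos3 <- as.integer(seq(1e6, 4e6, length.out = 19))
  expect_equal(nrow(roh_one(rep(2L, 19), pos3)), 0)

  # a 600 kb gap splits the run; only the long right-hand stretch survives
  pos4 <- c(seq(1e6, 2.2e6, by = 1e5), seq(2.9e6, 5.4e6, by = 1e5))
  segs4 <- roh_one(rep(0L, length(pos4)), as.integer(pos4))
  expect_equal(nrow(segs4), 1)
  expect_equal(segs4$start_bp, 2900000L)
  expect_equal(segs4$end_bp, 5400000L)

  # one heterozygous call breaks the run; three missing calls exceed budget
  g <- rep(0L, 50); g[25] <- 1L
  pos5 <- as.integer(seq(1e6, 8e6, length.out = 50))
  segs5 <- roh_one(g, pos5)
  expect_true(all(segs5$n_het == 0))
  g2 <- rep(0L, 50); g2[c(10, 20, 30)] <- NA
  segs6 <- roh_one(g2, pos5)
  expect_true(all(segs6$n_missing <= 2))
})

test_that("missing-call handling matches the exhaustive oracle on the planted case", {
  g <- rep(2L, 60); g[c(10, 30, 50)] <- NA
  pos <- as.integer(seq(1e6, 7e6, length.out = 60))
  segs <- roh_one(g, pos)
  want <- oracle_roh(g, pos)
  expect_equal(segs$start_bp, want$start_bp)
  expect_equal(segs$end_bp, want$end_bp)
  expect_equal(segs$n_snps, want$n_snps)
})

test_that("detector equals the exhaustive sub-interval oracle on random strings", {
  set.seed(12)
  n_cases <- 250
  for (case in seq_len(n_cases)) {
    n <- sample(30:120, 1)
    g <- sample(c(0L, 1L, 2L, NA), n, replace = TRUE,
                prob = c(0.45, 0.06, 0.45, 0.04))
    pos <- as.integer(sort(sample.int(8e6, n)))
    ms <- sample(c(10L, 20L), 1)
    ml <- sample(c(1e6, 2e6), 1)
    segs <- roh_one(g, pos, min_snps = ms, min_length_bp = ml)
    want <- oracle_roh(g, pos, min_snps = ms, min_length_bp = ml)
    if (is.null(want)) {
      expect_equal(nrow(segs), 0, info = paste("case", case))
    } else {
      expect_equal(segs$start_bp, want$start_bp, info = paste("case", case))
      expect_equal(segs$end_bp, want$end_bp, info = paste("case", case))
      expect_equal(segs$n_snps, want$n_snps, info = paste("case", case))
    }
  }
})

test_that("threshold monotonicity holds", {
  set.seed(13)
  sim <- small_sim(seed = 21)
  base <- nrow(detect_roh(sim$dataset, min_snps = 15, min_length_bp = 1e6))
  expect_lte(nrow(detect_roh(sim$dataset, min_snps = 25, min_length_bp = 1e6)),
             base)
  expect_lte(nrow(detect_roh(sim$dataset, min_snps = 15, min_length_bp = 3e6)),
             base)
  lo <- nrow(detect_roh(sim$dataset, min_snps = 15, min_length_bp = 1e6,
                        max_missing = 0))
  expect_gte(base, lo)
})

test_that("length classes use half-open bins", {
  segs <- data.frame(sample_id = "s", chromosome = "1",
                     start_bp = 1L,
                     end_bp = c(3999999L + 1L, 4000000L + 1L, 17000000L + 1L),
                     length_bp = c(3999999L, 4000000L, 17000000L),
                     n_snps = 30L, n_missing = 0L, n_het = 0L,
                     length_class = NA_character_)
  cl <- classify_segments(segs)
  expect_equal(cl$length_class, c("2-4", "4-8", ">16"))
  segs$length_bp[1] <- 1e6
  expect_error(classify_segments(segs), "shorter than 2 Mb")
})

test_that("F_ROH arithmetic and the zero-ROH individual are handled", {
  # one 24.63 Mb segment over a 2.463 Gb autosome: F_ROH = 0.01 exactly
  pos <- as.integer(seq(1e6, 25.63e6, length.out = 83))
  calls <- rbind(rep(0L, 83), rep(1L, 83))
  gd <- make_dataset(calls, positions = pos, breeds = c("X", "X"))
  segs <- classify_segments(detect_roh(gd))
  expect_equal(segs$length_bp, 24630000L)
  sm <- summarize_roh(segs, gd, l_auto_bp = 2.463e9)
  expect_equal(sm$per_individual$f_roh_total, c(0.01, 0))
  expect_equal(sm$per_breed$n_0, 1L)
  # class-wise F_ROH sums to the total exactly
  cls <- as.matrix(sm$per_individual[, paste0("f_roh_", c("2-4", "4-8", "8-16", ">16"))])
  expect_equal(unname(rowSums(cls)), sm$per_individual$f_roh_total,
               tolerance = 1e-12)
  # N_0 + individuals with ROH = breed size
  expect_equal(sm$per_breed$n_0 + sum(sm$per_individual$n_roh > 0),
               sm$per_breed$n)
})

test_that("expected ROH length follows 100/(2g) Mb", {
  expect_equal(expected_roh_length(25), 2)
  expect_equal(expected_roh_length(50), 1)
  expect_equal(expected_roh_length(1), 50)
  expect_error(expected_roh_length(0), "positive")
})

test_that("recent autozygosity yields long ROH, ancient yields short", {
  classes <- paste0("f_roh_", c("2-4", "4-8", "8-16", ">16"))
  shares <- list()
  for (g0 in c(3, 25)) {
    sim <- simulate_dataset(sim_config(
      seed = 9, chrom_lengths_bp = stats::setNames(rep(1.2e8, 3), as.character(1:3)),
      markers_per_chrom = 3600L, breed_names = "B", samples_per_breed = 20L,
      drift = 0.05, autozygosity_f = 0.15, autozygosity_g = g0,
      sweep = NULL, missing_rate = 0.005))
    sm <- summarize_roh(classify_segments(detect_roh(sim$dataset)),
                        sim$dataset)
    shares[[as.character(g0)]] <- unlist(sm$per_breed[1, classes])
  }
  recent <- shares[["3"]]; ancient <- shares[["25"]]
  # recent inbreeding: the >16 Mb class dominates coverage
  expect_equal(names(which.max(recent)), "f_roh_>16")
  # ancient inbreeding: >16 Mb is the smallest class, short classes dominate
  expect_equal(names(which.min(ancient)), "f_roh_>16")
  expect_gt(ancient[["f_roh_2-4"]] + ancient[["f_roh_4-8"]],
            ancient[["f_roh_8-16"]] + ancient[["f_roh_>16"]])
  # the short-class share is far larger under ancient inbreeding
  expect_gt(ancient[["f_roh_2-4"]] / sum(ancient),
            3 * recent[["f_roh_2-4"]] / sum(recent))
})
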