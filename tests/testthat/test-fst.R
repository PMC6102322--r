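test_that("theta is 1 for opposite fixation and clamps to 0 at equality", {
  calls <- rbind(matrix(0L, 5, 10), matrix(2L, 7, 10))
  gd <- make_dataset(calls, breeds = rep(c("F", "R"), c(5, 7)))
  tr <- wc_theta(gd, "F")
  expect_equal(tr$raw_theta, rep(1, 10))

  # identical genotype arrays in both groups: estimator <= 0, clamped to 0
  block <- random_calls(6, 10, p_miss = 0)
  gd2 <- make_dataset(rbind(block, block), breeds = rep(c("F", "R"), each = 6))
  tr2 <- wc_theta(gd2, "F")
  expect_true(all(tr2$raw_theta[!is.na(tr2$raw_theta)] <= 1e-12))
  expect_equal(tr2$clamped_theta[!is.na(tr2$raw_theta)],
               rep(0, sum(!is.na(tr2$raw_theta))))
})

test_that("theta matches the independent component oracle", {
  # 13 vs 131 with the fixed genotype counts
  g1 <- rep(c(0L, 1L), c(10, 3))
  g2 <- rep(c(0L, 1L, 2L), c(20, 60, 51))
  gd <- make_dataset(matrix(c(g1, g2), ncol = 1),
                     breeds = rep(c("F", "R"), c(13, 131)))
  tr <- wc_theta(gd, "F")
  expect_equal(tr$raw_theta, oracle_wc_theta(c(10, 3, 0), c(20, 60, 51)),
               tolerance = 1e-12)
  expect_equal(tr$raw_theta, 0.350237009854, tolerance = 1e-9)

  set.seed(9)
  for (rep in 1:100) {
    c1 <- as.vector(stats::rmultinom(1, sample(2:40, 1), c(0.4, 0.3, 0.3)))
    c2 <- as.vector(stats::rmultinom(1, sample(2:40, 1), c(0.2, 0.3, 0.5)))
    gd <- make_dataset(matrix(c(rep(0:2, c1), rep(0:2, c2)), ncol = 1),
                       breeds = rep(c("F", "R"), c(sum(c1), sum(c2))))
    got <- wc_theta(gd, "F")$raw_theta
    want <- oracle_wc_theta(c1, c2)
    if (is.nan(want)) expect_true(is.na(got)) else
      expect_equal(got, want, tolerance = 1e-12,
                   info = paste(c(c1, c2), collapse = ","))
  }
})

test_that("theta is invariant to swapping allele labels", {
  set.seed(10)
  calls <- random_calls(30, 50, p_miss = 0.05)
  gd <- make_dataset(calls, breeds = rep(c("F", "R"), c(12, 18)))
  tr <- wc_theta(gd, "F")
  gds <- make_dataset(2L - calls, breeds = rep(c("F", "R"), c(12, 18)))
  trs <- wc_theta(gds, "F")
  expect_equal(tr$raw_theta, trs$raw_theta, tolerance = 1e-12)
  expect_true(all(tr$clamped_theta >= 0 & tr$clamped_theta <= 1, na.rm = TRUE))
})

test_that("markers with fewer than two calls in a group are undefined", {
  calls <- rbind(c(0L, NA), c(0L, NA), c(2L, 0L), c(2L, 2L), c(2L, 1L))
  gd <- make_dataset(calls, breeds = rep(c("F", "R"), c(2, 3)))
  tr <- wc_theta(gd, "F")
  expect_false(is.na(tr$raw_theta[1]))
  expect_true(is.na(tr$raw_theta[2]))
  expect_error(wc_theta(gd, "Z"), "absent")
  expect_error(wc_theta(gd, "F", exclude_breeds = "R"), "empty")
})

test_that("moving average equals the brute-force windowed mean", {
  # constant track
  calls <- rbind(matrix(0L, 4, 20), matrix(2L, 4, 20))
  gd <- make_dataset(calls, breeds = rep(c("F", "R"), each = 4))
  tr <- moving_average(wc_theta(gd, "F"))
  expect_equal(tr$ma_theta[3:18], rep(1, 16))
  expect_true(all(is.na(tr$ma_theta[c(1, 2, 19, 20)])))

  # (0,0,1,0,0) -> 0.2 at the centre
  tr2 <- wc_theta(gd, "F")[1:5, ]
  tr2$clamped_theta <- c(0, 0, 1, 0, 0)
  tr2$raw_theta <- tr2$clamped_theta
  expect_equal(moving_average(tr2)$ma_theta[3], 0.2)

  # random track with NA holes vs brute force, across two chromosomes
  set.seed(11)
  n <- 1000
  chrom <- rep(c("1", "2"), c(600, 400))
  clamped <- stats::runif(n)
  clamped[sample(n, 50)] <- NA
  track <- data.frame(marker_id = as.character(seq_len(n)),
                      chromosome = chrom, position_bp = seq_len(n) * 1e5,
                      raw_theta = clamped, clamped_theta = clamped,
                      ma_theta = NA_real_)
  got <- moving_average(track)$ma_theta
  want <- oracle_ma(clamped, chrom, 5)
  expect_equal(got, want)
})

test_that("region calling uses a strict threshold and maximal runs", {
  n <- 200
  base <- data.frame(marker_id = as.character(seq_len(n)), chromosome = "1",
                     position_bp = seq_len(n) * 1e5,
                     raw_theta = rep(0.2, n), clamped_theta = rep(0.2, n),
                     ma_theta = NA_real_)
  # all raw values equal: threshold = value, strict ">" yields no regions
  flat <- moving_average(base)
  expect_equal(nrow(call_regions(flat)), 0)

  # one injected 10-marker plateau above threshold
  plat <- base
  plat$raw_theta[21:30] <- plat$clamped_theta[21:30] <- 0.9
  plat <- moving_average(plat)
  rg <- call_regions(plat, quantile_level = 0.95)
  expect_equal(nrow(rg), 1)
  # the run of ma values above the threshold is the plateau core
  above <- which(!is.na(plat$ma_theta) &
                   plat$ma_theta > attr(rg, "threshold_used"))
  expect_equal(rg$start_bp, plat$position_bp[min(above)])
  expect_equal(rg$end_bp, plat$position_bp[max(above)])
  expect_equal(rg$n_markers, length(above))
  expect_gt(rg$peak_ma_theta, attr(rg, "threshold_used"))

  # invariance under marker-order-preserving position rescaling
  resc <- plat
  resc$position_bp <- resc$position_bp * 7L
  rg2 <- call_regions(moving_average(resc), quantile_level = 0.95)
  expect_equal(rg2$n_markers, rg$n_markers)
  expect_equal(rg2$start_bp, rg$start_bp * 7L)
})

test_that("excluding a breed removes it from the complement", {
  sim <- simulate_dataset(sim_config(
    seed = 13, chrom_lengths_bp = stats::setNames(5e7, "1"),
    markers_per_chrom = 300L, breed_names = c("A", "B", "C"),
    samples_per_breed = c(10L, 10L, 10L), drift = c(0.3, 0.05, 0.05),
    autozygosity_f = c(0, 0, 0), autozygosity_g = c(5, 5, 5),
    sweep = NULL, missing_rate = 0))
  with_a <- wc_theta(sim$dataset, "B")
  without_a <- wc_theta(sim$dataset, "B", exclude_breeds = "A")
  expect_false(isTRUE(all.equal(with_a$raw_theta, without_a$raw_theta)))
  # complement of B without A is exactly C: same as a two-breed dataset
  keep <- sim$dataset$samples$breed %in% c("B", "C")
  two <- genotype_dataset(sim$dataset$calls[keep, ],
                          sim$dataset$map,
                          sim$dataset$samples[keep, ])
  expect_equal(without_a$raw_theta, wc_theta(two, "B")$raw_theta)
})
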