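# One-vs-rest Weir-Cockerham fixation-index scan.
#
# Per SNP, the two-population variance-component estimator theta-hat =
# a / (a + b + c) of Weir & Cockerham (1984) compares the focal breed to
# the pooled remaining breeds; negative values are clamped to zero, a
# centred moving average smooths the clamped track, and maximal runs of
# smoothed values above an empirical quantile of the raw per-SNP
# distribution become candidate selection-signature regions.

#' Per-marker Weir-Cockerham fixation index, one breed vs the rest
#'
#' Computes the two-population Weir-Cockerham (1984) estimator
#' `theta = a / (a + b + c)` at every marker, contrasting `focal_breed`
#' with the pooled complement. The full variance components are used,
#' including the observed-heterozygosity correction; each marker gets its
#' own ratio (no ratio-of-sums pooling), since downstream thresholding is
#' per SNP. A marker is undefined (`NA`) when either group has fewer than
#' two non-missing calls or the marker is monomorphic overall
#' (denominator zero).
#'
#' @param dataset A [genotype_dataset()].
#' @param focal_breed Breed label whose differentiation from the pooled
#'   remaining breeds is scanned.
#' @param exclude_breeds Optional breed labels dropped from the complement
#'   (e.g. to rescan native breeds without an exotic outgroup).
#' @return An `fst_track` data frame with one row per marker: `marker_id`,
#'   `chromosome`, `position_bp`, `raw_theta`, `clamped_theta`
#'   (`max(raw, 0)`), `ma_theta` (`NA` until [moving_average()]);
#'   attributes `focal_breed`, `genome_mean_theta` (mean of defined
#'   clamped per-SNP values — the usual reporting convention for breed
#'   averages) and `genome_theta_multilocus` (ratio of summed variance
#'   components over defined markers — Weir & Cockerham's multi-locus
#'   estimator, the calibrated estimate of genome-wide differentiation;
#'   the mean of per-SNP ratios is biased low under strong drift).
#' @export
wc_theta <- function(dataset, focal_breed, exclude_breeds = NULL) {
  breeds <- dataset$samples$breed
  if (!focal_breed %in% breeds) stopf("focal breed '%s' absent", focal_breed)
  in_focal <- breeds == focal_breed
  in_rest <- !in_focal & !(breeds %in% exclude_breeds)
  if (!any(in_rest)) stopf("complement of '%s' is empty", focal_breed)

  g1 <- dataset$calls[in_focal, , drop = FALSE]
  g2 <- dataset$calls[in_rest, , drop = FALSE]
  n1 <- colSums(!is.na(g1)); n2 <- colSums(!is.na(g2))
  p1 <- colSums(g1, na.rm = TRUE) / (2 * pmax(n1, 1L))
  p2 <- colSums(g2, na.rm = TRUE) / (2 * pmax(n2, 1L))
  h1 <- colSums(g1 == 1L, na.rm = TRUE) / pmax(n1, 1L)
  h2 <- colSums(g2 == 1L, na.rm = TRUE) / pmax(n2, 1L)

  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)

  a <- nbar / nc *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2

  raw <- a / (a + b + cc)
  raw[n1 < 2L | n2 < 2L] <- NA_real_
  raw[!is.finite(raw)] <- NA_real_
  clamped <- pmax(raw, 0)
  def <- !is.na(raw)

  track <- data.frame(marker_id = dataset$map$marker_id,
                      chromosome = dataset$map$chromosome,
                      position_bp = dataset$map$position_bp,
                      raw_theta = raw, clamped_theta = clamped,
                      ma_theta = NA_real_)
  attr(track, "focal_breed") <- focal_breed
  attr(track, "genome_mean_theta") <- mean(clamped, na.rm = TRUE)
  attr(track, "genome_theta_multilocus") <-
    sum(a[def]) / sum(a[def] + b[def] + cc[def])
  class(track) <- c("fst_track", "data.frame")
  track
}

#' Moving average of the clamped fixation-index track
#'
#' Smooths `clamped_theta` with an unweighted centred moving average over
#' `window` adjacent markers of the same chromosome. Undefined markers
#' inside a window are skipped (the mean is over the defined values);
#' markers within `(window - 1) / 2` positions of a chromosome end get no
#' value, as truncated edge windows would inflate variance there.
#'
#' @param track An `fst_track` from [wc_theta()].
#' @param window Odd window size in markers (default 5).
#' @return The track with `ma_theta` filled.
#' @export
moving_average <- function(track, window = 5L) {
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) stopf("window must be odd and >= 1")
  half <- (window - 1L) %/% 2L
  ma <- rep(NA_real_, nrow(track))
  for (chr in unique(track$chromosome)) {
    idx <- which(track$chromosome == chr)
    nc <- length(idx)
    if (nc < window) {
      warnf("chromosome %s has %d < %d markers; no moving average", chr, nc, window)
      next
    }
    x <- track$clamped_theta[idx]
    def <- !is.na(x)
    # direct per-window sums (no cumulative-sum rounding drift)
    tot <- stats::filter(ifelse(def, x, 0), rep(1, window), sides = 2)
    cnt <- stats::filter(as.numeric(def), rep(1, window), sides = 2)
    val <- ifelse(!is.na(cnt) & cnt > 0, tot / cnt, NA_real_)
    ma[idx] <- as.numeric(val)
  }
  track$ma_theta <- ma
  track
}

#' Call selection-signature regions from a smoothed track
#'
#' The threshold is the empirical `quantile_level` quantile (linear
#' interpolation between order statistics, quantile type 7) of the
#' *clamped raw* per-SNP values over all defined markers genome-wide.
#' Maximal runs of consecutive markers with `ma_theta` strictly above the
#' threshold on one chromosome become regions; region bounds are the
#' positions of the run's first and last marker.
#'
#' @param track An `fst_track` with `ma_theta` filled (see
#'   [moving_average()]).
#' @param quantile_level Quantile of the raw distribution used as the
#'   threshold (default 0.95).
#' @return A `region_set` data frame (`chromosome`, `start_bp`, `end_bp`,
#'   `n_markers`, `peak_ma_theta`, `peak_marker_id`) with attributes
#'   `threshold_used`, `quantile_level` and `focal_breed`. Zero rows when
#'   no marker exceeds the threshold.
#' @export
call_regions <- function(track, quantile_level = 0.95) {
  if (all(is.na(track$ma_theta)))
    stopf("track has no moving-average values; run moving_average() first")
  thr <- stats::quantile(track$clamped_theta, quantile_level,
                         na.rm = TRUE, names = FALSE, type = 7)
  above <- !is.na(track$ma_theta) & track$ma_theta > thr

  regions <- data.frame(chromosome = character(), start_bp = integer(),
                        end_bp = integer(), n_markers = integer(),
                        peak_ma_theta = numeric(), peak_marker_id = character())
  for (chr in unique(track$chromosome)) {
    idx <- which(track$chromosome == chr)
    ab <- above[idx]
    if (!any(ab)) next
    r <- rle(ab)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      run <- idx[starts[k]:ends[k]]
      peak <- run[which.max(track$ma_theta[run])]
      regions <- rbind(regions, data.frame(
        chromosome = chr,
        start_bp = track$position_bp[run[1]],
        end_bp = track$position_bp[run[length(run)]],
        n_markers = length(run),
        peak_ma_theta = track$ma_theta[peak],
        peak_marker_id = track$marker_id[peak]))
    }
  }
  rownames(regions) <- NULL
  attr(regions, "threshold_used") <- thr
  attr(regions, "quantile_level") <- quantile_level
  attr(regions, "focal_breed") <- attr(track, "focal_breed")
  class(regions) <- c("region_set", "data.frame")
  regions
}

#' Full one-breed selection scan
#'
#' Convenience chain [wc_theta()] -> [moving_average()] ->
#' [call_regions()].
#'
#' @inheritParams wc_theta
#' @inheritParams moving_average
#' @inheritParams call_regions
#' @return List with elements `track` and `regions`.
#' @export
fst_scan <- function(dataset, focal_breed, exclude_breeds = NULL,
                     window = 5L, quantile_level = 0.95) {
  track <- moving_average(wc_theta(dataset, focal_breed, exclude_breeds),
                          window)
  list(track = track, regions = call_regions(track, quantile_level))
}

#' Write a region set as a BED file
#'
#' Internal coordinates are 1-based inclusive; BED output is 0-based
#' half-open (`start_bp - 1`, `end_bp`).
#'
#' @param regions A `region_set` (or ROH segment data frame with
#'   `chromosome`, `start_bp`, `end_bp` and an optional name column).
#' @param path Output path.
#' @param name_col Column used for the BED name field (default: peak
#'   marker or sample id if present).
#' @return Invisibly, `path`.
#' @export
regions_to_bed <- function(regions, path,
                           name_col = intersect(c("peak_marker_id", "sample_id"),
                                                names(regions))[1]) {
  name <- if (!is.na(name_col) && !is.null(name_col)) regions[[name_col]] else "."
  bed <- data.frame(regions$chromosome, regions$start_bp - 1L,
                    regions$end_bp, name)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
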