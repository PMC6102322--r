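# Runs of homozygosity and the genomic inbreeding coefficient F_ROH.
#
# An ROH is a maximal stretch of an individual's genotype calls that is
# free of heterozygous calls, contains at most a fixed number of missing
# calls, has no large inter-marker gap, and passes marker-count and
# physical-length minima. Candidate stretches are resolved into a
# deterministic non-overlapping set by a leftmost-longest rule: repeatedly
# take the valid sub-interval with the smallest start (ties: the longest)
# among those not overlapping a segment already kept.

#' Detect runs of homozygosity
#'
#' Scans each individual's genotype calls chromosome by chromosome. A
#' valid run must (1) span at least `min_snps` consecutive markers,
#' (2) cover at least `min_length_bp` base pairs (`end - start` positions
#' of its first and last marker), (3) contain no inter-marker gap larger
#' than `max_gap_bp`, and (4) contain at most `max_missing` missing calls
#' and at most `max_het` heterozygous calls. Run endpoints must be
#' homozygous non-missing calls, so missing calls cannot inflate run
#' length at the flanks. Overlapping candidates are resolved greedily
#' left-to-right, always keeping the longest run at the leftmost feasible
#' start; the result is deterministic and order-independent.
#'
#' @param dataset A [genotype_dataset()] (QC'd; markers sorted).
#' @param min_snps Minimum number of markers in a run (default 20).
#' @param min_length_bp Minimum physical length in bp (default 2e6).
#' @param max_gap_bp Maximum gap between consecutive markers inside a run
#'   (default 5e5).
#' @param max_missing Maximum missing calls inside a run (default 2).
#' @param max_het Maximum heterozygous calls inside a run (default 0).
#' @return Data frame of segments: `sample_id`, `chromosome`, `start_bp`,
#'   `end_bp`, `length_bp` (= end - start), `n_snps`, `n_missing`,
#'   `n_het`, `length_class` (filled by [classify_segments()]).
#' @export
detect_roh <- function(dataset, min_snps = 20L, min_length_bp = 2e6,
                       max_gap_bp = 5e5, max_missing = 2L, max_het = 0L) {
  if (min_snps < 1 || min_length_bp < 0 || max_gap_bp < 0 ||
      max_missing < 0 || max_het < 0)
    stopf("ROH thresholds must be non-negative (min_snps >= 1)")
  map <- dataset$map
  if (is.unsorted(marker_order(map)))  # construction guarantees this
    stopf("markers are not sorted by (chromosome, position)")

  out <- vector("list", 0L)
  chrs <- unique(map$chromosome)
  for (chr in chrs) {
    idx <- which(map$chromosome == chr)
    pos <- map$position_bp[idx]
    # split points where the inter-marker gap exceeds max_gap_bp
    gap_break <- which(diff(pos) > max_gap_bp)
    stretch_id <- cumsum(c(1L, seq_along(pos)[-1] %in% (gap_break + 1L)))
    for (s in seq_len(nrow(dataset$calls))) {
      g <- dataset$calls[s, idx]
      for (st in unique(stretch_id)) {
        sel <- which(stretch_id == st)
        segs <- roh_in_stretch(g[sel], pos[sel], min_snps, min_length_bp,
                               max_missing, max_het)
        if (!is.null(segs)) {
          segs$sample_id <- dataset$samples$sample_id[s]
          segs$chromosome <- chr
          out[[length(out) + 1L]] <- segs
        }
      }
    }
  }
  if (!length(out)) {
    segs <- data.frame(sample_id = character(), chromosome = character(),
                       start_bp = integer(), end_bp = integer(),
                       length_bp = integer(), n_snps = integer(),
                       n_missing = integer(), n_het = integer())
  } else {
    segs <- do.call(rbind, out)
    segs <- segs[, c("sample_id", "chromosome", "start_bp", "end_bp",
                     "length_bp", "n_snps", "n_missing", "n_het")]
  }
  segs$length_class <- rep(NA_character_, nrow(segs))
  rownames(segs) <- NULL
  segs
}

# Greedy leftmost-longest ROH search within one gap-free stretch of one
# chromosome for one individual. g: dosage vector (0/1/2/NA); pos:
# positions, strictly increasing, all gaps <= max_gap_bp.
roh_in_stretch <- function(g, pos, min_snps, min_length_bp,
                           max_missing, max_het) {
  n <- length(g)
  if (n < min_snps) return(NULL)
  hom <- !is.na(g) & g != 1L
  cmiss <- c(0L, cumsum(is.na(g)))
  chet <- c(0L, cumsum(!is.na(g) & g == 1L))
  res <- NULL
  i <- 1L
  j_hi <- 0L
  while (i <= n) {
    if (!hom[i]) { i <- i + 1L; next }
    # furthest right endpoint with both interior budgets respected
    if (j_hi < i) j_hi <- i
    while (j_hi < n &&
           cmiss[j_hi + 2L] - cmiss[i] <= max_missing &&
           chet[j_hi + 2L] - chet[i] <= max_het) j_hi <- j_hi + 1L
    j <- j_hi
    while (j > i && !hom[j]) j <- j - 1L  # trim to homozygous endpoint
    if (j - i + 1L >= min_snps && pos[j] - pos[i] >= min_length_bp) {
      res <- rbind(res, data.frame(
        start_bp = pos[i], end_bp = pos[j], length_bp = pos[j] - pos[i],
        n_snps = j - i + 1L,
        n_missing = cmiss[j + 1L] - cmiss[i],
        n_het = chet[j + 1L] - chet[i]))
      i <- j + 1L
      j_hi <- j
    } else {
      i <- i + 1L
    }
  }
  res
}

#' Assign ROH length classes
#'
#' Bins segments into the length categories 2-4, 4-8, 8-16 and >16 Mb
#' (half-open on the right: a 4.000.000 bp segment falls in 4-8). Short
#' classes reflect more ancient inbreeding, the open-ended class recent
#' inbreeding.
#'
#' @param segments Segment data frame from [detect_roh()].
#' @return The segments with `length_class` filled.
#' @export
classify_segments <- function(segments) {
  if (nrow(segments) == 0L) return(segments)
  if (any(segments$length_bp < 2e6))
    stopf("segment shorter than 2 Mb cannot be length-classified")
  segments$length_class <- as.character(cut(
    segments$length_bp / 1e6, breaks = c(2, 4, 8, 16, Inf),
    labels = c("2-4", "4-8", "8-16", ">16"), right = FALSE))
  segments
}

ROH_CLASSES <- c("2-4", "4-8", "8-16", ">16")

#' Per-individual and per-breed ROH summaries
#'
#' Computes, per individual, the ROH count, total ROH length and the
#' genomic inbreeding coefficient `F_ROH` (total ROH length divided by
#' `L_AUTO`, the summed per-chromosome marker span), in total and per
#' length class; and per breed, the total ROH count `nROH`, the mean
#' per-individual ROH coverage `S_ROH` (Mb), the mean segment length
#' `L_ROH` (Mb), the count `N_0` of individuals without any ROH, and
#' class-wise mean `F_ROH`. Also emits each breed's per-chromosome share
#' of its total ROH coverage.
#'
#' @param segments Classified segments (see [classify_segments()]).
#' @param dataset The [genotype_dataset()] the segments came from (used
#'   for the sample/breed table and the marker spans).
#' @param l_auto_bp Optional override of the autosome length covered by
#'   the markers; by default the summed per-chromosome span
#'   (max - min position) of the dataset's markers.
#' @return List of data frames `per_individual`, `per_breed`,
#'   `per_chromosome`, plus `l_auto_bp`.
#' @export
summarize_roh <- function(segments, dataset, l_auto_bp = NULL) {
  map <- dataset$map
  spans <- tapply(map$position_bp, map$chromosome,
                  function(p) diff(range(p)))
  if (is.null(l_auto_bp)) l_auto_bp <- sum(spans)
  if (l_auto_bp <= 0) stopf("L_AUTO must be positive (need >= 2 markers on some chromosome)")
  if (nrow(segments) > 0 && anyNA(segments$length_class))
    segments <- classify_segments(segments)

  smp <- dataset$samples
  per_ind <- data.frame(sample_id = smp$sample_id, breed = smp$breed,
                        n_roh = 0L, sum_roh_bp = 0)
  for (cl in ROH_CLASSES) per_ind[[paste0("f_roh_", cl)]] <- 0
  if (nrow(segments) > 0) {
    cnt <- table(factor(segments$sample_id, levels = smp$sample_id))
    per_ind$n_roh <- as.integer(cnt)
    tot <- as.numeric(tapply(segments$length_bp,
                             factor(segments$sample_id, levels = smp$sample_id), sum))
    per_ind$sum_roh_bp <- ifelse(is.na(tot), 0, tot)
    for (cl in ROH_CLASSES) {
      sl <- segments[segments$length_class == cl, ]
      t2 <- as.numeric(tapply(sl$length_bp,
                              factor(sl$sample_id, levels = smp$sample_id), sum))
      per_ind[[paste0("f_roh_", cl)]] <- ifelse(is.na(t2), 0, t2) / l_auto_bp
    }
  }
  per_ind$f_roh_total <- per_ind$sum_roh_bp / l_auto_bp

  breeds <- unique(smp$breed)
  per_breed <- data.frame(breed = breeds,
                          n = as.integer(table(factor(smp$breed, levels = breeds))))
  bseg <- merge(segments, smp, by = "sample_id")
  per_breed$n_roh <- as.integer(table(factor(bseg$breed, levels = breeds)))
  sum_by_breed <- tapply(bseg$length_bp, factor(bseg$breed, levels = breeds), sum)
  sum_by_breed[is.na(sum_by_breed)] <- 0
  per_breed$s_roh_mb <- as.numeric(sum_by_breed) / per_breed$n / 1e6
  mean_len <- tapply(bseg$length_bp, factor(bseg$breed, levels = breeds), mean)
  per_breed$mean_l_roh_mb <- as.numeric(mean_len) / 1e6
  per_breed$n_0 <- as.integer(tapply(per_ind$n_roh == 0,
                                     factor(per_ind$breed, levels = breeds), sum))
  for (cl in ROH_CLASSES)
    per_breed[[paste0("f_roh_", cl)]] <-
      as.numeric(tapply(per_ind[[paste0("f_roh_", cl)]],
                        factor(per_ind$breed, levels = breeds), mean))
  per_breed$f_roh_total <- as.numeric(tapply(per_ind$f_roh_total,
                                             factor(per_ind$breed, levels = breeds), mean))

  chrs <- names(spans)
  per_chrom <- expand.grid(breed = breeds, chromosome = chrs,
                           stringsAsFactors = FALSE)
  cov <- tapply(bseg$length_bp,
                list(factor(bseg$breed, levels = breeds),
                     factor(bseg$chromosome, levels = chrs)), sum)
  cov[is.na(cov)] <- 0
  tot_b <- rowSums(cov)
  per_chrom$roh_bp <- as.vector(cov[cbind(per_chrom$breed, per_chrom$chromosome)])
  per_chrom$share_of_breed_roh <-
    ifelse(tot_b[per_chrom$breed] > 0,
           per_chrom$roh_bp / tot_b[per_chrom$breed], NA_real_)

  list(per_individual = per_ind, per_breed = per_breed,
       per_chromosome = per_chrom, l_auto_bp = l_auto_bp)
}

#' Expected ROH length for autozygosity of a given age
#'
#' The length of an identical-by-descent segment inherited from a common
#' ancestor `g` generations back is approximately exponentially
#' distributed with mean `100 / (2 g)` centimorgan; at the usual livestock
#' approximation of 1 cM per Mb this is returned directly in Mb. For
#' example, 25 generations gives 2 Mb — the usual minimum-length cutoff
#' for array-based ROH calling.
#'
#' @param generations Number of generations to the common ancestor
#'   (>= 1).
#' @return Expected segment length in Mb.
#' @export
expected_roh_length <- function(generations) {
  if (any(!is.finite(generations)) || any(generations <= 0))
    stopf("generations must be positive")
  100 / (2 * generations)
}
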