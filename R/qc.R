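# Sample- and marker-level quality control.
#
# Filters follow standard SNP-array practice for multi-breed diversity
# panels: drop samples with high missingness first, then drop markers by
# call rate, minor allele frequency, autosome membership, Hardy-Weinberg
# exact test on the pooled samples, and finally unknown map position.
# Each removed marker is attributed to the first filter that rejects it.

#' Remove samples with excessive missingness
#'
#' Drops every sample whose missing-call fraction is greater than or
#' *equal to* `max_missing_rate` (the threshold is inclusive).
#'
#' @param dataset A [genotype_dataset()].
#' @param max_missing_rate Missing-call fraction at or above which a sample
#'   is removed. Default 0.1.
#' @return List with elements `dataset` (filtered) and `report`
#'   (data frame: per-sample missing rate and removal flag plus counts).
#' @export
filter_samples <- function(dataset, max_missing_rate = 0.1) {
  miss <- rowMeans(is.na(dataset$calls))
  drop <- miss >= max_missing_rate
  if (all(drop)) stopf("sample filter removed all %d samples", length(drop))
  out <- dataset
  out$calls <- dataset$calls[!drop, , drop = FALSE]
  out$samples <- dataset$samples[!drop, , drop = FALSE]
  rownames(out$samples) <- NULL
  list(dataset = out,
       report = list(n_samples_in = length(drop),
                     n_samples_out = sum(!drop),
                     removed_sample_call_rate = sum(drop),
                     max_missing_rate = max_missing_rate,
                     removed_ids = dataset$samples$sample_id[drop]))
}

marker_stats <- function(dataset) {
  g <- dataset$calls
  n_called <- colSums(!is.na(g))
  call_rate <- n_called / nrow(g)
  p_b <- colSums(g, na.rm = TRUE) / (2 * pmax(n_called, 1L))
  maf <- pmin(p_b, 1 - p_b)
  n_aa <- colSums(g == 0L, na.rm = TRUE)
  n_ab <- colSums(g == 1L, na.rm = TRUE)
  n_bb <- colSums(g == 2L, na.rm = TRUE)
  data.frame(marker_id = dataset$map$marker_id, n_called = n_called,
             call_rate = call_rate, maf = maf,
             n_aa = n_aa, n_ab = n_ab, n_bb = n_bb)
}

#' Marker-level quality control
#'
#' Applies, in order: call-rate, minor-allele-frequency, autosome,
#' Hardy-Weinberg (exact test, pooled samples) and unknown-position
#' filters. Thresholds follow the conventions of PLINK-style SNP-array QC:
#' a marker is removed when its call rate is *below* `min_call_rate`, its
#' MAF is *strictly below* `min_maf` (a marker at exactly the threshold is
#' kept), its chromosome is not in `autosomes`, its pooled HWE exact p-value
#' is below `hwe_alpha`, or its position is unknown (chromosome `"0"` or
#' position 0). Allele frequencies and HWE are computed on all samples
#' pooled across breeds by default; `per_breed = TRUE` instead tests HWE
#' within each breed and removes a marker if it fails in any breed.
#'
#' @param dataset A [genotype_dataset()].
#' @param min_call_rate Minimum marker call rate (default 0.95).
#' @param min_maf Minimum minor allele frequency (default 0.05, strict).
#' @param autosomes Character vector of autosome labels (default
#'   `as.character(1:29)`, the goat autosomes).
#' @param hwe_alpha HWE exact-test significance level (default 0.001).
#' @param per_breed Test HWE/MAF within breeds instead of pooled
#'   (default `FALSE`).
#' @return List with elements `dataset` (filtered) and `report`
#'   (a `qc_report` list of per-filter removal counts and thresholds).
#' @export
filter_markers <- function(dataset, min_call_rate = 0.95, min_maf = 0.05,
                           autosomes = as.character(1:29), hwe_alpha = 0.001,
                           per_breed = FALSE) {
  st <- marker_stats(dataset)
  m <- nrow(st)

  fail_call <- st$call_rate < min_call_rate
  if (per_breed) {
    breeds <- unique(dataset$samples$breed)
    maf_b <- hwe_b <- matrix(NA_real_, m, length(breeds))
    for (j in seq_along(breeds)) {
      sub <- dataset
      keep <- dataset$samples$breed == breeds[j]
      sub$calls <- dataset$calls[keep, , drop = FALSE]
      sub$samples <- dataset$samples[keep, , drop = FALSE]
      stb <- marker_stats(sub)
      maf_b[, j] <- stb$maf
      hwe_b[, j] <- hwe_exact_test(stb$n_aa, stb$n_ab, stb$n_bb)
    }
    fail_maf <- apply(maf_b < min_maf, 1, any)
    fail_hwe <- apply(hwe_b < hwe_alpha, 1, any)
  } else {
    fail_maf <- st$maf < min_maf
    fail_hwe <- hwe_exact_test(st$n_aa, st$n_ab, st$n_bb) < hwe_alpha
  }
  fail_auto <- !(dataset$map$chromosome %in% autosomes)
  fail_pos <- dataset$map$position_bp == 0L | dataset$map$chromosome == "0"

  # attribute each marker to the first failing filter
  first_fail <- rep(NA_character_, m)
  for (f in c("call_rate", "maf", "non_autosomal", "hwe", "unknown_position")) {
    fl <- switch(f, call_rate = fail_call, maf = fail_maf,
                 non_autosomal = fail_auto, hwe = fail_hwe,
                 unknown_position = fail_pos)
    first_fail[is.na(first_fail) & fl] <- f
  }
  keep <- is.na(first_fail)
  if (!any(keep)) stopf("marker filters removed all %d markers", m)

  out <- dataset
  out$calls <- dataset$calls[, keep, drop = FALSE]
  out$map <- dataset$map[keep, , drop = FALSE]
  rownames(out$map) <- NULL

  counts <- table(factor(first_fail,
                         levels = c("call_rate", "maf", "non_autosomal",
                                    "hwe", "unknown_position")))
  report <- structure(list(
    n_markers_in = m, n_markers_out = sum(keep),
    removed_marker_call_rate = unname(counts[["call_rate"]]),
    removed_maf = unname(counts[["maf"]]),
    removed_non_autosomal = unname(counts[["non_autosomal"]]),
    removed_hwe = unname(counts[["hwe"]]),
    removed_unknown_position = unname(counts[["unknown_position"]]),
    thresholds = list(min_call_rate = min_call_rate, min_maf = min_maf,
                      autosomes = autosomes, hwe_alpha = hwe_alpha,
                      per_breed = per_breed)), class = "qc_report")
  list(dataset = out, report = report)
}

#' Full quality-control pass
#'
#' Convenience wrapper: [filter_samples()] followed by [filter_markers()],
#' returning the filtered dataset and a merged report.
#'
#' @inheritParams filter_samples
#' @inheritParams filter_markers
#' @return List with elements `dataset` and `report`.
#' @export
run_qc <- function(dataset, max_missing_rate = 0.1, min_call_rate = 0.95,
                   min_maf = 0.05, autosomes = as.character(1:29),
                   hwe_alpha = 0.001, per_breed = FALSE) {
  s <- filter_samples(dataset, max_missing_rate)
  mk <- filter_markers(s$dataset, min_call_rate, min_maf, autosomes,
                       hwe_alpha, per_breed)
  rep <- mk$report
  rep$n_samples_in <- s$report$n_samples_in
  rep$n_samples_out <- s$report$n_samples_out
  rep$removed_sample_call_rate <- s$report$removed_sample_call_rate
  rep$thresholds$max_missing_rate <- max_missing_rate
  list(dataset = mk$dataset, report = rep)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report\n")
  if (!is.null(x$n_samples_in))
    cat(sprintf("  samples: %d -> %d (removed %d, missing rate >= %.3g)\n",
                x$n_samples_in, x$n_samples_out, x$removed_sample_call_rate,
                x$thresholds$max_missing_rate))
  cat(sprintf("  markers: %d -> %d\n", x$n_markers_in, x$n_markers_out))
  cat(sprintf("    call rate < %.3g: %d\n", x$thresholds$min_call_rate,
              x$removed_marker_call_rate))
  cat(sprintf("    MAF < %.3g: %d\n", x$thresholds$min_maf, x$removed_maf))
  cat(sprintf("    non-autosomal: %d\n", x$removed_non_autosomal))
  cat(sprintf("    HWE p < %.3g: %d\n", x$thresholds$hwe_alpha, x$removed_hwe))
  cat(sprintf("    unknown position: %d\n", x$removed_unknown_position))
  invisible(x)
}

#' Flatten a QC report to a one-row data frame
#'
#' @param report A `qc_report` from [filter_markers()] or [run_qc()].
#' @return One-row data frame suitable for [write_tsv()].
#' @export
qc_report_table <- function(report) {
  data.frame(
    n_samples_in = report$n_samples_in %||% NA_integer_,
    n_samples_out = report$n_samples_out %||% NA_integer_,
    removed_sample_call_rate = report$removed_sample_call_rate %||% NA_integer_,
    n_markers_in = report$n_markers_in,
    n_markers_out = report$n_markers_out,
    removed_marker_call_rate = report$removed_marker_call_rate,
    removed_maf = report$removed_maf,
    removed_non_autosomal = report$removed_non_autosomal,
    removed_hwe = report$removed_hwe,
    removed_unknown_position = report$removed_unknown_position)
}
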