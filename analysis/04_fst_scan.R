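#!/usr/bin/env Rscript
# Stage 4: one-vs-rest Weir-Cockerham F_ST selection scans.
#
# For every breed: per-SNP theta against the pooled remaining breeds,
# negative values clamped to zero, 5-SNP centred moving average, regions
# called where the smoothed track exceeds the 95% quantile of the raw
# per-SNP distribution. The weakly drifted breeds are additionally
# rescanned with the exotic breed excluded from the complement, to check
# that the outgroup does not drive their signals.

library(breedscan)

ds <- read_plink("results/sim/panel_qc")
dir.create("results/fst", showWarnings = FALSE, recursive = TRUE)

breeds <- unique(ds$samples$breed)
summary_rows <- list()
for (br in breeds) {
  scan <- fst_scan(ds, br, window = 5L, quantile_level = 0.95)
  write_tsv(as.data.frame(scan$track),
            sprintf("results/fst/track_%s.tsv", br))
  write_tsv(as.data.frame(scan$regions),
            sprintf("results/fst/regions_%s.tsv", br))
  if (nrow(scan$regions) > 0)
    regions_to_bed(scan$regions, sprintf("results/fst/regions_%s.bed", br))
  summary_rows[[br]] <- data.frame(
    focal_breed = br,
    genome_mean_theta = attr(scan$track, "genome_mean_theta"),
    genome_theta_multilocus = attr(scan$track, "genome_theta_multilocus"),
    threshold_95 = attr(scan$regions, "threshold_used"),
    n_regions = nrow(scan$regions),
    max_ma_theta = max(scan$track$ma_theta, na.rm = TRUE))
  cat(sprintf("%-6s mean theta %.4f  multilocus %.4f  threshold %.4f  regions %d\n",
              br, summary_rows[[br]]$genome_mean_theta,
              summary_rows[[br]]$genome_theta_multilocus,
              summary_rows[[br]]$threshold_95, summary_rows[[br]]$n_regions))
}
write_tsv(do.call(rbind, summary_rows), "results/fst/scan_summary.tsv")

# rescan without the exotic outgroup
for (br in setdiff(breeds, "EXO")) {
  scan <- fst_scan(ds, br, exclude_breeds = "EXO")
  write_tsv(as.data.frame(scan$regions),
            sprintf("results/fst/regions_%s_noEXO.tsv", br))
}
cat("rescans excluding EXO written to results/fst/\n")
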