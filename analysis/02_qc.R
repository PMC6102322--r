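#!/usr/bin/env Rscript
# Stage 2: quality control.
#
# Sample filter (missing-call rate >= 0.10 removed, inclusive), then
# marker filters in order: call rate < 0.95, MAF < 0.05 (strict; pooled
# across breeds), non-autosomal, Hardy-Weinberg exact p < 0.001 (pooled),
# unknown position. Each marker is counted at the first filter that
# rejects it.

library(breedscan)

ds <- read_plink("results/sim/panel")
qc <- run_qc(ds)

print(qc$report)
write_tsv(qc_report_table(qc$report), "results/qc_report.tsv")
write_plink(qc$dataset, "results/sim/panel_qc", dialect = "bed")
cat(sprintf("retained %d/%d markers, %d/%d samples\n",
            qc$report$n_markers_out, qc$report$n_markers_in,
            qc$report$n_samples_out, qc$report$n_samples_in))
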