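#!/usr/bin/env Rscript
# Stage 1: build the synthetic six-breed study-scale dataset.
#
# One strongly drifted, inbred "exotic" breed (EXO: c = 0.2, autozygous
# fraction 0.138) against five weakly drifted "indigenous" breeds, 29
# autosomes, ~43,500 markers, one selective sweep injected on chromosome 1
# of EXO, 1% missing calls. Everything downstream reads the PLINK files
# written here; the ground truth goes alongside so each stage can be
# scored against it.

library(breedscan)

seed <- 2024L
out <- "results/sim"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = seed)
sim <- simulate_dataset(cfg)

cat("simulated dataset:\n")
print(sim$dataset)

write_plink(sim$dataset, file.path(out, "panel"), dialect = "bed")
write_tsv(sim$truth$tracts, file.path(out, "truth_tracts.tsv"))
write_tsv(sim$truth$autozygosity, file.path(out, "truth_autozygosity.tsv"))
write_tsv(sim$truth$breeds, file.path(out, "truth_breeds.tsv"))
write_tsv(sim$truth$frequencies, file.path(out, "truth_frequencies.tsv"))
write_tsv(as.data.frame(sim$truth$sweep), file.path(out, "truth_sweep.tsv"))

cat(sprintf("wrote PLINK fileset and truth tables to %s/\n", out))
cat(sprintf("sweep: breed %s, chr %s, %.1f-%.1f Mb -> freq %.2f\n",
            cfg$sweep$breed, cfg$sweep$chromosome,
            cfg$sweep$start_bp / 1e6, cfg$sweep$end_bp / 1e6,
            cfg$sweep$final_freq))
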