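#!/usr/bin/env Rscript
# Stage 3: pairwise IBS genomic similarity and breed-level means.
#
# Self-pairs are included in the within-breed averages, so the diagonal
# of the breed summary equals each breed's expected homozygosity.

library(breedscan)

ds <- read_plink("results/sim/panel_qc")
s <- sim_matrix(ds)
print(s)

bs <- breed_summary(s, ds)
cat("breed-by-breed mean similarity (diagonal = within):\n")
print(round(bs, 3))

write_tsv(data.frame(sample_id = rownames(s$sim), s$sim,
                     check.names = FALSE),
          "results/similarity_matrix.tsv")
write_tsv(data.frame(breed = rownames(bs), round(bs, 6),
                     check.names = FALSE),
          "results/similarity_breeds.tsv")
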