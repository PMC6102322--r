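#!/usr/bin/env Rscript
# Stage 6: candidate-gene annotation of the called selection regions.
#
# No real gene build ships with the package, so a synthetic gene model is
# generated here (uniformly placed intervals, ~15 genes per 10 Mb, sizes
# 5-150 kb) purely to exercise the overlap stage; region-gene pairs are
# reported whenever closed intervals intersect by at least 1 bp.

library(breedscan)

ds <- read_plink("results/sim/panel_qc")
set.seed(2024)
chrs <- unique(ds$map$chromosome)
genes <- do.call(rbind, lapply(chrs, function(ch) {
  len <- max(ds$map$position_bp[ds$map$chromosome == ch])
  n <- max(3L, round(len / 1e6 * 1.5))
  st <- sort(sample.int(len, n))
  data.frame(gene_id = sprintf("SYNGENE_%s_%03d", ch, seq_len(n)),
             chromosome = ch, start_bp = st,
             end_bp = pmin(st + sample(5e3:1.5e5, n, replace = TRUE), len),
             strand = sample(c("+", "-"), n, replace = TRUE))
}))
dir.create("results", showWarnings = FALSE)
write_tsv(genes, "results/synthetic_gene_models.tsv")

hits_all <- list()
for (f in list.files("results/fst", "^regions_[A-Z0-9]+\\.tsv$",
                     full.names = TRUE)) {
  br <- sub("^regions_(.*)\\.tsv$", "\\1", basename(f))
  regions <- read.delim(f)
  if (nrow(regions) == 0) next
  hits <- overlap_genes(regions, genes)
  if (nrow(hits) > 0) hits$focal_breed <- br
  hits_all[[br]] <- hits
  cat(sprintf("%-6s %d region(s), %d overlapping gene hit(s)\n",
              br, nrow(regions), nrow(hits)))
}
out <- do.call(rbind, hits_all)
write_tsv(out, "results/region_genes.tsv")
cat(sprintf("wrote %d region-gene pairs to results/region_genes.tsv\n",
            if (is.null(out)) 0L else nrow(out)))
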