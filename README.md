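# breedscan

Genome-wide characterisation of **selection signatures** and **runs of
homozygosity (ROH)** in multi-breed SNP-array genotype panels, built for
livestock diversity studies where a handful of breeds (often one
intensively selected exotic breed against several local ones) are
genotyped on a medium-density array.

## What it computes

For a PLINK-format panel (PED/MAP or BED/BIM/FAM) with a breed label per
sample, the package provides:

* **Quality control** — sample missingness (≥ 0.1 removed), marker call
  rate (< 0.95), MAF (< 0.05, strict), autosome restriction,
  Hardy–Weinberg exact test (Wigginton–Cutler–Abecasis, p < 0.001 on the
  pooled samples), unknown positions; each removed marker attributed to
  the first failing filter.
* **IBS genomic similarity** — for every ordered sample pair (self-pairs
  included) the fraction of the four allele pairs identical by state,
  averaged over shared non-missing markers; within-breed means equal the
  breed's expected homozygosity Σₐ p̂ₐ² for complete data.
* **Selection-signature scan** — per-SNP one-vs-rest Weir–Cockerham
  fixation index θ̂ = a/(a+b+c) (focal breed vs the pooled rest),
  negative values clamped to 0, a 5-SNP centred moving average
  (*ma*F_ST), and candidate regions called where the smoothed track
  strictly exceeds the empirical 95% quantile of the raw per-SNP
  distribution.
* **ROH and genomic inbreeding** — per-individual runs of ≥ 20
  consecutive homozygous markers spanning ≥ 2 Mb with no gap > 500 kb,
  ≤ 2 missing and 0 heterozygous calls; F_ROH = ROH-covered length /
  marker-covered autosome length, decomposed into 2–4, 4–8, 8–16 and
  > 16 Mb classes (short ≈ ancient, long ≈ recent inbreeding; a segment
  from an ancestor *g* generations back has expected length 100/(2*g*)
  Mb ≈ 2 Mb at *g* = 25).
* **Candidate-gene annotation** — closed-interval overlap of called
  regions with BED/GFF3 gene models.
* **A synthetic-data generator** — Balding–Nichols breed drift, injected
  selective sweeps, segmental autozygosity of configurable age and
  coverage, and missingness, with full ground-truth tables, so every
  stage of the pipeline can be scored against a known answer.

The methods, conventions and their rationale are described in
`vignettes/selection-and-roh.Rmd`.

## Worked example

```r
library(breedscan)

# a 3-chromosome, 4,500-marker, 144-sample six-breed panel with one
# drifted inbred breed ("EXO"), one sweep, and known autozygosity
sim <- simulate_dataset(sim_config(seed = 11,
  chrom_lengths_bp = setNames(rep(1e8, 3), as.character(1:3)),
  markers_per_chrom = 1500))

qc <- run_qc(sim$dataset)
print(qc$report)
#> QC report
#>   samples: 144 -> 144 (removed 0, missing rate >= 0.1)
#>   markers: 4500 -> 4425
#>     call rate < 0.95: 0
#>     MAF < 0.05: 15
#>     non-autosomal: 0
#>     HWE p < 0.001: 60
#>     unknown position: 0

scan <- fst_scan(qc$dataset, "EXO")   # wc_theta |> moving_average |> call_regions
head(as.data.frame(scan$regions), 3)
#>   chromosome start_bp   end_bp n_markers peak_ma_theta peak_marker_id
#> 1          1 59609968 60027793         3     0.4415077    snp_1_00888
#> 2          1 60231536 60231536         1     0.3341195    snp_1_00892
#> 3          1 60383328 60951182         9     0.5545325    snp_1_00899
```

The genome-wide mean per-SNP θ̂ for EXO is 0.085 (multi-locus estimate
0.100, matching the simulated differentiation of the drifted breed
against the pooled rest), the 95% threshold is 0.322, and the called
regions cluster around the sweep injected at 60–65 Mb on chromosome 1 —
the top peaks above sit exactly there.

```r
segs <- classify_segments(detect_roh(qc$dataset))
sm   <- summarize_roh(segs, qc$dataset)
data.frame(breed = sm$per_breed$breed, nROH = sm$per_breed$n_roh,
           N0 = sm$per_breed$n_0,
           F_ROH_pct = round(100 * sm$per_breed$f_roh_total, 2))
#>   breed nROH N0 F_ROH_pct
#> 1   EXO   78  0     12.46
#> 2  IND1    7 10      0.92
#> 3  IND2   26 12      1.12
#> 4  IND3   15 18      0.81
#> 5  IND4   22 13      1.04
#> 6  IND5   22 11      0.91
```

The inbred exotic breed carries ROH in every individual (N0 = 0) and a
mean F_ROH of 12.5%, against ~1% in the weakly inbred breeds — the
configured contrast (f = 0.138 vs 0.008–0.024) recovered from genotypes
alone.

## The analysis workflow

The `analysis/` directory chains the full study as numbered drivers, each
a thin script over the package functions, writing tables under
`results/`:

```sh
Rscript analysis/01_simulate.R   # study-scale six-breed fixture + truth
Rscript analysis/02_qc.R         # QC report, filtered panel
Rscript analysis/03_similarity.R # similarity matrix, breed summary
Rscript analysis/04_fst_scan.R   # per-breed tracks, regions, outgroup-excluded rescan
Rscript analysis/05_roh.R        # segments, per-individual/breed/chromosome summaries
Rscript analysis/06_annotate.R   # synthetic gene models, region-gene overlaps
```

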