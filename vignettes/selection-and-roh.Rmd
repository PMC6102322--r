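---
title: "Selection signatures and runs of homozygosity in multi-breed SNP panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selection signatures and runs of homozygosity in multi-breed SNP panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(breedscan)
```

# Scope and model

`breedscan` characterises two complementary footprints of selection and
population history in multi-breed SNP-array genotype panels:

* **between-breed differentiation** — a per-SNP one-vs-rest fixation-index
  scan, smoothed and thresholded into candidate selection-signature
  regions; and
* **within-individual autozygosity** — runs of homozygosity (ROH) and the
  genomic inbreeding coefficient $F_{ROH}$, decomposed by segment length
  into recent and ancient inbreeding.

Both analyses consume the same canonical object, a `genotype_dataset`:
an $n \times m$ matrix of B-allele dosages ($0, 1, 2$, `NA` for missing
calls) over a sorted marker map, with one breed label per sample, read
from and written to the PLINK text (PED/MAP) and binary (BED/BIM/FAM)
dialects.

## Fixation index

For a focal breed against the pooled complement, each marker gets the
two-population Weir–Cockerham (1984) variance-component estimator

$$\hat\theta = \frac{a}{a + b + c},$$

with the full finite-sample corrections including the observed
heterozygosity terms. A marker is undefined when either group has fewer
than two non-missing calls or the pooled marker is monomorphic. Negative
estimates imply no differentiation and are clamped to zero before
smoothing, matching standard practice in array-based selection scans.

Two genome-wide summaries are attached to every track, and they are not
interchangeable:

* `genome_mean_theta`, the mean of defined per-SNP clamped ratios. This
  is the convention used when a scan reports "the average $F_{ST}$ across
  all SNPs" for a breed, and it is what the package prints as a breed's
  average differentiation.
* `genome_theta_multilocus`, the ratio of summed components
  $\sum_k a_k / \sum_k (a_k + b_k + c_k)$. This is Weir & Cockerham's
  multi-locus estimator and is the quantity that is ratio-consistent for
  the underlying differentiation parameter. The mean of per-SNP ratios is
  Jensen-biased: on Balding–Nichols simulations the multi-locus estimate
  recovers the drift parameter $c$ across $c \in \{0.05, 0.1, 0.2\}$,
  while the per-SNP mean falls measurably short at $c = 0.2$. The
  package's parameter-recovery tests therefore score the multi-locus
  estimator, and the per-SNP mean is reported as a descriptive summary
  only.

Smoothing is an unweighted centred moving average of the clamped track
over `window = 5` adjacent markers of the same chromosome. Undefined
markers inside a window are skipped (the mean is over the defined values);
the $(window-1)/2$ markers at each chromosome end get no value, because a
truncated edge window would have inflated variance precisely where the map
ends. Window sums are computed per window rather than by
cumulative-sum differences to avoid rounding drift across a chromosome.

The region threshold is the empirical 95% quantile (type 7, linear
interpolation — the default of mainstream numeric stacks; no estimator is
canonical here) of the *raw* clamped per-SNP distribution over all defined
markers genome-wide, and the comparison is strict (`ma > threshold`,
"above" the quantile). Candidate regions are maximal runs of consecutive
above-threshold markers on one chromosome; no sub-threshold gap bridging
is performed. This is the most literal convention, and it is the main
reason region *counts* are not comparable across tools that merge nearby
windows. Region bounds are the positions of the run's first and last
markers (1-based inclusive internally; BED output converts to 0-based
half-open).

## Runs of homozygosity

An ROH is called when all of the following hold, mirroring stringent
array-based criteria that guard against false positives in regions of low
marker density:

| criterion | default |
|---|---|
| minimum consecutive markers | 20 |
| minimum physical length | 2 Mb |
| maximum inter-marker gap | 500 kb |
| maximum missing calls inside | 2 |
| heterozygous calls inside | 0 |

The 2 Mb minimum corresponds to autozygosity roughly 25 generations old:
an IBD segment from a common ancestor $g$ generations back is
approximately exponentially distributed with mean $100/(2g)$ cM, and at
the usual livestock approximation of 1 cM/Mb, `expected_roh_length(25)`
is 2 Mb. The length classes 2–4, 4–8, 8–16 (half-open on the right) and
>16 Mb separate ancient from recent inbreeding; 16 Mb is the expected
segment length at $g = 3$.

Because overlapping candidate stretches arise when missing calls are
scattered, the caller needs a deterministic tie-break. `detect_roh`
resolves candidates *leftmost-longest*: repeatedly keep the valid
sub-interval with the smallest start (ties broken by length) among those
not overlapping a kept segment. Segment endpoints must be homozygous
non-missing calls, so missing flanks cannot inflate lengths. The rule is
order-independent, and the implementation (a greedy sweep with two-pointer
budget tracking) is verified against an exhaustive $O(n^2)$ enumeration
of all valid sub-intervals on thousands of random genotype strings. Any
published ROH count obtained with an unpublished in-house tie-break can
differ by a few segments from this convention; totals and $F_{ROH}$ are
robust to it, exact segment counts are not.

$F_{ROH}$ divides each individual's summed ROH length by $L_{AUTO}$, the
summed per-chromosome span (max − min marker position) of the post-QC
map. Computing $L_{AUTO}$ from the data keeps the denominator consistent
with the marker panel actually analysed; `summarize_roh(l_auto_bp = )`
overrides it when replicating a published denominator. Class-wise
$F_{ROH}$ sums to the total exactly, per-breed summaries report the total
count `nROH`, mean per-individual coverage $S_{ROH}$ (Mb), mean segment
length, and $N_0$, the number of individuals with no ROH at all.

## Quality control

Samples with a missing-call fraction $\ge 0.1$ are removed first (the
threshold is inclusive; with clean array data this is usually vacuous).
Markers are then filtered in a fixed order — call rate $< 0.95$, MAF
$< 0.05$ (strict: a marker at exactly 0.05 is kept), non-autosomal
chromosome, Hardy–Weinberg exact-test $p < 0.001$, unknown position —
with each removed marker attributed to the first filter that rejects it,
so the per-filter counts sum exactly to the total removed. Allele
frequencies and HWE are computed on all samples pooled across breeds,
which is the single-pass convention of PLINK-style QC on multi-breed
panels; pooling breeds violates the HWE sampling model when
differentiation is strong (a Wahlund effect), which is why the threshold
is left loose at $10^{-3}$ and a `per_breed = TRUE` mode exists. The HWE
test is the Wigginton–Cutler–Abecasis exact test (two-sided, no mid-p —
the PLINK default), implemented with the stable ratio recurrence from the
modal heterozygote count and verified against direct enumeration of the
conditional distribution.

## Genomic similarity

The identity-by-state similarity of individuals $i, j$ averages, over
markers where both are called, the fraction of the four ordered allele
pairs that are identical by state. Two conventions matter:

* **Self-pairs are included** in within-breed averages. Under that
  convention (and only that one) the within-breed mean equals the breed's
  expected homozygosity $\frac{1}{m}\sum_k \sum_a \hat p_{a,k}^2$ exactly
  for complete data — an identity the test suite asserts to $10^{-12}$.
* **Missing data** uses a pairwise-complete denominator by default, so
  similarity stays a proper proportion per pair; `denominator = "all"`
  reproduces the literal fixed-denominator formula, which differs
  negligibly at post-QC missingness levels.

# The synthetic-data generator

`simulate_dataset` emulates the statistical structure of a multi-breed
50K goat panel so that every stage has a recoverable target:

* **Map**: 29 autosomes with lengths declining 155→45 Mb, ~1,500 markers
  per chromosome placed uniformly (defaults; all configurable).
* **Drift**: ancestral frequencies $p \sim U(0.1, 0.9)$; breed
  frequencies Balding–Nichols,
  $p_b \sim \mathrm{Beta}\!\big(p\tfrac{1-c}{c}, (1-p)\tfrac{1-c}{c}\big)$,
  with per-breed drift $c$. Defaults: one "exotic" breed at $c = 0.2$ and
  five "indigenous" breeds at $c = 0.05$, sized 13, 15, 29, 29, 29, 29 —
  the sample structure of a typical multi-breed diversity panel where one
  intensively selected outgroup faces several weakly structured local
  breeds.
* **Autozygosity**: per individual and chromosome, tracts arrive as a
  Poisson process with $\mathrm{Exponential}(100/(2g)\ \mathrm{Mb})$
  lengths, truncated at chromosome ends and merged; markers inside a
  tract are homozygous for a single haplotype draw. The Poisson intensity
  is calibrated (by solving the coverage-process integral) so the
  *expected realized* coverage equals the configured fraction $f$ despite
  truncation and overlap; realized per-individual fractions are recorded
  as truth. Defaults mirror a strongly inbred exotic breed
  ($f = 0.138$, $g = 10$) against weakly inbred locals
  ($f = 0.008$–$0.024$).
* **Sweep**: inside a configured interval the focal breed's frequencies
  move to a final value (default 0.95 on chromosome 1 of the exotic
  breed), with a linear 10-marker shoulder on each side so the signal
  decays rather than steps.
* **Missingness**: i.i.d. masking at rate 0.01.

Everything is deterministic given `seed` — the same seed yields
byte-identical PLINK and truth files.

What the generator does **not** emulate: linkage disequilibrium and
haplotype structure (markers are conditionally independent given breed
frequencies and tracts), genotyping error beyond missingness, ascertainment
bias of array content, sex chromosomes, and pedigree relationships within
breeds. Passing recovery tests on this generator therefore demonstrates
the estimators' correctness and calibration under drift, sweeps and
segmental autozygosity — not robustness to LD or array ascertainment on
real data.

# Numerical and design notes

* **PED allele canonicalisation.** The PED text dialect does not record
  allele order or unobserved alleles, so `read_plink` canonicalises PED
  alleles as sorted codes, and a marker with only one observed allele
  cannot be restored to its original coding. Round-trips are exact for
  markers where both alleles are observed, and always exact in the binary
  dialect, which stores A1/A2 explicitly.
* **Tied marker positions** are kept in input order with a warning;
  co-located markers are rare artefacts and no convention is canonical.
* **Degenerate scans.** If every raw value is equal, the threshold equals
  that value and the strict comparison calls no regions. Chromosomes with
  fewer markers than the smoothing window get no smoothed values, with a
  warning.
* **Class dominance across tract ages.** At $g = 3$ the >16 Mb class
  dominates $F_{ROH}$ and at $g = 25$ it is negligible, with short
  classes dominating — the directional contrast the length classes exist
  for. The finer claim that the 2–4 Mb bin specifically dominates at
  $g = 25$ is *not* robust: the length-biased exponential places nearly
  equal coverage mass in 2–4 and 4–8 Mb (analytically ≈1.32 vs ≈1.26),
  and detected segments extend past true tract boundaries to the first
  heterozygous marker, which tips the balance towards 4–8 Mb. The tests
  assert the robust contrast only.
* **Short-tract under-detection.** At $g = 25$ most tracts are shorter
  than the 2 Mb / 20-marker minima, so $F_{ROH}$ systematically
  under-reports the simulated autozygous fraction for old inbreeding;
  recovery tests use $g = 3$, where marker resolution is the only loss
  and per-breed recovery lands within a few percent.

# Problem sizes

The test suite and the acceptance script are sized for a single CPU:
oracle-equivalence suites run on strings of ≤200 markers (1,000 cases)
and random count tables; recovery experiments use two breeds × 30 samples
× 5,000 markers for drift, 100 replicates of a 3-chromosome two-breed
panel for sweep localisation, and a six-breed panel of 2 × 3,000 markers
for $F_{ROH}$; the end-to-end workflow fixture is the full 29-chromosome,
~43,500-marker, 144-sample configuration. These sizes were chosen so each
property is measured well clear of its tolerance while the whole suite
stays desk-scale.

# Limitations

Haplotype-based statistics (hapFLK and relatives), LD-aware simulation,
ROH islands/consensus regions across individuals, VCF ingestion, sex
chromosomes and enrichment analyses are out of scope. Region counts
depend on the no-gap-bridging convention documented above; cross-tool
comparisons should use thresholds and overlaps, not counts.
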