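Package: breedscan
Title: Selection Signatures and Runs of Homozygosity in Multi-Breed SNP Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genome-wide characterization of selection signatures
    and inbreeding in multi-breed SNP-array genotype panels. Reads and writes
    PLINK PED/MAP and BED/BIM/FAM files, applies standard marker- and
    sample-level quality control (call rate, minor allele frequency,
    Hardy-Weinberg exact test, autosome restriction), computes pairwise
    identity-by-state genomic similarity, scans the genome with a one-vs-rest
    Weir-Cockerham fixation index smoothed by a moving average and calls
    selection-signature regions above an empirical quantile threshold,
    detects runs of homozygosity per individual under sliding criteria
    (marker count, physical length, gap, missing calls) and derives the
    genomic inbreeding coefficient F_ROH with length-class decomposition,
    annotates called regions with overlapping gene models, and simulates
    multi-breed genotype data under the Balding-Nichols drift model with
    injected selective sweeps and segmental autozygosity so that every
    pipeline stage has a recoverable ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
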