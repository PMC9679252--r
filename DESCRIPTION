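Package: poolscan
Title: Kernel-Smoothed Divergence Scans for Pooled Whole-Genome Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of Pool-Seq allele-frequency data along a genome:
    per-SNP Nei F_ST and absolute divergence d_XY between superpools,
    Gaussian kernel-smoothed moving weighted averages in overlapping
    sliding windows, bootstrap null distributions with Benjamini-Hochberg
    false-discovery-rate control, calling of genomic islands of
    differentiation, pooled nucleotide diversity and Tajima's D per
    window, Lin's concordance correlation for replicate pools,
    gene-annotation overlap for called islands, and tabulation of
    environmental-association Bayes-factor outliers. Includes a
    Balding-Nichols based synthetic Pool-Seq generator with ground-truth
    records for validating the scan end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
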