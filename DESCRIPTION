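Package: temposcan
Title: Selection-Signature Scanning in Serial Genotype Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects genomic signatures of sustained directional selection by
    direct comparison of SNP-array genotypes from cohorts sampled at different
    points along a breeding timeline. Implements per-SNP allele-frequency
    difference (AFD) and expected-heterozygosity difference (HD) tracks with
    empirical random-AFD threshold calibration, sliding-window long-range
    statistics standardized per chromosome (Z_AFD, Z_HD) with peak-and-extend
    signature calling, extended haplotype homozygosity (EHH) profiles and decay
    distances around core haplotypes, identity-by-state distances with classical
    multidimensional scaling of cohort structure, and signature-conditioned
    correlations between per-SNP trait effects. A Wright-Fisher forward
    simulator generates serial cohorts with implanted sweeps so every stage of
    the pipeline can be validated against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    vcfR,
    rtracklayer,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
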