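Package: tropiscan
Title: Haplotype-Based Selection Scans and Introgression Analysis for
    Phased Variant Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for detecting recent positive selection and quantifying
    donor-population introgression in closely related diploid populations
    from phased biallelic variant data.  Implements extended haplotype
    homozygosity statistics (EHH, EHHS, iHH, iES) with a compiled scan
    kernel, the cross-population Rsb and within-population iHS scans, a
    genome-wide label-permutation significance procedure with top-window
    selection and control-pair exclusion, windowed Watterson theta and
    Hudson F_ST with missing-data-aware estimators, local-ancestry dosage
    summaries with rank-based enrichment tests, consequence and
    position-weight-matrix (PWM) based regulatory annotation of candidate
    variants, and a deterministic synthetic-data generator (Balding-Nichols
    allele frequencies, block-copying haplotypes, implanted sweeps and
    introgression tracts) with exact ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    withr,
    vcfR,
    Biostrings,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
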