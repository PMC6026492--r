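Package: vitiscan
Title: Genome Scans for Domestication Signatures in Grapevine SNP Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for comparing wild (Vitis vinifera subsp.
    sylvestris) and cultivated (subsp. sativa) grapevine from SNP genotype
    panels: platform merging, call-rate and minor-allele-frequency filtering,
    LD-kNN genotype imputation, sliding-window Weir-Cockerham F_ST with
    permutation-calibrated outlier thresholds, nucleotide diversity and
    Tajima's D, linkage-disequilibrium decay profiling, PCA-based
    stratification, kinship, mixed-model association mapping for
    domestication traits, and intersection of association hits with
    selection signatures.  A synthetic-data generator with planted sweeps
    and QTLs provides ground truth for calibration and recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    ape,
    lme4,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
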