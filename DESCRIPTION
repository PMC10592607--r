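Package: cascadeQTL
Title: Multi-Omics cis-QTL Mapping and Central-Dogma Cascade Analysis
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps cis quantitative trait loci (QTLs) independently on mRNA,
    ribosome-occupancy and protein quantification layers measured on the same
    cohort, quantifies how genetic effects on transcription attenuate through
    translation to protein (Storey pi1 replication matrices, direction-aware
    replication curves, external-eQTL aggregate effect profiles), detects
    omics-specific QTL genes by conditional elastic-net imputation with a
    permutation-calibrated squared imputation correlation, and classifies
    candidate disease risk genes through a Bayesian colocalization /
    summary-statistic transcriptome-wide association / Mendelian randomization
    cascade. Ships a generative simulator of genotypes, a three-layer molecular
    cascade with known attenuation structure, and GWAS summary statistics, so
    every stage is testable against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    limma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
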