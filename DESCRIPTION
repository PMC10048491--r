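Package: herdgwas
Title: Whole-Genome Association Analysis for Milk Traits in Structured Cattle Herds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for genome-wide association studies of
    305-day milk production traits (milk, fat and protein yield and content) in
    small, strongly structured dairy cattle populations. Covers cohort and
    variant quality control, identity-by-state relatedness clustering with a
    pairwise population concordance constraint, delta-AIC fixed-effect
    selection, per-variant fixed-effects linear regression, genomic-control
    rescaling of inflated test statistics toward a target lambda, significance
    thresholds from LD-pruned effective test counts, two-stage QTL region
    definition, genomic-relationship-matrix REML heritability, and a
    structured-population genotype/phenotype simulator with known ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    vcfR,
    readr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    GenomicRanges,
    S4Vectors,
    jsonlite,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
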