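Package: genoprev
Title: Recessive-Disease Genetic Prevalence from Population Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Estimates the genetic prevalence of an autosomal recessive disease
    from population sequencing cohorts. Intersects a cohort VCF with a catalog
    of reported pathogenic variants, computes ancestry-stratified allele
    frequencies, applies the ACMG frequency-based evidence rules (BA1, BS1,
    PM2) with detection of conflicts against asserted classifications, and
    derives Hardy-Weinberg carrier and affected rates under variant
    inclusion/exclusion scenarios. Ships a seeded synthetic-cohort generator
    (VCF, sample panel, variant catalog, external frequency table) so the full
    pipeline is reproducible without restricted-access data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
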