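Package: gwamaqc
Title: Across-Cohort Quality Control for GWAS Meta-Analysis Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quality-control metrics for genome-wide association meta-analysis
    (GWAMA) computed from cohort-level summary statistics alone. Implements
    Fst-based genetic-distance profiling of cohorts against reference panels
    with a two-dimensional "cartographer" projection, principal component
    analysis over cohorts using reported allele frequencies (meta-PCA), the
    lambda_meta statistic for detecting sample overlap or heterogeneity
    between cohort pairs together with its transformation to an effective
    overlapping sample count, and pseudo profile score regression (PPSR) for
    pinpointing duplicate individuals and close relatives across cohorts
    without sharing genotypes. Includes a Balding-Nichols simulator of
    multi-cohort GWAS experiments with configurable heritability, sample
    overlap and relatedness, and a command-line interface wiring the metrics
    into a QC workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    optparse,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
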