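Package: agingproteome
Title: Differential Abundance, Enrichment, Turnover and Lifespan Analysis
    for Aging Proteomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for quantitative proteomics studies of aging
    built around replicate log2 heavy/light ratio tables. Identifies proteins
    that change abundance between two ages with the rank-product statistic and
    a permutation estimate of the proportion of false predictions (PFP),
    computes set-level statistics (Fisher fold enrichment over expectation,
    Kolmogorov-Smirnov distribution-shift tests, permutation gene set
    enrichment, cross-study direction concordance), clusters developmental
    stage expression with correlation distance to extract adult-specific
    proteins, estimates protein half-lives and synthesis rates from
    photoconvertible-reporter timecourses, and compares lifespans with
    Kaplan-Meier curves and the log-rank test. Includes seeded synthetic-data
    generators with planted ground truth for every input type, plain-text
    readers and writers, and a reproducibility manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    survival
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
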