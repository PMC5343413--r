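Package: trioDNM
Title: De Novo Mutation Discovery and Statistical Evidence from Exome Trios
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects candidate de novo mutations (DNMs) in parent-offspring
    exome trios from multi-sample VCFs using explicit depth, genotype-quality
    and allele-fraction filters, ranks call confidence from base quality and
    strand bias, flags post-zygotic mosaics, and classifies functional
    consequences. Provides the statistical evidence layer for small trio
    cohorts: Poisson modelling of per-trio DNM counts with an exact
    Kolmogorov-Smirnov goodness-of-fit, exact conditional binomial rate
    comparisons against reference cohorts, per-gene expected-rate
    over-representation tests, carrier-collapsing (CMC) rare-variant burden
    tests with sample-size-weighted Z-score meta-analysis, and rule-based
    CNV/ROH calling from SNP-array log R ratio tracks. Includes seeded
    simulators for trio cohorts, case/control genotype matrices and probe
    tracks so every stage can be validated against planted truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
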