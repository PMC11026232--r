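Package: triptanscore
Title: Genetic and Clinical Profiling of Triptan Usage in Cluster Headache Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for candidate-gene pharmacogenetics of triptan
    usage in cluster headache: tri-allelic 5-HTTLPR/rs25531 genotype calling from
    PCR-RFLP restriction-fragment band patterns, per-variant allelic association
    under an additive logistic model with Bonferroni correction, an unweighted
    cumulative genetic effector score with covariate-adjusted logistic regression,
    clinical-feature comparison between usage groups, and a detectable odds-ratio
    power solver for case-control allelic tests. Includes a seeded synthetic
    cohort generator emulating the genotype-phenotype structure of a cluster
    headache biobank so that every stage is testable without individual-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
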