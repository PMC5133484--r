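Package: bpsimr
Title: Pedigree-Based Simulation of Longitudinal Blood-Pressure Phenotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable simulation engine for family and population studies of
    blood pressure. Given genotypes (real, from VCF, or gene-dropped through a
    pedigree), a pedigree-derived or SNV-based empirical kinship matrix, and an
    effect-model configuration, the package generates replicated longitudinal
    bivariate systolic/diastolic blood-pressure phenotypes with sequence-variant
    effects sized from PolyPhen-2 scores and expression-trait genetic
    correlations, kinship-structured polygenic residuals, age and sex covariate
    effects, an antihypertensive-medication effect with a
    genotype-by-medication interaction, and a heritable null trait for type-I
    error benchmarking. Also provides the companion variant quality-control
    filters (call rate, exact Hardy-Weinberg test, differential call rate) and
    the expression-array processing pipeline (sample QC, exact binomial probe
    detection test, false-discovery-rate filtering, min-shift log2 transform
    and quantile normalization).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    vcfR,
    limma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
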