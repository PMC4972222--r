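Package: markerQG
Title: Marker-Based Quantitative Genetics for Clonal Plant Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: In-situ quantitative genetics from codominant SSR (microsatellite)
    genotypes in clonal plant populations. Reads and summarizes diploid
    genotype tables (GENEPOP and delimited formats), identifies clonal
    replicates by Lynch band-sharing distance and computes the multilocus
    probability of identity, estimates pairwise relatedness with the
    Queller-Goodnight, Li, Lynch-Ritland and Wang moment estimators,
    conditions relatedness matrices for mixed-model use (unit diagonal,
    nearest positive-definite projection), and fits REML animal models with
    a marker-inferred relatedness matrix to obtain additive genetic
    variances, narrow-sense heritabilities with delta-method confidence
    intervals, and genetic covariances (G matrix). Also derives snowmelt
    phenology traits from soil-temperature logger series (snowmelt day,
    growing-degree days) and fits standardized-trait performance
    regressions with nested random effects across snowmelt microhabitats.
    A synthetic-data generator with known pedigree ground truth makes the
    whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    nlme
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'genotype-io.R'
    'clonal-id.R'
    'relatedness.R'
    'animal-model.R'
    'phenotypes.R'
    'performance-models.R'
    'synthetic-data.R'
    'pipeline.R'
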