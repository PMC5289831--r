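Package: phenodim
Title: Two-Stage Analysis of Rare-Event Categorical Phenotypes and
    Sexual Dimorphism
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Statistical pipeline for high-throughput categorical
    phenotyping screens where abnormal outcomes are rare and cohorts are
    small (typically seven knockout animals per sex). Stage 1 tests for a
    genotype effect with exact conditional tests (Fisher, stratified
    Cochran-Mantel-Haenszel) with optional mid-P correction, or Firth
    bias-reduced logistic regression; stage 2 tests for a genotype-by-sex
    interaction (sexual dimorphism) among stage-1 discoveries. Hypotheses
    that cannot attain significance given their margins are removed by
    minimum-attainable-P ("alpha star") filters before multiplicity
    control by Benjamini-Hochberg or the Benjamini-Bogomolov within-family
    procedure. Effect sizes are differences in abnormality proportions
    with Newcombe method-10 confidence intervals. Includes simulation
    machinery for type-I error and power assessment of the whole workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
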