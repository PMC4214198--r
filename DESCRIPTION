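Package: minitwin
Title: Environmental and Genetic Analysis of Infant Salivary Testosterone in Twin Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing hormone phenotypes in infant twin/singleton
    cohorts during the post-natal activation of the
    hypothalamic-pituitary-gonadal axis ("minipuberty"). Implements
    adaptive-Lasso fixed-effect selection in family-clustered linear mixed
    models with a feasible-GLS initial estimator and BIC tuning, cluster
    bootstrap stability assessment, twin intraclass correlations and ACE
    variance decomposition with boundary-respecting one-tailed tests,
    candidate-SNP mixed-model association scans with likelihood-ratio tests
    and false-discovery-rate control, twin-structured Monte-Carlo power
    simulation, and residualized random-forest stability selection. A
    synthetic twin-cohort generator with Mendelian genotype transmission and
    an additive-genetic/shared-environment/unique-error phenotype model makes
    every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    ranger
Suggests:
    testthat (>= 3.0.0),
    lme4,
    glmnet,
    vcfR
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
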