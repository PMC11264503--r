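Package: fetalgrs
Title: Maternal Polygenic Risk and Fetal Growth Across the Ancestry Continuum
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to study how a maternal type-2-diabetes genetic risk score
    relates to longitudinal fetal growth and birthweight in multi-ancestral
    cohorts, stratified along the continuum of genetic ancestry rather than by
    discrete race/ethnicity labels. Implements weighted risk scores from
    effect-allele dosages, per-anchor PCA-projection genetic distance to
    reference panels, supervised admixture EM ancestry proportions, sliding
    window LD pruning, Hadlock estimated fetal weight, linear mixed-model
    growth trajectories with cubic-spline mean and cubic-polynomial random
    effects, and per-gestational-week stratified and interaction association
    models. A fully specified synthetic-cohort generator with known ground
    truth makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    MASS,
    lme4,
    splines,
    vcfR,
    yaml,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
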