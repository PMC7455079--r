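Package: slestrat
Title: Whole-Blood Transcriptomic Stratification of SLE Heterogeneity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for stratifying systemic lupus erythematosus (SLE) patients
    from whole-blood transcriptomes: per-sample gene-module enrichment scoring
    by a kernel-CDF, Kolmogorov-Smirnov-like random-walk statistic;
    healthy-control-referenced trichotomization of module scores into
    increased/normal/decreased signature calls; empirical-Bayes moderated
    differential expression with randomized-split null controls and
    Fisher's-exact gene-list overlap; a 26-binary-predictor stepwise logistic
    odds-ratio framework with Spearman collinearity screening,
    Hosmer-Lemeshow calibration gating and interval-graph odds-ratio edge
    mapping; penalized-logistic ancestry classification with stratified
    cross-validation and ROC/AUC; transcriptome-based sex inference; and a
    synthetic-cohort generator that emulates the statistical structure of a
    large multi-ancestry SLE trial population so the whole pipeline is
    testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    tibble,
    glmnet,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
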