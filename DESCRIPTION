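Package: LipoPheno
Title: Lipoprotein-Based Phenotyping of Sepsis Cohorts
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Unsupervised derivation and cross-cohort replication of
    lipoprotein-based sepsis phenotypes. Patients are clustered by Ward
    agglomeration on Spearman-correlation distance between z-scored
    biomarker profiles, yielding Hypolipoprotein and Normolipoprotein
    phenotypes; a per-feature t-test signature with stored scaling
    parameters is projected onto independent cohorts; cluster membership
    is related to rapid recovery, chronic critical illness and early
    death, compared against SOFA and APACHE II by ROC analysis, and
    outcome predictors are selected by cross-validated LASSO logistic
    regression. A configurable correlated log-normal cohort simulator
    with planted two-phenotype structure supports end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    Matrix,
    MASS,
    glmnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    pROC,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Clustering, Classification, ImmunoOncology, Software
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'LipoPheno-package.R'
    'cohort.R'
    'clinical.R'
    'clustering.R'
    'cohort-io.R'
    'outcome-stats.R'
    'simulate.R'
    'preprocess.R'
    'signature.R'
    'pipeline.R'
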