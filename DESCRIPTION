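Package: phenomap
Title: Comparative COPD Phenotyping on Paired Inspiratory-Expiratory CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for comparative phenotyping of chronic
    obstructive pulmonary disease (COPD) on paired inspiratory and
    registered expiratory chest CT. Implements voxel-wise parametric
    response mapping (PRM) into normal, functional small-airway disease
    (fSAD) and emphysema classes; overlapping 3D patch extraction with
    fixed-length patch featurization; density-based regional anomaly
    scoring by negative log-likelihood against a reference of healthy
    lung regions; latent-structure analysis with Horn's parallel
    analysis, mini-batch k-means and Gaussian-mixture clustering with
    multi-metric model selection, and t-SNE visualization; and the
    cohort statistics layer (Jonckheere-Terpstra trend tests, Tukey
    post-hoc comparisons, bootstrap Pearson confidence intervals, Zou
    comparison of dependent overlapping correlations, Holm-Bonferroni
    adjustment, linear mixed models with likelihood-ratio tests and
    adjusted conditional R-squared, and regression-based Bland-Altman
    limits of agreement). A synthetic paired-CT cohort generator with
    known voxel-level ground truth drives testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    RNifti,
    mclust,
    lme4,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    cluster,
    withr
Config/testthat/edition: 3
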