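Package: neurovar
Title: Intra-Person Across-Test Cognitive Variability and Risk Profiling
    for Aging-Cohort Baselines
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for baseline analyses of healthy-aging cohorts that
    combine clinical risk profiling, neuropsychology and brain volumetry.
    Implements composite cardiovascular and cognitive risk scores from raw
    clinical fields, the intra-person across-neuropsychological-test
    variability statistic V (the sample standard deviation of one subject's
    z-scores across a test battery), total-intracranial-volume normalised
    brain volumes with white-matter-lesion aggregation by anatomical class,
    and the accompanying inference toolkit: exhaustive predictor-subset
    regression selected by leave-one-out cross-validated bias-corrected
    RMSE, Spearman and partial correlations, age-residualised median-split
    group comparisons and Holm step-down multiplicity correction.  A
    calibrated synthetic cohort generator with latent ground truth makes
    every pipeline stage testable without access to subject-level data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
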