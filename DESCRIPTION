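Package: mskmark
Title: Mask-to-Decision Quantitative Biomarkers for Musculoskeletal MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts multi-label musculoskeletal MRI segmentation masks into
    standardized quantitative imaging biomarkers (medial-axis cartilage and
    meniscus thickness, intervertebral disc height, tissue volume, parametric
    relaxometry means) and drives two decision layers built on them: a
    specificity-targeted multi-stage triage cascade with workload accounting,
    and landmark-time risk models with isotonic calibration, decision-curve
    analysis and survival comparators. Includes an assumption-gated agreement
    framework (Shapiro-Wilk/Levene screening, two-way ICC with parametric or
    bootstrap mixed-effects intervals, Bland-Altman limits, OLS or Gaussian
    process regression, Spearman correlation, Benjamini-Hochberg control),
    overlap metrics with paired non-parametric model comparison, standardized
    mask refinement, NIfTI/CSV/YAML input-output, and a phantom and cohort
    simulator with analytically known ground truth so every component is
    testable without imaging data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    yaml,
    jsonlite,
    glmnet,
    xgboost,
    ranger,
    survival,
    lme4,
    car,
    kernlab,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    EBImage,
    pROC
Config/testthat/edition: 3
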