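Package: serocluster
Title: Autoantibody Serology Profiling and Ratio-Based Patient Clustering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for quantitative autoantibody serology panels
    measured in light units (LU), as produced by luciferase immunoprecipitation
    (LIPS) assays. Calibrates per-antigen seropositivity cutoffs from healthy
    controls (mean plus three standard deviations), computes control-referenced
    Z-scores, evaluates single-antigen and panel diagnostic performance
    (including ROC-optimal cutoffs by Youden's J), and segregates systemic
    lupus erythematosus patients into Sm/RNP and Ro/La autoantibody clusters by
    the relative-ratio rule on trio titer sums. Includes exact association
    tests (Fisher, Mann-Whitney, Spearman, log-titer t-test), reconstruction
    of contingency tables from printed percentages, a six-antigen mixture-assay
    model, a synthetic-cohort generator with latent cluster structure for
    validation, and Z-score heatmap reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, grDevices, yaml
Suggests: testthat (>= 3.0.0), jsonlite, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
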