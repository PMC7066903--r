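Package: megdmn
Title: Resting-State MEG Default Mode Network Connectivity Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for resting-state magnetoencephalography (MEG) analysis of the
    default mode network (DMN): synthetic coupled-envelope cohort simulation,
    artifact preprocessing (notch filtering, PCA-based signal-space projection),
    depth-weighted minimum-norm source estimation, Welch relative band power,
    amplitude envelope correlation (AEC) networks with graph node strength, group
    statistics (ANOVA with FDR correction, Bonferroni edge tests, one-tailed
    Spearman correlation), and ROC discrimination of subjective cognitive decline
    (SCD) from healthy controls.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
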