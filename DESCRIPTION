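Package: psylikeness
Title: Neuromonitoring of Psychosis-Likeness Change from Resting-State
    Connectivity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds a repeated nested cross-validated, class-weighted linear
    support vector machine separating healthy controls from recent-onset
    psychosis patients on resting-state functional connectivity vectors,
    applies the frozen model ensemble out-of-sample to paired baseline and
    follow-up scans to quantify per-subject psychosis-likeness change across
    the decision hyperplane, and relates that change to sensory-processing
    subgroups and cognitive gains with the accompanying statistical battery
    (pooled t, chi-square, mixed-design ANOVA, ANCOVA, paired t with Cohen's
    d, Benjamini-Hochberg FDR). Includes a synthetic cohort generator
    producing ROI time series with group-specific covariance structure,
    nuisance signals, motion, longitudinal hyperplane shifts and correlated
    behavioral outcomes, plus the connectivity preprocessing chain
    (Friston-24 expansion, framewise displacement, band-pass filtering,
    nuisance regression, Pearson connectomes).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    signal,
    MASS,
    car,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    rlang,
    withr,
    yaml
Config/testthat/edition: 3
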