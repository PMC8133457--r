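Package: lingmark
Title: Linguistic Markers of Depression, Anxiety and Suicidal Ideation in
    Longitudinal Blog Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline linking per-fortnight linguistic feature
    scores extracted from blog text (LIWC percent-of-words categories) to
    concurrent self-reported depression (PHQ-9), anxiety (GAD-7) and
    suicidal-ideation scores. Provides mass bivariate Spearman screening
    with max-statistic permutation control of the family-wise error rate
    and bootstrap confidence intervals; partial least squares regression
    with cross-validated component selection, bootstrap-z feature
    selection and restricted-model refitting; and a within-subject test
    of whether group-level models generalise to individual symptom change
    over time. A synthetic-cohort generator with configurable
    between-subject effect structure and an ergodicity knob makes every
    stage testable without participant data.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    mixOmics,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
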