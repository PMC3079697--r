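Package: actiq
Title: Measurement Properties of Physical-Activity Questionnaires and
    Accelerometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying the measurement properties of 7-day recall
    physical-activity questionnaires against hip-worn accelerometry in
    clinical cohorts. Scores the Activity Questionnaire for Adults and
    Adolescents (AQuAA; MET*min/week total score and intensity-band
    minutes) and the Physical Activity Scale for the Elderly (PASE;
    weighted sum score), processes 15-second accelerometer epoch streams
    into wear time, Freedson intensity bands and weekly summaries,
    and computes test-retest reliability (one-way intraclass correlation
    with exact F confidence intervals, standard error of measurement,
    smallest detectable difference, distinguishable steps) and
    construct-validity statistics (Spearman correlation, agreement
    intraclass correlation, activity-guideline compliance). A calibrated
    synthetic-cohort generator with known variance components and
    questionnaire-accelerometer coupling makes the whole pipeline testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
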