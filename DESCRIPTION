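Package: qiatr
Title: Scoring and Psychometric Evaluation of Questionnaire-Based
    Implicit Association Tests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for building, administering plans for, scoring and
    psychometrically evaluating questionnaire-based Implicit Association
    Tests (qIATs), with the Level of Personality Functioning Scale qIAT
    (LPFS-qIAT) shipped as a packaged instrument. Includes the seven-block
    instrument model with counterbalancing, a canonical trial-level data
    format, the improved D-score cleaning and scoring algorithm with both
    the D600 and built-in-error-penalty error-handling schemes, parcel-based
    internal consistency (Cronbach's alpha variant), split-half and
    bootstrap test-retest reliability, percentile-bootstrap Pearson
    correlation confidence intervals, minimum detectable effect size
    sensitivity analysis, and a generative respondent simulator for
    end-to-end validation with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
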