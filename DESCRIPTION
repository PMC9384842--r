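Package: tvfb
Title: Scoring, Norming and Psychometrics for a Telephone-Based Verbal
    Fluency Battery
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Standardization toolkit for a telephone-administered verbal
    fluency battery (phonemic, semantic and alternate fluency, nine
    60-second trials). Scores batteries and the Composite Shifting Index;
    derives demographically adjusted norms with nonparametric tolerance
    limits and Equivalent-Score bands; runs paired two-one-sided-tests
    (TOST) equivalence analyses and the matching design-stage sample-size
    calculators; computes reliability and validity psychometrics
    (intraclass correlations, Cronbach's alpha, principal-component
    structure, ROC/AUC with Hanley-McNeil standard errors); scores word
    streams for semantic clusters and switches; and simulates stratified
    normative cohorts so the whole pipeline is testable without raw
    participant data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    MASS,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
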