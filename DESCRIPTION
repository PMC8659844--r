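Package: cohortcoach
Title: Coaching Analytics for Older-Adult Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analytics engine for virtual-coaching programs in older-adult
    cohorts. Scores daily coaching-questionnaire activity per coaching
    dimension (Physical, Cognitive, Social, Nutritional) as a weighted sum of
    encoded answers, groups participants by weighted Manhattan similarity on
    robustly standardized baseline assessments using average-linkage
    hierarchical clustering, and relates in-program activity to pre/post
    assessment change with moving-window trajectory smoothing and
    improvement color coding. Includes a synthetic cohort generator with
    exported ground truth so every stage is testable without study data, a
    report pipeline with static chart exports, and System Usability Scale
    (SUS) scoring utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
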