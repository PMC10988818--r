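Package: petrelwind
Title: Movement, Windscape and Foraging-Niche Segregation Analysis for
    Sympatric Seabirds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for quantifying how two sympatric,
    allochronically breeding seabird species partition their foraging
    niche, built around central-place foraging tracks and gridded wind
    fields. Provides wind-relative track annotation (delta-angle and
    tail-wind component), two-state hidden Markov behavioural decoding
    (gamma step lengths, von Mises turning angles, Viterbi), seasonal
    kernel utilization distributions and core-area overlap under a
    breeding-phenology shift, boosted-regression-tree habitat preference
    with pseudo-absences, gamma smooth models of ground speed against
    wind, and a track-swap/season-swap simulation of flight performance.
    A synthetic-world generator with known ground truth supports
    end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    geosphere,
    ggplot2,
    jsonlite,
    lubridate,
    mgcv,
    pROC,
    purrr,
    readr,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
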