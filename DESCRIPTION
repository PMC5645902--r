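Package: dhsi
Title: Construction of a Depression Health State Index from Healthcare Event Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a continuous 0-100 Depression Health State Index (DHSI)
    from longitudinal primary-care event records. Derives depressive episodes
    anchored at incident antidepressant prescriptions, detects 29 binary
    clinical parameters over baseline and follow-up windows, aggregates them
    with a lexicographic base-6 weighting into positive and negative
    pre-scores, merges dual rankings and normalizes to 0-100, then distills
    the index into a linear model augmented with regression-tree-discovered
    interaction terms and evaluates it on a held-out split. Includes a
    synthetic event-stream and parameter-matrix generator so the whole
    pipeline is exercisable without access to any proprietary database.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    knitr,
    optparse,
    readr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
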