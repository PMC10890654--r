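Package: pacemetrics
Title: Pacing Variability Metrics for Multi-Stage Long-Distance Running
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes commonly used pacing variables (coefficient of
    variation, change in mean speed, change from first-lap speed, absolute
    change in mean speed, pace range, mid-race split and the 32-10 km
    split) from per-lap marathon split times, classifies per-race pacing
    profiles by linear regression of lap speed on lap index, and evaluates
    the variables' test-retest reliability (repeated-measures ANOVA,
    standard error of measurement, typical-error coefficient of variation,
    intraclass correlation with confidence intervals), concurrent validity
    and sensitivity across the days of a multi-stage race. Includes a
    seeded synthetic-cohort generator that emulates the statistical
    structure of multi-day loop-course marathon data, and a single-call
    pipeline that writes the full tabular report bundle.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    broom,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
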