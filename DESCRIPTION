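Package: neutrojb
Title: Jarque-Bera Normality Testing for Interval-Valued (Neutrosophic) Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing normality of interval-valued samples recorded
    in neutrosophic form z = a + b*I, where I ranges over an indeterminacy
    interval. Provides interval-valued descriptive moments (mean, sum of
    squares, standard deviation, skewness, excess kurtosis) computed by
    endpoint evaluation, the neutrosophic Jarque-Bera statistic JB_N with a
    tri-state accept/indeterminate/reject decision rule, a scalar measure of
    decision indeterminacy, a Monte-Carlo harness for size and power under
    indeterminacy, delimited-text input/output, and a command-line interface.
    The classical Jarque-Bera test is recovered exactly when the indeterminate
    part vanishes.
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
    utils,
    yaml
Suggests:
    e1071,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
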