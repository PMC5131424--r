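Package: codemort
Title: Compression and Delay of Mortality via a Parametric Age Pattern Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits a ten-parameter piecewise parametric model (the CoDe model)
    to single-year-of-age death probabilities over the full age range, with
    an inverse-age infant term, a logistic accident-hump/background term, and
    Kannisto-type logistic terms with separate slopes in young adulthood,
    late adulthood, and old age, joined continuously at breakpoints anchored
    on the modal age at death. Provides period life-table construction,
    weighted least-squares estimation on log death probabilities and the
    age-at-death distribution, readers for Human Mortality Database 1x1
    layouts, a synthetic-schedule generator with binomial sampling noise, and
    a parameter-substitution decomposition that attributes changes in life
    expectancy at birth to delay of mortality versus compression at
    different stages of life.
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
    lhs,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
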