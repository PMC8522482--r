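Package: runequity
Title: Longitudinal Inequality in Access to and Participation in Community Running Events
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for longitudinal ecological analysis of small-area access to
    and participation in free community running events. Builds monthly panels of
    geodesic distance from area centroids to the nearest active event, computes
    regression-based Relative Index of Inequality (RII) series for distance
    (linear model) and participation (offset-Poisson model) by deprivation,
    fits yearly multivariable offset-Poisson models of the determinants of
    participation with quasi-Poisson and urban/rural sensitivity analyses, and
    produces deprivation-quintile descriptive tables. A seeded synthetic-data
    generator emulates the statistical structure of English small-area (LSOA)
    data so the whole pipeline runs end-to-end without external downloads.
License: MIT
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
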