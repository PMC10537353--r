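Package: floracal
Title: Flowering Phenology Descriptors and Pattern Classification for
    Weekly Floral Calendars
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative analysis of flowering phenology from
    weekly flower-bud censuses, as used in perennial-crop studies such as
    Coffea arabica in the Colombian coffee zones. Validates and normalizes
    long-format bud-count records into per-population floral calendars;
    computes the phenological descriptors flowering synchrony among
    individuals (mean absolute pairwise Spearman correlation), intraindividual
    temporal variability (mean coefficient of variation) and the number of
    flowering events; assigns Newstrom flowering-pattern classes (continual,
    sub-annual, annual, supra-annual) with explicit operational thresholds;
    and runs the inferential stage: factorial analysis of variance with
    Type-II sums of squares, simple-effects decomposition and
    Bonferroni-adjusted pairwise comparisons, with Shapiro-Wilk and Levene
    assumption checks. A seeded stochastic calendar generator with annual
    and continual regime presets supports power and calibration studies, and
    the semester climate summaries of the four Colombian study departments
    ship as a built-in fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    car,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
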