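Package: transcreen
Title: Transparency and Reproducibility Screening of Published Research
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for auditing the transparency of published research
    articles. Implements a screening-record schema for coding journal
    articles against an instrument of accessibility criteria (materials,
    data, analysis scripts, pre-registration, protocol, conflict-of-interest,
    funding and open-access items), computes a per-article accessibility
    score, classifies each article's potential replicability and
    reproducibility from resource availability, and runs the associated
    comparison battery: group summaries, unbalanced two-way ANOVA,
    chi-squared tests of homogeneity with a Fisher's exact fallback for
    sparse tables, and Bonferroni correction with a ceiling at 1. A seedable
    synthetic-record generator calibrated to published marginal proportions
    makes the whole pipeline testable without access to any primary corpus.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    jsonlite,
    yaml,
    withr,
    generics,
    car,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
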