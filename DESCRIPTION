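Package: mrpipe
Title: Two-Sample Mendelian Randomization from GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for two-sample Mendelian randomization
    (MR) on GWAS summary statistics. Reads and harmonizes per-variant
    exposure/outcome association tables, constructs nested instrumental-variable
    sets (lead variants, pleiotropy-filtered, heterogeneity-pruned), estimates
    causal effects with inverse-variance weighted, penalized robust IVW,
    weighted median and MR-Egger regression, runs multivariable MR,
    heterogeneity (Cochran's Q) and leave-one-out diagnostics, analytic power
    and variance-explained calculations, and a synthetic summary-statistic
    generator with known ground truth for end-to-end validation.
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
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
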