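Package: survldm
Title: Microbiome Association Tests for Censored Survival Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Permutation-based tests of microbiome association with censored
    survival outcomes at both the community and the individual-taxon level.
    Survival information enters through Martingale or deviance residuals of a
    covariate-only Cox proportional hazards model; the residuals are then used
    as the tested regressor in linear-decomposition-model (LDM) style
    permutation F-tests, in a PERMANOVA extension for arbitrary ecological
    distances, and in kernel score tests (MiRKAT-S and covariate-adjusted
    variants).  Results from the two residual types, and from multiple data
    scales or distances, are combined with permutation-calibrated min-p
    omnibus tests.  Includes a Dirichlet-Multinomial simulator of confounded
    taxon count tables with Cox-Weibull or accelerated-hazards event times,
    and a benchmark harness for type I error, power, sensitivity and
    false-discovery-rate experiments.
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
    survival,
    tibble,
    tidyr,
    vegan
Suggests:
    biomformat,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
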