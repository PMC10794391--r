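Package: screenplan
Title: Evaluation and Planning of Binary Screening Tests for Online Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating binary screening tests (for example,
    headphone-versus-loudspeaker checks in Internet-based listening
    experiments) and for planning screening studies. Implements
    sensitivity, specificity, prevalence-adjusted predictive values and
    utility-weighted test evaluation; Wilson score confidence intervals;
    empirical ROC curves with trapezoidal AUC; parallel combination of up
    to three tests via weighted voting rules, either by the product rule
    under conditional independence or empirically from item-level data;
    conditional-independence testing (chi-square with an exact multinomial
    fallback); exact and normal-approximation binomial sample-size planning
    with continuity correction for the Filter-Without-Request,
    Filter-After-Request and Split-Convince-Compare screening strategies;
    and a seeded synthetic-cohort simulator for end-to-end validation.
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
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
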