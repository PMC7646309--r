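Package: smdpair
Title: Standardized Mean Differences for Paired and Pre-Post Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Point estimation, small-sample bias correction, sampling
    variances, confidence intervals and common-language effect size
    conversions for standardized mean differences in repeated-measures
    designs: Cohen's d_z (signal-to-noise), Glass's Delta_pre, Cohen's d_av
    and d_rm (magnitude-based), and the pretest-posttest-control contrast.
    Includes a seeded Monte Carlo simulator for studying estimator bias and
    precision over grids of pre-post correlation and baseline spread,
    subject-level bootstrap intervals, and deterministic rendering of
    results paragraphs from raw paired data or printed summary statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    testthat (>= 3.0.0)
Config/testthat/edition: 3
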