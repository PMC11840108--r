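Package: rwrbias
Title: Bias in Resampling-Based Estimates of Statistical Errors for
    Mass-Univariate Association Studies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation machinery for quantifying how resampling with
    replacement from a single large sample biases data-driven estimates of
    statistical errors (power, false negative/positive rates, sign errors,
    effect-size inflation, probability of replication) in mass-univariate
    brain-wide association studies. Provides subject-level and
    summary-level null and ground-truth generators under full seed
    control, the Fisher-z power machinery (critical correlations, inverse
    power analysis, analytical power curves), fresh-sample
    infinite-population baselines with closed-form expectations, and a
    variance-convolution diagnostic explaining the bias as additive
    sampling variance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
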