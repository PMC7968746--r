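Package: fpinfer
Title: Phenomenological Multi-Path Gamma Mixture Models for First-Passage Times
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers phenomenological models of first-passage (completion) time
    distributions, such as neuronal inter-spike intervals, from discretized
    i.i.d. samples. The model family consists of mixtures of Gamma-distributed
    completion paths, each path a chain of L sequential states with mean
    per-state dwell time tau. Model complexity (the number of paths M) is
    selected by Bayesian model selection, with log marginal likelihoods
    estimated by importance sampling around the maximum a posteriori fit.
    Fitted families indexed by an external condition can be interpolated or
    extrapolated to unobserved conditions and validated with bootstrap
    Jensen-Shannon divergences, and early-time decomposition of the completion
    CDF yields lower bounds on the number of internal states any mechanistic
    model must contain.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
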