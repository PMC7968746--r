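# fpinfer

Phenomenological inference for first-passage (FP) time distributions.

Many biological completion processes — the inter-spike intervals (ISIs) of a
neuron, the time for a biochemical cascade to produce its product — are
measured as i.i.d. samples of a completion time, while the microscopic
network generating them is far too complex to model mechanistically.
`fpinfer` fits such samples within a nested, complete family of **multi-path
Gamma mixtures**: a model with `M` completion paths has density

    P(t | θ, M) = Σᵢ pᵢ · Gamma(t; shape Lᵢ, scale τᵢ),
    p₁ = 1 / (1 + x₂ + … + x_M),   pᵢ = xᵢ / (1 + x₂ + … + x_M),

where path `i` is a chain of `Lᵢ` internal states with mean per-state dwell
time `τᵢ` (ms), so `T̄ᵢ = τᵢLᵢ` is its mean completion time and
`CVᵢ² = 1/Lᵢ` its squared coefficient of variation. The package is aimed at
anyone analyzing spike trains or completion-time assays who wants a model
whose complexity adapts to the data instead of being guessed.

What it does:

* **Fitting** (`bin_isi()`, `fit_mle()`): binned maximum a posteriori fits
  at the recording resolution `dt`, by bounded multi-start Nelder-Mead.
* **Model selection** (`select_model()`, `select_model_multi()`): natural-log
  marginal likelihoods per path count `M` by importance sampling around the
  MAP point (Hessian-based proposal with a defensive prior component, a
  block-form covariance for boundary fits with zero-flux paths, and a
  `(M−1)!` relabeling-degeneracy correction), with asymmetric Monte-Carlo
  error bars; multi-condition experiments are scored by summing
  per-condition log evidences.
* **Posterior summaries** (`posterior_curve()`, `entropy_plugin()`,
  `cross_entropy()`): posterior-averaged fit curves with uncertainty bands
  and entropy-based fit diagnostics.
* **Prediction across conditions** (`match_paths()`, `interpolate_model()`,
  `evaluate_prediction()`): path correspondence across an external scalar
  condition (e.g. injected current), linear interpolation/extrapolation of
  path summaries to unobserved conditions, and bootstrap Jensen-Shannon
  validation against data-vs-data and direct-fit baselines.
* **Mechanistic bounds** (`min_states_lower_bound()`): early-time CDF
  decomposition giving a lower bound on the number of internal states any
  Markovian mechanistic model must contain.
* **Synthetic data** (`generate_dataset()`, `make_condition_family()`,
  `completeness_construction()`): quantized samples from arbitrary mixtures
  and condition-indexed families with known ground truth.

Results are tibbles or small S3 objects with `tidy()`/`glance()` methods and
`autoplot()` plots, so everything composes with the tidyverse. A thin CLI
(`exec/fpinfer`, installed under the package's `exec/` directory) exposes
`simulate`, `fit`, `select`, `select-multi`, `curve`, `predict`, `validate`,
and `bound` subcommands over the same functions.

## Worked example

Two well-separated completion paths (a fast variable path at ~10 ms, a slow
regular one at ~80 ms), recovered from 8000 quantized samples:

```r
library(fpinfer)

m_true <- fp_model(tau = c(2.5, 3.2), L = c(4, 25), x = 2/3)
isi <- generate_dataset(m_true, 8000, dt = 0.1, seed = 42)

sel <- select_model(isi, dt = 0.1, M_max = 3,
                    fit_cfg = fit_config(n_starts = 2),
                    is_cfg = is_config(n_samples = 5000))
tidy(sel)[, 1:5]
#> # A tibble: 3 × 5
#>       M log_evidence  err_lo  err_hi    ess
#>   <int>        <dbl>   <dbl>   <dbl>  <dbl>
#> 1     1      -55559. 0.00340 0.00339 4728.
#> 2     2      -51362. 0.00605 0.00601 4230.
#> 3     3      -51370. 0.141   0.123     57.4
```

`M = 2` wins by ~8 nats over `M = 3` (the Occam penalty for the superfluous
path) and by ~4200 nats over `M = 1`. The winning fit recovers the
generator's per-path summaries:

```r
tidy(sel$fits[[sel$best_M]])
#> # A tibble: 2 × 8
#>    path   tau     L     x weight mean_completion    cv at_boundary
#>   <int> <dbl> <dbl> <dbl>  <dbl>           <dbl> <dbl> <lgl>
#> 1     1  3.20 25.1   1     0.401           80.3  0.200 FALSE
#> 2     2  2.57  3.88  1.50  0.599            9.96 0.507 FALSE
```

(truth: `T̄ = (80, 10)` ms, `CV = (0.2, 0.5)`, `p = (0.4, 0.6)`). The fit
diagnostics and the mechanistic bound:

```r
cross_entropy(sel$data, sel$fits[[sel$best_M]]$model)  # 6.416 nats
entropy_plugin(sel$data)                               # 6.331 nats (floor)

min_states_lower_bound(sel$fits[[sel$best_M]]$model, isi, n_events = 50)
#> <fp_bound> first 50 events explained by path(s) 2; >= 4 internal states required
```

The 50 earliest events are carried by the fast path (`L ≈ 3.9`), so any
mechanistic model of this process needs at least 4 internal states.
`autoplot(sel)`, `autoplot(posterior_curve(...))`, and `autoplot()` on the
bound object draw the corresponding figures.

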