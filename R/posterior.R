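#' Posterior-averaged fit curve with uncertainty band
#'
#' Computes the posterior mean and standard deviation of the discretized
#' model density over the parameter posterior by self-normalized importance
#' sampling, reusing the same proposal (and seed) as the evidence estimator.
#' At each grid point `t` the curve is the model probability of the bin
#' `(t - dt, t]` divided by `dt`, i.e. a density in 1/ms.
#'
#' @param data The `fp_binned` data the fit was computed on.
#' @param fit The `fp_fit` to average around.
#' @param grid Ascending positive time points (ms). Defaults to the data's
#'   bin upper edges.
#' @param cfg An [is_config()].
#' @param Sigma Optional precomputed [proposal_covariance()].
#' @param ess_warn Effective-sample-size fraction below which a warning is
#'   attached.
#' @return A tibble of class `fp_curve` with columns `t`, `mean`, `std`, and
#'   attributes `dt` and `ess`.
#' @export
posterior_curve <- function(data, fit, grid = NULL, cfg = is_config(),
                            Sigma = NULL, ess_warn = 0.01) {
  stopifnot_binned(data)
  stopifnot(inherits(fit, "fp_fit"))
  dt <- data$dt
  if (is.null(grid)) grid <- data$edges[-1L]
  grid <- as.numeric(grid)
  if (any(diff(grid) <= 0) || any(grid <= 0)) {
    stop("`grid` must be positive and strictly ascending", call. = FALSE)
  }
  is_res <- importance_sample(data, fit, cfg, Sigma)
  keep <- which(is.finite(is_res$lw))
  lw <- is_res$lw[keep]
  w <- exp(lw - logsumexp(lw))
  lo <- pmax(grid - dt, 0)
  # curve matrix: grid points x posterior draws
  fmat <- vapply(keep, function(i) {
    model <- model_from_theta(is_res$theta[i, ], fit$M)
    bin_probability(lo, grid, model) / dt
  }, numeric(length(grid)))
  fmat <- matrix(fmat, nrow = length(grid))
  mean_f <- as.numeric(fmat %*% w)
  var_f <- pmax(as.numeric(fmat^2 %*% w) - mean_f^2, 0)
  ess <- 1 / sum(w^2)
  if (ess < ess_warn * length(w)) {
    warning(sprintf("posterior-curve effective sample size %.0f of %d draws",
                    ess, length(w)), call. = FALSE)
  }
  out <- tibble::tibble(t = grid, mean = mean_f, std = sqrt(var_f))
  class(out) <- c("fp_curve", class(out))
  attr(out, "dt") <- dt
  attr(out, "ess") <- ess
  out
}

#' Plug-in entropy of the empirical bin distribution
#'
#' `H0 = -sum_i (n_i/N) ln(n_i/N)` over occupied bins, in nats. The optional
#' Miller-Madow correction adds `(K_occ - 1) / (2N)`.
#'
#' @param counts An `fp_binned` object.
#' @param miller_madow Apply the Miller-Madow bias correction?
#' @return Entropy in nats.
#' @export
entropy_plugin <- function(counts, miller_madow = FALSE) {
  stopifnot_binned(counts)
  n <- counts$counts[counts$counts > 0L]
  p <- n / counts$n_total
  H <- -sum(p * log(p))
  if (miller_madow) H <- H + (length(n) - 1) / (2 * counts$n_total)
  H
}

#' Cross-entropy between the empirical bin distribution and a model
#'
#' `H_M = -sum_i (n_i/N) ln P_dt(bin_i | model)`, in nats: minus the mean
#' per-event log likelihood. Approaches [entropy_plugin()] from above as the
#' fit improves (Gibbs' inequality holds when the model mass is concentrated
#' on the observed bins).
#'
#' @param counts An `fp_binned` object.
#' @param model An [fp_model()].
#' @return Cross-entropy in nats; `+Inf` with a warning if an occupied bin
#'   has zero model probability.
#' @export
cross_entropy <- function(counts, model) {
  stopifnot_binned(counts)
  stopifnot_model(model)
  ll <- withCallingHandlers(
    log_likelihood(counts, model),
    warning = function(w) {
      warning("occupied bin with zero model probability; cross-entropy is +Inf",
              call. = FALSE)
      invokeRestart("muffleWarning")
    }
  )
  -ll / counts$n_total
}
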