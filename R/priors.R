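#' Prior configuration
#'
#' Independent priors on the model parameters: exponential priors with scales
#' `Z_tau` (ms) and `Z_L` on each path's `tau` and `L`, and a uniform prior on
#' each relative flux weight `x` over `[0, Z_x]`. The scales are deliberately
#' wide relative to the measured time scales so that `tau * L` can range from
#' the temporal resolution to beyond the longest observed completion times.
#'
#' @param Z_tau Exponential prior scale for `tau` (ms). Default 20.
#' @param Z_L Exponential prior scale for `L`. Default 20.
#' @param Z_x Upper bound of the uniform prior on `x`. Default `1e3`.
#' @return A list of class `fp_priors`.
#' @export
prior_config <- function(Z_tau = 20, Z_L = 20, Z_x = 1e3) {
  stopifnot(Z_tau > 0, Z_L > 0, Z_x > 0)
  structure(list(Z_tau = Z_tau, Z_L = Z_L, Z_x = Z_x), class = "fp_priors")
}

#' Log prior density of a model's parameters
#'
#' @param model An [fp_model()].
#' @param priors A [prior_config()].
#' @return The log prior density; `-Inf` outside the support (any
#'   `x > Z_x`, or non-positive `tau` or `L`).
#' @export
log_prior <- function(model, priors = prior_config()) {
  stopifnot_model(model)
  log_prior_theta(theta_from_model(model), model$M, priors)
}

# theta packing: (tau1, L1, x2, tau2, L2, ..., xM, tauM, LM), length 3M - 1
theta_from_model <- function(model) {
  if (model$M == 1L) {
    c(model$tau[1L], model$L[1L])
  } else {
    c(model$tau[1L], model$L[1L],
      as.numeric(rbind(model$x, model$tau[-1L], model$L[-1L])))
  }
}

model_from_theta <- function(theta, M) {
  if (M == 1L) {
    fp_model(tau = theta[1L], L = theta[2L])
  } else {
    rest <- matrix(theta[-(1:2)], nrow = 3L)
    fp_model(tau = c(theta[1L], rest[2L, ]),
             L = c(theta[2L], rest[3L, ]),
             x = rest[1L, ])
  }
}

theta_indices <- function(M) {
  # per-path indices into theta: path 1 -> (tau, L); path i>1 -> (x, tau, L)
  out <- vector("list", M)
  out[[1L]] <- c(tau = 1L, L = 2L)
  if (M > 1L) {
    for (i in 2:M) {
      base <- 2L + 3L * (i - 2L)
      out[[i]] <- c(x = base + 1L, tau = base + 2L, L = base + 3L)
    }
  }
  out
}

# raw-theta variant used on importance-sampling draws (no fp_model validation)
log_prior_theta <- function(theta, M, priors) {
  idx <- theta_indices(M)
  tau <- vapply(idx, function(ix) theta[[ix[["tau"]]]], numeric(1))
  L <- vapply(idx, function(ix) theta[[ix[["L"]]]], numeric(1))
  x <- if (M > 1L) vapply(idx[-1L], function(ix) theta[[ix[["x"]]]], numeric(1)) else numeric(0)
  if (any(tau <= 0) || any(L <= 0) || any(x < 0) || any(x > priors$Z_x)) {
    return(-Inf)
  }
  -(M - 1) * log(priors$Z_x) +
    sum(-tau / priors$Z_tau - log(priors$Z_tau) - L / priors$Z_L - log(priors$Z_L))
}

theta_in_support <- function(theta, M, priors) {
  is.finite(log_prior_theta(theta, M, priors))
}
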