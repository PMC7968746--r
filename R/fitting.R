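#' Fitting configuration
#'
#' Settings for the bounded multi-start derivative-free search used by
#' [fit_mle()]. Optimization runs in transformed coordinates: `log(tau)` and
#' `log(L)` are mapped to the unbounded line through a scaled logistic over
#' their boxes, and each flux weight `x` through a logistic over `[0, Z_x]`,
#' so a plain Nelder-Mead simplex respects all box constraints.
#'
#' @param n_starts Number of optimization starts (>= 1). One start is a
#'   method-of-moments initialization (plus a warm start when a lower-order
#'   fit is supplied); the rest are randomized perturbations.
#' @param max_iter Iteration cap per start.
#' @param tol Relative convergence tolerance on the log objective.
#' @param tau_lo,tau_hi Box for `tau` (ms).
#' @param L_lo,L_hi Box for `L`.
#' @param seed Integer seed making the randomized starts reproducible.
#' @return A list of class `fp_fit_config`.
#' @export
fit_config <- function(n_starts = 4L, max_iter = 2000L, tol = 1e-8,
                       tau_lo = 1e-3, tau_hi = 1e3,
                       L_lo = 1e-2, L_hi = 1e2, seed = 1L) {
  stopifnot(n_starts >= 1, max_iter >= 1, tol > 0,
            tau_lo > 0, tau_lo < tau_hi, L_lo > 0, L_lo < L_hi)
  structure(
    list(n_starts = as.integer(n_starts), max_iter = as.integer(max_iter),
         tol = tol, tau_lo = tau_lo, tau_hi = tau_hi, L_lo = L_lo, L_hi = L_hi,
         seed = as.integer(seed)),
    class = "fp_fit_config"
  )
}

#' Binned log likelihood of a model
#'
#' The multinomial log likelihood of the binned sample:
#' `sum_i n_i * log P(bin_i | model)` with bin probabilities from
#' [bin_probability()] (exact CDF differences, with a midpoint log-density
#' fallback where the difference underflows).
#'
#' @param data An [bin_isi()] result (`fp_binned`).
#' @param model An [fp_model()].
#' @return The log likelihood; `-Inf` (with a warning) if some occupied bin
#'   has zero probability under the model.
#' @export
log_likelihood <- function(data, model) {
  stopifnot_binned(data)
  stopifnot_model(model)
  occ <- occupied_bins(data)
  ll <- loglik_occ(occ, model)
  if (!is.finite(ll)) {
    warning("occupied bin with zero model probability; log likelihood is -Inf",
            call. = FALSE)
  }
  ll
}

occupied_bins <- function(data) {
  K <- length(data$counts)
  keep <- which(data$counts > 0L)
  list(lo = data$edges[keep], hi = data$edges[keep + 1L],
       n = data$counts[keep], n_total = data$n_total, dt = data$dt)
}

loglik_occ <- function(occ, model) {
  sum(occ$n * log_bin_probability(occ$lo, occ$hi, model))
}

# ---- bounded transform (scaled logistic per coordinate) ---------------------

clamp_u <- function(u) pmin(pmax(u, -40), 40)

u_from_theta <- function(theta, M, config, priors) {
  idx <- theta_indices(M)
  u <- numeric(length(theta))
  frac <- function(v, lo, hi) pmin(pmax((v - lo) / (hi - lo), 1e-12), 1 - 1e-12)
  for (i in seq_len(M)) {
    ix <- idx[[i]]
    u[ix[["tau"]]] <- stats::qlogis(frac(log(theta[ix[["tau"]]]),
                                         log(config$tau_lo), log(config$tau_hi)))
    u[ix[["L"]]] <- stats::qlogis(frac(log(theta[ix[["L"]]]),
                                       log(config$L_lo), log(config$L_hi)))
    if (i > 1L) {
      u[ix[["x"]]] <- stats::qlogis(frac(theta[ix[["x"]]], 0, priors$Z_x))
    }
  }
  clamp_u(u)
}

theta_from_u <- function(u, M, config, priors) {
  idx <- theta_indices(M)
  theta <- numeric(length(u))
  for (i in seq_len(M)) {
    ix <- idx[[i]]
    theta[ix[["tau"]]] <- exp(log(config$tau_lo) +
      (log(config$tau_hi) - log(config$tau_lo)) * stats::plogis(u[ix[["tau"]]]))
    theta[ix[["L"]]] <- exp(log(config$L_lo) +
      (log(config$L_hi) - log(config$L_lo)) * stats::plogis(u[ix[["L"]]]))
    if (i > 1L) theta[ix[["x"]]] <- priors$Z_x * stats::plogis(u[ix[["x"]]])
  }
  theta
}

# ---- initialization ---------------------------------------------------------

# method-of-moments per quantile block of the (bin-midpoint expanded) sample
moments_init <- function(data, M, config) {
  td <- tidy.fp_binned(data)
  values <- rep(td$mid, td$count)
  values <- sort(values)
  blocks <- if (M == 1L) {
    list(values)
  } else {
    split(values, cut(seq_along(values), M, labels = FALSE))
  }
  tau <- L <- numeric(M)
  for (i in seq_len(M)) {
    v <- blocks[[i]]
    m <- mean(v)
    s2 <- stats::var(v)
    if (!is.finite(s2) || s2 <= 0) s2 <- (data$dt / 2)^2 + (0.25 * m)^2
    L[i] <- min(max(m^2 / s2, 2 * config$L_lo), config$L_hi / 2)
    tau[i] <- min(max(m / L[i], 2 * config$tau_lo), config$tau_hi / 2)
  }
  fp_model(tau = tau, L = L, x = rep(1, M - 1))
}

warm_init <- function(warm, data, M, config) {
  wm <- if (inherits(warm, "fp_fit")) warm$model else warm
  if (!is_fp_model(wm)) return(NULL)
  if (wm$M == M) return(wm)        # same-order warm start: reuse directly
  if (wm$M != M - 1L) return(NULL)
  td <- tidy.fp_binned(data)
  values <- rep(td$mid, td$count)
  m <- mean(values)
  s2 <- stats::var(values)
  L_new <- min(max(m^2 / max(s2, 1e-12), 2 * config$L_lo), config$L_hi / 2)
  tau_new <- min(max(m / L_new, 2 * config$tau_lo), config$tau_hi / 2)
  fp_model(tau = c(wm$tau, tau_new), L = c(wm$L, L_new), x = c(wm$x, 0.05))
}

# ---- MAP / MLE fit ----------------------------------------------------------

#' Maximum a posteriori fit of an M-path model
#'
#' Maximizes `log F(theta) = log P(D | theta, M) + log P(theta | M)` over the
#' bounded parameter space by multi-start Nelder-Mead in transformed
#' coordinates. One start uses method-of-moments values per quantile block of
#' the sample; if `warm` supplies an `(M - 1)`-path fit, a warm start appends
#' one weak extra path to it; remaining starts perturb the best initializer.
#'
#' @param data An `fp_binned` object from [bin_isi()].
#' @param M Number of completion paths (>= 1).
#' @param priors A [prior_config()].
#' @param config A [fit_config()].
#' @param warm Optional `(M - 1)`-path `fp_fit` or `fp_model` used as a warm
#'   start.
#' @return An object of class `fp_fit`: fields `model`, `log_f`, `log_lik`,
#'   `log_prior`, `at_boundary` (per-path trivial/boundary flags), `M`,
#'   `starts_used`, `convergence`, `priors`, `config`, `data_info`.
#' @export
fit_mle <- function(data, M, priors = prior_config(), config = fit_config(),
                    warm = NULL) {
  stopifnot_binned(data)
  stopifnot(M >= 1)
  M <- as.integer(M)
  occ <- occupied_bins(data)

  neg_obj <- function(u) {
    theta <- theta_from_u(u, M, config, priors)
    lp <- log_prior_theta(theta, M, priors)
    if (!is.finite(lp)) return(1e12)
    model <- model_from_theta(theta, M)
    ll <- loglik_occ(occ, model)
    if (!is.finite(ll)) return(1e12)
    -(ll + lp)
  }

  inits <- list(moments_init(data, M, config))
  if (!is.null(warm)) {
    wi <- warm_init(warm, data, M, config)
    if (!is.null(wi)) inits <- c(inits, list(wi))
  }
  u_inits <- lapply(inits, function(m)
    u_from_theta(theta_from_model(m), M, config, priors))

  run <- function() {
    # seed base starts, then random perturbations of the best base start
    base_vals <- vapply(u_inits, neg_obj, numeric(1))
    best_base <- u_inits[[which.min(base_vals)]]
    starts <- u_inits
    while (length(starts) < config$n_starts) {
      starts <- c(starts, list(clamp_u(best_base +
        stats::rnorm(length(best_base), 0, 0.75))))
    }
    starts <- starts[seq_len(max(config$n_starts, length(u_inits)))]
    fits <- lapply(starts, function(u0) {
      stats::optim(u0, neg_obj, method = "Nelder-Mead",
                   control = list(maxit = config$max_iter,
                                  reltol = config$tol))
    })
    fits
  }
  fits <- withr::with_seed(config$seed, run())

  vals <- vapply(fits, `[[`, numeric(1), "value")
  if (all(vals >= 1e12)) {
    stop("optimization failed from every start (all objectives degenerate)",
         call. = FALSE)
  }
  best <- fits[[which.min(vals)]]
  theta <- theta_from_u(best$par, M, config, priors)
  model <- model_from_theta(theta, M)
  ll <- loglik_occ(occ, model)
  lp <- log_prior_theta(theta, M, priors)

  structure(
    list(model = model, M = M,
         log_f = ll + lp, log_lik = ll, log_prior = lp,
         at_boundary = boundary_flags(model, priors, config),
         starts_used = length(fits),
         convergence = best$convergence,
         priors = priors, config = config,
         data_info = list(dt = data$dt, n_total = data$n_total,
                          K = length(data$counts))),
    class = "fp_fit"
  )
}

# a path is trivial/boundary when its probability is negligible or any of its
# parameters sits against a box bound (relative tolerance 1e-6)
boundary_flags <- function(model, priors, config, p_tol = 1e-6, rel = 1e-6) {
  p <- mixture_weights(model$x)
  near <- function(v, b) abs(v - b) <= rel * max(abs(b), 1)
  vapply(seq_len(model$M), function(i) {
    flag <- p[i] < p_tol ||
      near(model$tau[i], config$tau_lo) || near(model$tau[i], config$tau_hi) ||
      near(model$L[i], config$L_lo) || near(model$L[i], config$L_hi)
    if (i > 1L) {
      flag <- flag || model$x[i - 1L] < p_tol ||
        near(model$x[i - 1L], priors$Z_x)
    }
    flag
  }, logical(1))
}

#' @export
print.fp_fit <- function(x, ...) {
  cat(sprintf("<fp_fit> M = %d, log F = %.4f, log lik = %.4f (%d starts)\n",
              x$M, x$log_f, x$log_lik, x$starts_used))
  if (any(x$at_boundary)) {
    cat("  boundary/trivial paths:", which(x$at_boundary), "\n")
  }
  print(path_summaries(x$model))
  invisible(x)
}

#' Tidy a fitted model: one row per completion path
#'
#' @param x An `fp_fit`.
#' @param ... Unused.
#' @return A tibble of per-path parameters and summaries with an
#'   `at_boundary` flag.
#' @method tidy fp_fit
#' @export
tidy.fp_fit <- function(x, ...) {
  out <- path_summaries(x$model)
  out$at_boundary <- x$at_boundary
  out
}

#' One-row summary of a fit
#'
#' @param x An `fp_fit`.
#' @param ... Unused.
#' @return A tibble with `M`, `log_f`, `log_lik`, `log_prior`, `n`,
#'   `starts_used`, `convergence`.
#' @method glance fp_fit
#' @export
glance.fp_fit <- function(x, ...) {
  tibble::tibble(
    M = x$M, log_f = x$log_f, log_lik = x$log_lik, log_prior = x$log_prior,
    n = x$data_info$n_total, starts_used = x$starts_used,
    convergence = x$convergence
  )
}
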