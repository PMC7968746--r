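#' Importance-sampling configuration
#'
#' Settings for the evidence estimator. The proposal is a multivariate normal
#' centered at the MAP point with covariance from the inverse negative Hessian
#' of `log F` (interior optima) or the boundary block form (trivial paths):
#' the covariance of the lower-order fit for the non-trivial coordinates plus
#' a diagonal `(alpha_x^2, alpha_tau_sq, alpha_L_sq)` block for each trivial
#' path, the latter two taken as `(3 * Z)^2` so the proposal comfortably
#' covers the exponential prior along flat likelihood directions.
#'
#' @param n_samples Number of importance samples (>= 1000). Default `1e5`.
#' @param seed Integer seed.
#' @param hess_step Relative step of the central finite-difference Hessian.
#' @param eig_floor Minimum eigenvalue (of the negative Hessian) used when
#'   repairing flat or indefinite curvature before inversion. The default
#'   `1/3600` caps any proposal variance at 3600, the boundary-case width,
#'   so near-degenerate fits (e.g. duplicated paths) still yield a usable
#'   proposal.
#' @param alpha_x Proposal standard deviation along a trivial path's flux
#'   weight. Default 0.01.
#' @param alpha_tau_sq,alpha_L_sq Proposal variances along a trivial path's
#'   `tau` and `L`. Default 3600 (= `(3 * 20)^2`).
#' @param defensive Fraction of proposal draws taken from the prior itself
#'   (defensive mixture). The prior component bounds the importance weights,
#'   keeping the estimator variance finite when the posterior tails are
#'   heavier than the Gaussian component (broad posteriors on small data);
#'   it costs at most this fraction of effective sample size when the
#'   Gaussian alone is adequate. Set to 0 for a pure Gaussian proposal.
#' @param rel_se_warn Relative standard error above which a convergence
#'   warning is attached to the estimate.
#' @return A list of class `fp_is_config`.
#' @export
is_config <- function(n_samples = 1e5, seed = 1L, hess_step = 1e-4,
                      eig_floor = 1 / 3600, alpha_x = 0.01,
                      alpha_tau_sq = 3600, alpha_L_sq = 3600,
                      defensive = 0.05, rel_se_warn = 0.5) {
  stopifnot(n_samples >= 1e3, hess_step > 0, eig_floor > 0,
            alpha_x > 0, alpha_tau_sq > 0, alpha_L_sq > 0,
            defensive >= 0, defensive < 1)
  structure(
    list(n_samples = as.integer(n_samples), seed = as.integer(seed),
         hess_step = hess_step, eig_floor = eig_floor, alpha_x = alpha_x,
         alpha_tau_sq = alpha_tau_sq, alpha_L_sq = alpha_L_sq,
         defensive = defensive, rel_se_warn = rel_se_warn),
    class = "fp_is_config"
  )
}

# log F(theta) = log P(D | theta, M) + log P(theta | M); -Inf out of support
log_f_theta <- function(theta, M, occ, priors) {
  lp <- log_prior_theta(theta, M, priors)
  if (!is.finite(lp)) return(-Inf)
  model <- tryCatch(model_from_theta(theta, M), error = function(e) NULL)
  if (is.null(model)) return(-Inf)
  ll <- loglik_occ(occ, model)
  ll + lp
}

# central finite-difference Hessian of f over coordinates `coords`,
# with per-coordinate steps shrunk to stay inside the support box
num_hessian <- function(f, theta, coords = seq_along(theta),
                        hess_step = 1e-4, lower = NULL, upper = NULL) {
  d <- length(coords)
  h <- hess_step * (1 + abs(theta[coords]))
  if (!is.null(lower)) h <- pmin(h, 0.49 * (theta[coords] - lower[coords]))
  if (!is.null(upper)) h <- pmin(h, 0.49 * (upper[coords] - theta[coords]))
  h <- pmax(h, 1e-12)
  f0 <- f(theta)
  H <- matrix(NA_real_, d, d)
  shift <- function(j, s) {
    th <- theta
    th[coords[j]] <- th[coords[j]] + s
    th
  }
  for (j in seq_len(d)) {
    H[j, j] <- (f(shift(j, h[j])) - 2 * f0 + f(shift(j, -h[j]))) / h[j]^2
    if (j < d) {
      for (k in (j + 1):d) {
        thpp <- shift(j, h[j]); thpp[coords[k]] <- thpp[coords[k]] + h[k]
        thpm <- shift(j, h[j]); thpm[coords[k]] <- thpm[coords[k]] - h[k]
        thmp <- shift(j, -h[j]); thmp[coords[k]] <- thmp[coords[k]] + h[k]
        thmm <- shift(j, -h[j]); thmm[coords[k]] <- thmm[coords[k]] - h[k]
        H[j, k] <- H[k, j] <-
          (f(thpp) - f(thpm) - f(thmp) + f(thmm)) / (4 * h[j] * h[k])
      }
    }
  }
  (H + t(H)) / 2
}

# invert the negative Hessian with symmetric eigenvalue flooring
invert_neg_hessian <- function(H, eig_floor) {
  A <- -(H + t(H)) / 2
  e <- eigen(A, symmetric = TRUE)
  vals <- pmax(e$values, eig_floor)
  if (any(!is.finite(vals))) {
    stop("covariance construction failed: non-finite Hessian", call. = FALSE)
  }
  Sigma <- e$vectors %*% (t(e$vectors) / vals)
  (Sigma + t(Sigma)) / 2
}

support_box <- function(M, priors) {
  d <- 3L * M - 1L
  lower <- rep(0, d)
  upper <- rep(Inf, d)
  idx <- theta_indices(M)
  for (i in seq_len(M)) {
    if (i > 1L) upper[idx[[i]][["x"]]] <- priors$Z_x
  }
  list(lower = lower, upper = upper)
}

#' Proposal covariance for the evidence estimator
#'
#' For an interior optimum, the inverse of the negative numerical Hessian of
#' `log F` at the MAP point (eigenvalue-floored to positive definite). When
#' the fit has trivial paths (near-zero flux, optimum on the boundary), the
#' covariance is block-structured: the Hessian-based covariance over the
#' non-trivial coordinates, plus an independent diagonal block
#' `diag(alpha_x^2, alpha_tau_sq, alpha_L_sq)` per trivial path. Rows/columns
#' are returned in the original parameter order; the trivial-path block
#' coordinates are uncorrelated with all others.
#'
#' @param fit An `fp_fit`.
#' @param data The `fp_binned` data the fit was computed on.
#' @param cfg An [is_config()].
#' @return A `(3M - 1) x (3M - 1)` covariance matrix over
#'   `theta = (tau1, L1, x2, tau2, L2, ...)`, with attribute
#'   `trivial_paths` (integer indices of boundary paths handled by the
#'   block form).
#' @export
proposal_covariance <- function(fit, data, cfg = is_config()) {
  stopifnot(inherits(fit, "fp_fit"))
  stopifnot_binned(data)
  occ <- occupied_bins(data)
  priors <- fit$priors
  M <- fit$M
  theta <- theta_from_model(fit$model)
  idx <- theta_indices(M)
  box <- support_box(M, priors)
  f <- function(th) log_f_theta(th, M, occ, priors)

  p <- mixture_weights(fit$model$x)
  trivial <- which(fit$at_boundary & p < 1e-6 & seq_len(M) > 1L)

  d <- length(theta)
  if (length(trivial) == 0L) {
    H <- num_hessian(f, theta, seq_len(d), cfg$hess_step, box$lower, box$upper)
    Sigma <- invert_neg_hessian(H, cfg$eig_floor)
  } else {
    triv_coords <- unlist(lapply(idx[trivial], as.integer))
    keep <- setdiff(seq_len(d), triv_coords)
    # likelihood is flat along a zero-flux path, so the restricted Hessian
    # equals the lower-order model's Hessian at its own optimum
    H <- num_hessian(f, theta, keep, cfg$hess_step, box$lower, box$upper)
    Sigma_p <- invert_neg_hessian(H, cfg$eig_floor)
    Sigma <- matrix(0, d, d)
    Sigma[keep, keep] <- Sigma_p
    for (i in trivial) {
      ix <- idx[[i]]
      Sigma[ix[["x"]], ix[["x"]]] <- cfg$alpha_x^2
      Sigma[ix[["tau"]], ix[["tau"]]] <- cfg$alpha_tau_sq
      Sigma[ix[["L"]], ix[["L"]]] <- cfg$alpha_L_sq
    }
  }
  attr(Sigma, "trivial_paths") <- as.integer(trivial)
  Sigma
}

# one prior draw per row, in theta order (tau1, L1, x2, tau2, L2, ...)
rprior_theta <- function(n, M, priors) {
  d <- 3L * M - 1L
  out <- matrix(NA_real_, n, d)
  idx <- theta_indices(M)
  for (i in seq_len(M)) {
    ix <- idx[[i]]
    out[, ix[["tau"]]] <- stats::rexp(n, rate = 1 / priors$Z_tau)
    out[, ix[["L"]]] <- stats::rexp(n, rate = 1 / priors$Z_L)
    if (i > 1L) out[, ix[["x"]]] <- stats::runif(n, 0, priors$Z_x)
  }
  out
}

# draw importance samples and evaluate log weights lw_i = logF_i - logF* - logG_i.
# G is a defensive mixture: (1 - lambda) * MVN(theta*, Sigma) + lambda * prior,
# which bounds the weights by max-likelihood / lambda and keeps the estimator's
# variance finite even when the posterior tails are heavier than Gaussian.
importance_sample <- function(data, fit, cfg = is_config(), Sigma = NULL) {
  occ <- occupied_bins(data)
  priors <- fit$priors
  M <- fit$M
  theta_star <- theta_from_model(fit$model)
  log_f_star <- fit$log_f
  if (is.null(Sigma)) Sigma <- proposal_covariance(fit, data, cfg)
  d <- length(theta_star)
  R <- tryCatch(chol(Sigma), error = function(e) {
    chol(Sigma + diag(cfg$eig_floor, d))
  })
  N <- cfg$n_samples
  lam <- cfg$defensive
  draws <- withr::with_seed(cfg$seed, {
    from_prior <- stats::runif(N) < lam
    Z <- matrix(stats::rnorm(N * d), N, d)
    P <- if (any(from_prior)) rprior_theta(sum(from_prior), M, priors) else NULL
    list(from_prior = from_prior, Z = Z, P = P)
  })
  X <- sweep(draws$Z %*% R, 2L, theta_star, `+`)
  if (any(draws$from_prior)) X[draws$from_prior, ] <- draws$P
  # MVN log density for every row (solve back to standardized coordinates)
  Y <- backsolve(R, t(sweep(X, 2L, theta_star, `-`)), transpose = TRUE)
  log_mvn <- -d / 2 * log(2 * pi) - sum(log(diag(R))) - 0.5 * colSums(Y^2)
  log_pri <- vapply(seq_len(N), function(i) {
    log_prior_theta(X[i, ], M, priors)
  }, numeric(1))
  log_g <- if (lam > 0) {
    pmax_part <- pmax(log(1 - lam) + log_mvn, log(lam) + log_pri)
    pmax_part + log1p(exp(-abs((log(1 - lam) + log_mvn) -
                                 (log(lam) + log_pri))))
  } else {
    log_mvn
  }
  log_f <- vapply(seq_len(N), function(i) {
    log_f_theta(X[i, ], M, occ, priors)
  }, numeric(1))
  lw <- ifelse(is.finite(log_f), log_f - log_f_star - log_g, -Inf)
  list(theta = X, lw = lw, log_f = log_f, log_g = log_g,
       log_f_star = log_f_star, Sigma = Sigma)
}

#' Log marginal likelihood of an M-path model by importance sampling
#'
#' Estimates `ln P(D | M)` with a multivariate normal proposal centered at
#' the MAP point. Proposal draws falling outside the prior support contribute
#' zero to the numerator but stay in the `1/N` normalization, keeping the
#' estimator unbiased for the integral of `F` over its support. A
#' `+ log((M - 1)!)` relabeling-degeneracy correction is added (the first
#' path is the reference and does not participate in the degeneracy). Error
#' bars are the estimator's standard deviation propagated through the
#' logarithm, hence asymmetric.
#'
#' @param data An `fp_binned` object.
#' @param fit The `fp_fit` for this data and order.
#' @param cfg An [is_config()].
#' @param Sigma Optional precomputed [proposal_covariance()].
#' @return A one-row tibble with `M`, `log_evidence`, `err_lo`, `err_hi`,
#'   `ess`, `rel_se`, `n_samples`, `converged`.
#' @export
log_marginal_likelihood <- function(data, fit, cfg = is_config(), Sigma = NULL) {
  is_res <- importance_sample(data, fit, cfg, Sigma)
  evidence_from_lw(is_res$lw, is_res$log_f_star, fit$M, cfg)
}

evidence_from_lw <- function(lw, log_f_star, M, cfg) {
  N <- length(lw)
  finite <- lw[is.finite(lw)]
  if (length(finite) == 0L) {
    stop("importance sampling failed: no in-support draws", call. = FALSE)
  }
  s1 <- logsumexp(finite)           # log sum w
  s2 <- logsumexp(2 * finite)       # log sum w^2
  log_mean <- s1 - log(N)
  log_evidence <- log_f_star + log_mean + lgamma(M)
  # sd of the mean: sqrt((mean(w^2) - mean(w)^2) / N), in log scale
  a <- s2 - log(N)
  b <- 2 * log_mean
  rel_se <- if (a > b) {
    exp(0.5 * (a + log1p(-exp(b - a))) - 0.5 * log(N) - log_mean)
  } else 0
  err_hi <- log1p(rel_se)
  err_lo <- if (rel_se < 1) -log1p(-rel_se) else Inf
  ess <- exp(2 * s1 - s2)
  converged <- rel_se <= cfg$rel_se_warn
  if (!converged) {
    warning(sprintf(
      "importance-sampling relative SE %.2f exceeds %.2f (M = %d); evidence may be unreliable",
      rel_se, cfg$rel_se_warn, M), call. = FALSE)
  }
  tibble::tibble(M = M, log_evidence = log_evidence, err_lo = err_lo,
                 err_hi = err_hi, ess = ess, rel_se = rel_se,
                 n_samples = N, converged = converged)
}

derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + 104729 * as.numeric(k)) %% 2147483587)
}

#' Bayesian model selection over the multi-path hierarchy
#'
#' Fits and scores models with `M = 1..M_max` completion paths, warm-starting
#' each order from the previous fit, and selects the order with the highest
#' log marginal likelihood (ties broken toward smaller `M`, favoring
#' parsimony). All orders are assumed a priori equally likely.
#'
#' @param times Completion-time sample (ms): numeric vector or data frame
#'   with a `value` column.
#' @param dt Temporal resolution (ms) used to bin the sample.
#' @param M_max Largest path count to try (>= 1).
#' @param priors A [prior_config()].
#' @param fit_cfg A [fit_config()].
#' @param is_cfg An [is_config()]. Per-order seeds are derived from
#'   `is_cfg$seed` so orders can be recomputed independently.
#' @return An object of class `fp_selection`: `per_M` tibble (one row per
#'   order, with evidence and asymmetric errors), `fits` (list of `fp_fit`),
#'   `covariances`, `best_M`, `M_max`, `dt`.
#' @examples
#' \donttest{
#' ts <- sample_fp_times(fp_model(tau = 5, L = 2), 2000, seed = 1)
#' sel <- select_model(ts, dt = 0.5, M_max = 2,
#'                     fit_cfg = fit_config(n_starts = 2),
#'                     is_cfg = is_config(n_samples = 2000))
#' tidy(sel)
#' }
#' @export
select_model <- function(times, dt, M_max, priors = prior_config(),
                         fit_cfg = fit_config(), is_cfg = is_config()) {
  stopifnot(M_max >= 1)
  data <- if (is_fp_binned(times)) times else bin_isi(times, dt)
  fits <- vector("list", M_max)
  covs <- vector("list", M_max)
  rows <- vector("list", M_max)
  prev <- NULL
  for (M in seq_len(M_max)) {
    res <- tryCatch({
      fcfg <- fit_cfg
      fcfg$seed <- derive_seed(fit_cfg$seed, M)
      fit <- fit_mle(data, M, priors, fcfg, warm = prev)
      icfg <- is_cfg
      icfg$seed <- derive_seed(is_cfg$seed, 1000L + M)
      Sigma <- proposal_covariance(fit, data, icfg)
      ev <- log_marginal_likelihood(data, fit, icfg, Sigma)
      list(fit = fit, Sigma = Sigma, ev = ev)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      rows[[M]] <- tibble::tibble(M = M, log_evidence = NA_real_,
                                  err_lo = NA_real_, err_hi = NA_real_,
                                  ess = NA_real_, rel_se = NA_real_,
                                  n_samples = NA_integer_, converged = FALSE,
                                  error = conditionMessage(res))
      next
    }
    fits[[M]] <- res$fit
    covs[[M]] <- res$Sigma
    rows[[M]] <- dplyr::mutate(res$ev, error = NA_character_)
    prev <- res$fit
  }
  per_M <- dplyr::bind_rows(rows)
  ok <- which(!is.na(per_M$log_evidence))
  if (length(ok) == 0L) stop("no model order could be scored", call. = FALSE)
  best_M <- ok[which.max(per_M$log_evidence[ok])]
  structure(
    list(per_M = per_M, fits = fits, covariances = covs,
         best_M = best_M, M_max = as.integer(M_max), dt = data$dt,
         data = data, priors = priors, fit_cfg = fit_cfg, is_cfg = is_cfg),
    class = "fp_selection"
  )
}

#' @export
print.fp_selection <- function(x, ...) {
  cat(sprintf("<fp_selection> best M = %d of 1..%d\n", x$best_M, x$M_max))
  print(x$per_M, ...)
  invisible(x)
}

#' Tidy a model-selection result: one row per model order
#'
#' @param x An `fp_selection`.
#' @param ... Unused.
#' @return The per-order evidence tibble with a `best` flag.
#' @method tidy fp_selection
#' @export
tidy.fp_selection <- function(x, ...) {
  dplyr::mutate(x$per_M, best = .data$M == x$best_M)
}

#' One-row summary of a model selection
#'
#' @param x An `fp_selection`.
#' @param ... Unused.
#' @return A tibble with `best_M`, its evidence, `M_max`, and data size.
#' @method glance fp_selection
#' @export
glance.fp_selection <- function(x, ...) {
  row <- x$per_M[x$per_M$M == x$best_M, ]
  tibble::tibble(best_M = x$best_M, log_evidence = row$log_evidence,
                 err_lo = row$err_lo, err_hi = row$err_hi,
                 M_max = x$M_max, n = x$data$n_total, dt = x$dt)
}

#' Joint model selection across experimental conditions
#'
#' Scores each order on every condition independently (each condition keeps
#' its own parameters) and sums the per-condition log evidences; the joint
#' best order maximizes the total.
#'
#' @param datasets A data frame with `condition` and `value` columns, or a
#'   named list of completion-time vectors.
#' @inheritParams select_model
#' @return An object of class `fp_selection_multi`: `per_condition` (named
#'   list of `fp_selection`), `totals` (tibble of summed evidences per `M`),
#'   `best_M`.
#' @export
select_model_multi <- function(datasets, dt, M_max, priors = prior_config(),
                               fit_cfg = fit_config(), is_cfg = is_config()) {
  samples <- coerce_condition_samples(datasets)
  if (length(samples) < 1L) stop("need at least one dataset", call. = FALSE)
  sels <- vector("list", length(samples))
  names(sels) <- names(samples)
  for (j in seq_along(samples)) {
    cfg_j <- is_cfg
    cfg_j$seed <- derive_seed(is_cfg$seed, 5000L + j)
    fit_j <- fit_cfg
    fit_j$seed <- derive_seed(fit_cfg$seed, 6000L + j)
    sels[[j]] <- select_model(samples[[j]], dt, M_max, priors, fit_j, cfg_j)
  }
  totals <- dplyr::bind_rows(lapply(names(sels), function(nm) {
    dplyr::mutate(sels[[nm]]$per_M, condition = nm)
  }))
  totals <- dplyr::summarise(
    dplyr::group_by(totals, .data$M),
    log_evidence = sum(.data$log_evidence),
    err_lo = sqrt(sum(.data$err_lo^2)),
    err_hi = sqrt(sum(.data$err_hi^2)),
    n_conditions = dplyr::n(),
    .groups = "drop"
  )
  ok <- which(!is.na(totals$log_evidence))
  best_M <- totals$M[ok][which.max(totals$log_evidence[ok])]
  structure(
    list(per_condition = sels, totals = totals, best_M = best_M,
         M_max = as.integer(M_max)),
    class = "fp_selection_multi"
  )
}

coerce_condition_samples <- function(datasets) {
  if (is.data.frame(datasets)) {
    if (!all(c("condition", "value") %in% names(datasets))) {
      stop("data frame input needs `condition` and `value` columns",
           call. = FALSE)
    }
    split(datasets$value, datasets$condition)
  } else if (is.list(datasets)) {
    if (is.null(names(datasets))) {
      names(datasets) <- paste0("condition_", seq_along(datasets))
    }
    lapply(datasets, as.numeric)
  } else {
    stop("`datasets` must be a data frame or a list of samples", call. = FALSE)
  }
}

#' @export
print.fp_selection_multi <- function(x, ...) {
  cat(sprintf("<fp_selection_multi> %d conditions, joint best M = %d\n",
              length(x$per_condition), x$best_M))
  print(x$totals, ...)
  invisible(x)
}

#' Tidy a multi-condition selection: summed evidences per order
#'
#' @param x An `fp_selection_multi`.
#' @param ... Unused.
#' @return The totals tibble with a `best` flag.
#' @method tidy fp_selection_multi
#' @export
tidy.fp_selection_multi <- function(x, ...) {
  dplyr::mutate(x$totals, best = .data$M == x$best_M)
}
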