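#' Multi-path completion-time mixture model
#'
#' Constructs a first-passage (FP) time model with `M` independent completion
#' paths. Path `i` is a chain of `L[i]` sequential states with mean per-state
#' dwell time `tau[i]` (ms), so its completion time is Gamma-distributed with
#' shape `L[i]` and scale `tau[i]`. `L` may be any positive real; integer `L`
#' recovers the Erlang case. Paths beyond the first carry relative flux
#' weights `x`, from which the path probabilities `p` are derived (see
#' [mixture_weights()]): the first path is the reference with unit flux.
#'
#' All times are in milliseconds throughout the package; unit conversion is
#' the caller's responsibility.
#'
#' @param tau Numeric vector of per-path mean inter-state transition times
#'   (ms, > 0), length `M`.
#' @param L Numeric vector of per-path state counts (> 0, real), length `M`.
#' @param x Numeric vector of relative flux weights for paths `2..M`
#'   (dimensionless, >= 0), length `M - 1`. Empty for `M = 1`.
#' @return An object of class `fp_model` with fields `M`, `tau`, `L`, `x`.
#' @examples
#' m <- fp_model(tau = c(2.5, 3.2), L = c(4, 25), x = 2 / 3)
#' tidy(m)
#' @export
fp_model <- function(tau, L, x = numeric(0)) {
  tau <- as.numeric(tau)
  L <- as.numeric(L)
  x <- as.numeric(x)
  if (length(tau) < 1L || length(tau) != length(L)) {
    stop("`tau` and `L` must have equal positive length", call. = FALSE)
  }
  if (length(x) != length(tau) - 1L) {
    stop("`x` must have length M - 1", call. = FALSE)
  }
  if (any(!is.finite(tau)) || any(tau <= 0)) {
    stop("all `tau` must be finite and > 0", call. = FALSE)
  }
  if (any(!is.finite(L)) || any(L <= 0)) {
    stop("all `L` must be finite and > 0", call. = FALSE)
  }
  if (length(x) && (any(!is.finite(x)) || any(x < 0))) {
    stop("all `x` must be finite and >= 0", call. = FALSE)
  }
  structure(
    list(M = length(tau), tau = tau, L = L, x = x),
    class = "fp_model"
  )
}

#' @export
print.fp_model <- function(x, ...) {
  cat(sprintf("<fp_model> M = %d completion path(s)\n", x$M))
  print(path_summaries(x), ...)
  invisible(x)
}

is_fp_model <- function(x) inherits(x, "fp_model")

stopifnot_model <- function(model) {
  if (!is_fp_model(model)) stop("`model` must be an fp_model", call. = FALSE)
  invisible(model)
}

#' Single-path Gamma completion-time density
#'
#' Density of the completion time of one path: a chain of `L` states with
#' mean dwell `tau` per state, i.e. the Gamma(shape `L`, scale `tau`) density.
#'
#' @param t Non-negative time(s), ms.
#' @param tau Mean inter-state transition time, ms (> 0).
#' @param L Number of states (> 0, real).
#' @param log Return the log density?
#' @return Density values (1/ms), or log densities.
#' @export
path_density <- function(t, tau, L, log = FALSE) {
  check_path_pars(tau, L)
  if (any(t < 0)) stop("`t` must be >= 0", call. = FALSE)
  stats::dgamma(t, shape = L, scale = tau, log = log)
}

#' Single-path Gamma completion-time CDF
#'
#' @inheritParams path_density
#' @param lower.tail If `FALSE`, return the survival probability.
#' @return `P(T <= t)` for the Gamma path.
#' @export
path_cdf <- function(t, tau, L, lower.tail = TRUE) {
  check_path_pars(tau, L)
  if (any(t < 0)) stop("`t` must be >= 0", call. = FALSE)
  stats::pgamma(t, shape = L, scale = tau, lower.tail = lower.tail)
}

check_path_pars <- function(tau, L) {
  if (any(!is.finite(tau)) || any(tau <= 0)) {
    stop("`tau` must be finite and > 0", call. = FALSE)
  }
  if (any(!is.finite(L)) || any(L <= 0)) {
    stop("`L` must be finite and > 0", call. = FALSE)
  }
  invisible(NULL)
}

#' Path probabilities from relative flux weights
#'
#' The first path is the reference with unit flux; paths `2..M` have relative
#' fluxes `x`. Probabilities are `p1 = 1 / (1 + sum(x))` and
#' `p_i = x_i / (1 + sum(x))` for `i >= 2`.
#'
#' @param x Numeric vector of relative flux weights (>= 0), possibly empty.
#' @return Probability vector of length `length(x) + 1`, summing to 1.
#' @export
mixture_weights <- function(x) {
  x <- as.numeric(x)
  if (length(x) && (any(!is.finite(x)) || any(x < 0))) {
    stop("all `x` must be finite and >= 0", call. = FALSE)
  }
  c(1, x) / (1 + sum(x))
}

#' Mixture completion-time density
#'
#' Convex combination of the per-path Gamma densities with weights derived
#' from the model's flux parameters.
#'
#' @param t Non-negative time(s), ms.
#' @param model An [fp_model()].
#' @param log Return the log density?
#' @return Density values (1/ms).
#' @export
mixture_density <- function(t, model, log = FALSE) {
  stopifnot_model(model)
  if (any(t < 0)) stop("`t` must be >= 0", call. = FALSE)
  p <- mixture_weights(model$x)
  # log-domain accumulation: stable for large L where densities under/overflow
  lp <- vapply(
    seq_len(model$M),
    function(i) log(p[i]) + stats::dgamma(t, shape = model$L[i],
                                          scale = model$tau[i], log = TRUE),
    numeric(length(t))
  )
  lp <- matrix(lp, nrow = length(t))
  out <- apply(lp, 1L, logsumexp)
  if (log) out else exp(out)
}

#' Mixture CDF
#'
#' @inheritParams mixture_density
#' @return `P(T <= t)` under the mixture.
#' @export
mixture_cdf <- function(t, model) {
  stopifnot_model(model)
  if (any(t < 0)) stop("`t` must be >= 0", call. = FALSE)
  p <- mixture_weights(model$x)
  cdfs <- vapply(
    seq_len(model$M),
    function(i) stats::pgamma(t, shape = model$L[i], scale = model$tau[i]),
    numeric(length(t))
  )
  as.numeric(matrix(cdfs, nrow = length(t)) %*% p)
}

#' Probability that a completion time falls in a bin
#'
#' Probability mass of the mixture on the half-open interval `(lo, hi]`.
#' The `"exact"` method differences the path CDFs; the `"midpoint"` method
#' approximates each path integral by density at the bin midpoint times the
#' bin width (the small-`dt` approximation used when fitting quantized data).
#'
#' @param lo,hi Bin edges, ms, with `0 <= lo < hi`. Vectorized.
#' @param model An [fp_model()].
#' @param method `"exact"` (default) or `"midpoint"`.
#' @return Probabilities in `[0, 1]`.
#' @export
bin_probability <- function(lo, hi, model, method = c("exact", "midpoint")) {
  stopifnot_model(model)
  method <- match.arg(method)
  if (length(lo) != length(hi)) stop("`lo` and `hi` lengths differ", call. = FALSE)
  if (any(lo < 0) || any(lo >= hi)) {
    stop("bins must satisfy 0 <= lo < hi", call. = FALSE)
  }
  if (method == "exact") {
    p <- mixture_weights(model$x)
    acc <- numeric(length(lo))
    for (i in seq_len(model$M)) {
      acc <- acc + p[i] * (stats::pgamma(hi, shape = model$L[i], scale = model$tau[i]) -
                             stats::pgamma(lo, shape = model$L[i], scale = model$tau[i]))
    }
    pmin(pmax(acc, 0), 1)
  } else {
    pmin(mixture_density((lo + hi) / 2, model) * (hi - lo), 1)
  }
}

# Log bin probability with an underflow fallback: where the exact CDF
# difference underflows to zero, substitute the midpoint log-density
# approximation evaluated fully in the log domain.
log_bin_probability <- function(lo, hi, model) {
  pr <- bin_probability(lo, hi, model, method = "exact")
  out <- log(pr)
  bad <- !is.finite(out)
  if (any(bad)) {
    out[bad] <- mixture_density((lo[bad] + hi[bad]) / 2, model, log = TRUE) +
      log(hi[bad] - lo[bad])
  }
  out
}

#' Draw i.i.d. completion times from a mixture model
#'
#' Each draw picks a path with probability `p_i`, then draws the path's
#' Gamma completion time. Identical seeds give identical samples.
#'
#' @param model An [fp_model()].
#' @param n Number of draws (>= 1).
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return Numeric vector of `n` completion times (ms).
#' @export
sample_fp_times <- function(model, n, seed = NULL) {
  stopifnot_model(model)
  if (length(n) != 1L || !is.finite(n) || n < 1) {
    stop("`n` must be a single integer >= 1", call. = FALSE)
  }
  n <- as.integer(n)
  draw <- function() {
    path <- sample.int(model$M, n, replace = TRUE, prob = mixture_weights(model$x))
    stats::rgamma(n, shape = model$L[path], scale = model$tau[path])
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Per-path summary statistics
#'
#' For each path: mean completion time `T = tau * L` (ms), coefficient of
#' variation `CV = 1 / sqrt(L)`, and path probability `p`.
#'
#' @param model An [fp_model()].
#' @return A tibble with columns `path`, `tau`, `L`, `x`, `weight`,
#'   `mean_completion`, `cv`.
#' @export
path_summaries <- function(model) {
  stopifnot_model(model)
  tibble::tibble(
    path = seq_len(model$M),
    tau = model$tau,
    L = model$L,
    x = c(1, model$x),
    weight = mixture_weights(model$x),
    mean_completion = model$tau * model$L,
    cv = 1 / sqrt(model$L)
  )
}

#' Rebuild a model from per-path summaries
#'
#' Inverts [path_summaries()]: `L = 1/CV^2`, `tau = T/L`, `x_i = p_i/p_1`.
#' Weights are renormalized to sum to one before conversion.
#'
#' @param summaries A data frame with columns `mean_completion`, `cv`,
#'   `weight` (one row per path, first row the reference path).
#' @return An [fp_model()].
#' @export
fp_model_from_summaries <- function(summaries) {
  need <- c("mean_completion", "cv", "weight")
  if (!all(need %in% names(summaries))) {
    stop("`summaries` needs columns mean_completion, cv, weight", call. = FALSE)
  }
  Tm <- summaries$mean_completion
  cv <- summaries$cv
  w <- summaries$weight / sum(summaries$weight)
  if (any(Tm <= 0) || any(cv <= 0)) {
    stop("summaries must be positive", call. = FALSE)
  }
  L <- 1 / cv^2
  tau <- Tm / L
  x <- if (length(w) > 1L) w[-1L] / w[1L] else numeric(0)
  fp_model(tau = tau, L = L, x = x)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}
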