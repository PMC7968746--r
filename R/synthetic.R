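#' Generate a time-quantized synthetic completion-time sample
#'
#' Draws i.i.d. completion times from a mixture model and snaps each draw to
#' the upper edge of its `(lo, hi]` bin of width `dt`, emulating the
#' quantization of experimental recordings at the acquisition resolution.
#'
#' @param model An [fp_model()].
#' @param n Number of events (>= 1).
#' @param dt Temporal resolution (ms, > 0).
#' @param seed Integer seed.
#' @return Numeric vector of `n` quantized completion times (ms), each a
#'   positive multiple of `dt`.
#' @export
generate_dataset <- function(model, n, dt, seed = NULL) {
  if (length(dt) != 1L || !is.finite(dt) || dt <= 0) {
    stop("`dt` must be a single value > 0", call. = FALSE)
  }
  raw <- sample_fp_times(model, n, seed)
  pmax(ceiling(raw / dt - 1e-12), 1) * dt
}

#' Condition-indexed synthetic family generator
#'
#' Describes a family of mixture models whose per-path summaries
#' `(mean completion time, CV, weight)` vary linearly with an external
#' scalar condition (the injected-current analogue): at condition `c`, path
#' summaries are `base + slope * c`, with weights renormalized. Used to test
#' multi-condition selection, path matching, and prediction end to end
#' against known ground truth.
#'
#' @param base_summaries Data frame with one row per path and columns
#'   `mean_completion` (ms), `cv`, `weight` — the summaries at condition 0.
#' @param slopes Data frame of the same shape: per-unit-condition linear
#'   coefficients for each summary.
#' @param conditions Numeric condition values to generate at.
#' @param dt Temporal resolution (ms).
#' @param n_per_condition Events per condition.
#' @param seed Integer seed.
#' @return A list of class `fp_condition_generator`.
#' @export
condition_generator <- function(base_summaries, slopes, conditions, dt,
                                n_per_condition, seed = 1L) {
  need <- c("mean_completion", "cv", "weight")
  if (!all(need %in% names(base_summaries)) || !all(need %in% names(slopes))) {
    stop("`base_summaries` and `slopes` need columns mean_completion, cv, weight",
         call. = FALSE)
  }
  if (nrow(base_summaries) != nrow(slopes)) {
    stop("`base_summaries` and `slopes` must have one row per path each",
         call. = FALSE)
  }
  gen <- structure(
    list(base_summaries = tibble::as_tibble(base_summaries[need]),
         slopes = tibble::as_tibble(slopes[need]),
         conditions = sort(as.numeric(conditions)), dt = dt,
         n_per_condition = as.integer(n_per_condition),
         seed = as.integer(seed)),
    class = "fp_condition_generator"
  )
  for (cond in gen$conditions) condition_model(gen, cond)  # validates
  gen
}

#' Summaries and model of a condition generator at a given condition
#'
#' @param gen An [condition_generator()].
#' @param condition Scalar condition value.
#' @return `condition_summaries()`: a tibble of per-path summaries;
#'   `condition_model()`: the corresponding [fp_model()].
#' @export
condition_summaries <- function(gen, condition) {
  s <- gen$base_summaries + gen$slopes * condition
  if (any(s$mean_completion <= 0) || any(s$cv <= 0) || any(s$weight <= 0)) {
    stop(sprintf("generator yields non-positive summaries at condition %g",
                 condition), call. = FALSE)
  }
  dplyr::mutate(tibble::as_tibble(s), weight = .data$weight / sum(.data$weight))
}

#' @rdname condition_summaries
#' @export
condition_model <- function(gen, condition) {
  fp_model_from_summaries(condition_summaries(gen, condition))
}

#' Generate one dataset per condition
#'
#' @param gen An [condition_generator()].
#' @return A named list of quantized samples, one per condition (names are
#'   the condition values); attribute `models` holds the generating models.
#' @export
make_condition_family <- function(gen) {
  stopifnot(inherits(gen, "fp_condition_generator"))
  out <- vector("list", length(gen$conditions))
  models <- vector("list", length(gen$conditions))
  for (j in seq_along(gen$conditions)) {
    models[[j]] <- condition_model(gen, gen$conditions[j])
    out[[j]] <- generate_dataset(models[[j]], gen$n_per_condition, gen$dt,
                                 seed = derive_seed(gen$seed, j))
  }
  names(out) <- format(gen$conditions, trim = TRUE)
  attr(out, "conditions") <- gen$conditions
  attr(out, "models") <- models
  out
}

#' Completeness construction: a mixture reproducing a histogram
#'
#' Builds, for any binned sample, an explicit mixture with one path per
#' occupied bin whose bin probabilities match the empirical frequencies
#' within `eps`: path `i` has weight `p_i = n_i/N`, mean completion time at
#' the bin center `T_i = t_i - dt/2`, and variance `sigma_i^2 =
#' dt^2 * eps_i / 4` with `eps_i = min(eps / sum_{j != i} p_j, eps / p_i)`,
#' so Chebyshev's inequality confines each path's mass to its bin. This
#' witnesses that the multi-path family can approximate any discretized
#' distribution arbitrarily well (the worst case; unoccupied bins need no
#' path).
#'
#' @param counts An `fp_binned` object with at least one occupied bin.
#' @param eps Tolerance probability, `0 < eps < 1`.
#' @return An [fp_model()] with one path per occupied bin, in bin order.
#' @export
completeness_construction <- function(counts, eps) {
  stopifnot_binned(counts)
  if (length(eps) != 1L || eps <= 0 || eps >= 1) {
    stop("`eps` must lie in (0, 1)", call. = FALSE)
  }
  occ <- which(counts$counts > 0L)
  p <- counts$counts[occ] / counts$n_total
  centers <- counts$edges[occ + 1L] - counts$dt / 2
  eps_i <- pmin(ifelse(1 - p > 0, eps / (1 - p), Inf), eps / p)
  sigma2 <- counts$dt^2 * eps_i / 4
  L <- centers^2 / sigma2
  tau <- sigma2 / centers
  if (any(!is.finite(L)) || any(L > 1e12)) {
    bad <- occ[which.max(L)]
    stop(sprintf(
      "construction infeasible: bin %d requires L = %.3g beyond the representable range; increase eps",
      bad, max(L)), call. = FALSE)
  }
  fp_model(tau = tau, L = L, x = p[-1L] / p[1L])
}
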