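#' Early-time decomposition of the completion CDF into paths
#'
#' Restricts attention to the `n_events` fastest events and compares the
#' empirical cumulative probability (rank `i` at probability `i/N`) with the
#' fitted model's CDF and its per-path weighted contributions
#' `p_i * path_cdf(t)`. At short times a Gamma path's CDF grows like
#' `t^L`, so the path(s) dominating this window carry mechanistic
#' information about the shortest completion route.
#'
#' @param model A fitted [fp_model()] for these data.
#' @param times The completion-time sample the model was fitted to (ms).
#' @param n_events Number of early events to analyze (default 50).
#' @return An object of class `fp_cdf_decomp`: list with `events` (tibble
#'   `event`, `t`, `emp_p`, `model_cdf`), `paths` (tibble `event`, `t`,
#'   `path`, `weighted_cdf`), `model`, `n_events`, `n_total`.
#' @export
early_cdf_decomposition <- function(model, times, n_events = 50L) {
  stopifnot_model(model)
  times <- coerce_times(times)
  N <- length(times)
  if (n_events > N) stop("`n_events` exceeds the sample size", call. = FALSE)
  if (n_events < 1L) stop("`n_events` must be >= 1", call. = FALSE)
  t_ord <- sort(times)[seq_len(n_events)]
  p <- mixture_weights(model$x)
  events <- tibble::tibble(
    event = seq_len(n_events),
    t = t_ord,
    emp_p = seq_len(n_events) / N,
    model_cdf = mixture_cdf(t_ord, model)
  )
  paths <- dplyr::bind_rows(lapply(seq_len(model$M), function(i) {
    tibble::tibble(
      event = seq_len(n_events), t = t_ord, path = i,
      weighted_cdf = p[i] * path_cdf(t_ord, model$tau[i], model$L[i])
    )
  }))
  structure(
    list(events = events, paths = paths, model = model,
         n_events = as.integer(n_events), n_total = N),
    class = "fp_cdf_decomp"
  )
}

#' Lower bound on the internal state count of any mechanistic model
#'
#' Identifies the smallest set of completion paths whose combined weighted
#' CDF reaches the empirical probability of the `n_events`-th earliest event
#' (paths added greedily by their contribution at the end of the early
#' window). Since a Gamma path with `L` states has CDF `~ t^L` at short
#' times, any Markovian mechanistic model reproducing the early-time data
#' needs at least `ceil(min L)` internal states over that dominant set (the
#' weakest, hence safest, bound).
#'
#' @inheritParams early_cdf_decomposition
#' @param single_path_factor A single path "explains" the window when its
#'   weighted CDF is within this multiplicative factor of the total model
#'   CDF across the window (default 2).
#' @return An object of class `fp_bound`: list with `n_events`,
#'   `dominant_paths`, `min_L`, `state_bound`, `single_path_explains`,
#'   `exponent_fit` (log-log least-squares slope of the empirical early
#'   CDF, a diagnostic requiring high temporal resolution), `poor_early_fit`,
#'   and the underlying `decomposition`.
#' @export
min_states_lower_bound <- function(model, times, n_events = 50L,
                                   single_path_factor = 2) {
  dec <- early_cdf_decomposition(model, times, n_events)
  t_last <- dec$events$t[n_events]
  target <- dec$events$emp_p[n_events]
  at_last <- dec$paths[dec$paths$event == n_events, ]
  ord <- order(at_last$weighted_cdf, decreasing = TRUE)
  cum <- cumsum(at_last$weighted_cdf[ord])
  k <- which(cum >= min(target, dec$events$model_cdf[n_events]))[1L]
  if (is.na(k)) k <- length(ord)
  dominant <- sort(at_last$path[ord[seq_len(k)]])
  min_L <- min(model$L[dominant])

  # does one path alone track the total model CDF across the window?
  single <- FALSE
  pos <- dec$events$model_cdf > 0
  if (any(pos)) {
    for (i in seq_len(model$M)) {
      wc <- dec$paths$weighted_cdf[dec$paths$path == i][pos]
      tot <- dec$events$model_cdf[pos]
      if (all(wc * single_path_factor >= tot)) {
        single <- TRUE
        break
      }
    }
  }

  poor_early_fit <- dec$events$model_cdf[n_events] < dec$events$emp_p[1L]
  if (poor_early_fit) {
    warning("model CDF lies below the first event's empirical probability over the early window",
            call. = FALSE)
  }
  ok <- dec$events$t > 0 & dec$events$emp_p > 0
  exponent_fit <- if (sum(ok) >= 2) {
    unname(stats::coef(stats::lm(log(emp_p) ~ log(t), data = dec$events[ok, ]))[2L])
  } else {
    NA_real_
  }
  structure(
    list(n_events = as.integer(n_events), dominant_paths = dominant,
         min_L = min_L,
         state_bound = max(1L, as.integer(ceiling(0.95 * min_L))),
         single_path_explains = single, exponent_fit = exponent_fit,
         poor_early_fit = poor_early_fit, decomposition = dec),
    class = "fp_bound"
  )
}

#' @export
print.fp_bound <- function(x, ...) {
  cat(sprintf(
    "<fp_bound> first %d events explained by path(s) %s; >= %d internal states required\n",
    x$n_events, paste(x$dominant_paths, collapse = ", "), x$state_bound))
  invisible(x)
}

#' Tidy a state-count bound
#'
#' @param x An `fp_bound`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @method tidy fp_bound
#' @export
tidy.fp_bound <- function(x, ...) {
  tibble::tibble(
    n_events = x$n_events,
    dominant_paths = paste(x$dominant_paths, collapse = ","),
    min_L = x$min_L,
    state_bound = x$state_bound,
    single_path_explains = x$single_path_explains,
    exponent_fit = x$exponent_fit,
    poor_early_fit = x$poor_early_fit
  )
}
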