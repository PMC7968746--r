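#' Establish path correspondence across conditions
#'
#' Given models fitted independently at several values of an external scalar
#' condition (e.g. injected current, nA), orders each model's paths by a
#' per-path summary so that the k-th path means "the k-th fastest (or least
#' variable, or least likely) path" at every condition. Ties are broken by
#' the remaining keys in the fixed cycle mean completion time, CV, weight.
#'
#' @param models List of [fp_model()] or `fp_fit` objects, all with the same
#'   number of paths.
#' @param conditions Numeric condition value per model.
#' @param key Ordering key: `"mean_completion"` (default), `"cv"`, or
#'   `"weight"`.
#' @return An object of class `fp_condition_series`: a tibble with one row
#'   per condition and path (columns `condition`, `path`, `mean_completion`,
#'   `cv`, `weight`, `tau`, `L`), plus attributes `models` (reordered),
#'   `permutations`, and `key`.
#' @export
match_paths <- function(models, conditions,
                        key = c("mean_completion", "cv", "weight")) {
  key <- match.arg(key)
  models <- lapply(models, function(m) if (inherits(m, "fp_fit")) m$model else m)
  if (!all(vapply(models, is_fp_model, logical(1)))) {
    stop("`models` must be fp_model or fp_fit objects", call. = FALSE)
  }
  if (length(models) != length(conditions)) {
    stop("`models` and `conditions` lengths differ", call. = FALSE)
  }
  M <- models[[1L]]$M
  if (!all(vapply(models, function(m) m$M, integer(1)) == M)) {
    stop("all models must share the same number of paths M", call. = FALSE)
  }
  ord_cond <- order(conditions)
  models <- models[ord_cond]
  conditions <- conditions[ord_cond]
  cycle <- c("mean_completion", "cv", "weight")
  keys <- c(key, setdiff(cycle, key))
  perms <- lapply(models, function(m) {
    s <- path_summaries(m)
    do.call(order, unname(s[keys]))
  })
  rows <- purrr::map2(seq_along(models), perms, function(j, pr) {
    s <- path_summaries(models[[j]])[pr, ]
    dplyr::mutate(s, path = dplyr::row_number(), condition = conditions[j],
                  .before = 1L)
  })
  out <- dplyr::select(dplyr::bind_rows(rows), "condition", "path", "tau",
                       "L", "weight", "mean_completion", "cv")
  class(out) <- c("fp_condition_series", class(out))
  attr(out, "models") <- models
  attr(out, "conditions") <- conditions
  attr(out, "permutations") <- perms
  attr(out, "key") <- key
  out
}

#' Predict a model at an unobserved condition
#'
#' Linearly interpolates (inside the observed condition range) or
#' extrapolates (outside, from the two nearest observed conditions) each
#' matched path's summaries `(mean completion time, CV, weight)` in the
#' condition variable, then back-transforms to model parameters via
#' `L = 1/CV^2`, `tau = T/L`, `x_i = p_i/p_1`. Interpolated weights are
#' renormalized to sum to one; non-positive interpolated summaries are
#' floored at `1e-6` of the nearest observed value, and a degenerate
#' prediction (flooring on a path with weight > 0.01) is an error.
#'
#' @param series An [match_paths()] result.
#' @param condition_new Scalar condition at which to predict.
#' @return An object of class `fp_prediction`: list with `condition_new`,
#'   `model` (the predicted [fp_model()]), `summaries`, `mode`
#'   (`"interpolated"` or `"extrapolated"`), `source_conditions`.
#' @export
interpolate_model <- function(series, condition_new) {
  stopifnot(inherits(series, "fp_condition_series"), length(condition_new) == 1L)
  conds <- attr(series, "conditions")
  if (length(conds) < 2L) {
    stop("need at least two conditions to interpolate", call. = FALSE)
  }
  inside <- condition_new >= min(conds) && condition_new <= max(conds)
  mode <- if (condition_new > min(conds) && condition_new < max(conds)) {
    "interpolated"
  } else {
    "extrapolated"
  }
  # bracketing pair inside the range; nearest edge pair outside
  if (inside) {
    hi_i <- min(which(conds >= condition_new))
    lo_i <- if (conds[hi_i] == condition_new) hi_i else hi_i - 1L
    if (lo_i == hi_i) lo_i <- max(hi_i - 1L, 1L)
  } else if (condition_new < min(conds)) {
    lo_i <- 1L; hi_i <- 2L
  } else {
    lo_i <- length(conds) - 1L; hi_i <- length(conds)
  }
  src <- conds[c(lo_i, hi_i)]

  lin <- function(y) {
    y0 <- y[1L]; y1 <- y[2L]
    y0 + (y1 - y0) * (condition_new - src[1L]) / (src[2L] - src[1L])
  }
  floored <- logical(0)
  pred <- dplyr::group_modify(
    dplyr::group_by(series[series$condition %in% src, ], .data$path),
    function(df, key) {
      df <- df[order(df$condition), ]
      out <- tibble::tibble(
        mean_completion = lin(df$mean_completion),
        cv = lin(df$cv),
        weight = lin(df$weight)
      )
      for (col in names(out)) {
        floor_val <- 1e-6 * min(abs(df[[col]]))
        if (out[[col]] <= 0 || out[[col]] < floor_val) {
          out[[col]] <- max(floor_val, 1e-12)
          floored <<- c(floored, stats::setNames(TRUE, col))
          attr(out, paste0("floored_", col)) <- TRUE
        }
      }
      out
    }
  )
  pred <- dplyr::ungroup(pred)
  if (any(pred$weight <= 0)) {
    stop("degenerate prediction: non-positive interpolated weights", call. = FALSE)
  }
  w <- pred$weight / sum(pred$weight)
  if (length(floored) > 0 && any(w > 0.01)) {
    # flooring on a non-negligible path signals the linear trend broke down
    bad <- pred[w > 0.01 & (pred$mean_completion <= 1e-6 * max(pred$mean_completion) |
                              pred$cv <= 1e-9), ]
    if (nrow(bad) > 0) {
      stop("degenerate prediction: floored summaries on a path with weight > 0.01",
           call. = FALSE)
    }
  }
  pred$weight <- w
  model <- fp_model_from_summaries(pred)
  structure(
    list(condition_new = condition_new, model = model, summaries = pred,
         mode = mode, source_conditions = src, key = attr(series, "key")),
    class = "fp_prediction"
  )
}

#' @export
print.fp_prediction <- function(x, ...) {
  cat(sprintf("<fp_prediction> %s model at condition %g (from %g, %g)\n",
              x$mode, x$condition_new, x$source_conditions[1L],
              x$source_conditions[2L]))
  print(path_summaries(x$model))
  invisible(x)
}

#' Jensen-Shannon divergence between two probability vectors
#'
#' `JSD(p, q) = KL(p || m)/2 + KL(q || m)/2` with `m = (p + q)/2`, natural
#' log, bounded by `[0, ln 2]`.
#'
#' @param p,q Probability vectors of equal length, each summing to one
#'   (tolerance `1e-6`; vectors are renormalized before use).
#' @return Divergence in nats.
#' @export
jsd <- function(p, q) {
  if (length(p) != length(q)) stop("`p` and `q` lengths differ", call. = FALSE)
  if (any(p < 0) || any(q < 0)) stop("probabilities must be >= 0", call. = FALSE)
  if (abs(sum(p) - 1) > 1e-6 || abs(sum(q) - 1) > 1e-6) {
    stop("`p` and `q` must each sum to 1", call. = FALSE)
  }
  p <- p / sum(p)
  q <- q / sum(q)
  m <- (p + q) / 2
  kl <- function(a, b) {
    nz <- a > 0
    sum(a[nz] * (log(a[nz]) - log(b[nz])))
  }
  kl(p, m) / 2 + kl(q, m) / 2
}

# common binning of samples/models on (0, Tmax] with an overflow bin
common_bins <- function(dt, t_max) {
  K <- ceiling(t_max / dt)
  dt * (0:K)
}

hist_probs <- function(times, edges) {
  idx <- pmin(ceiling(times / (edges[2L] - edges[1L]) - 1e-12),
              length(edges) - 1L)
  idx[idx < 1L] <- 1L
  c(tabulate(idx, nbins = length(edges) - 1L), 0) / length(times)
}

model_probs <- function(model, edges) {
  pr <- bin_probability(edges[-length(edges)], edges[-1L], model)
  c(pr, max(1 - sum(pr), 0))  # overflow bin keeps the vector normalized
}

#' Bootstrap Jensen-Shannon validation of a predicted model
#'
#' Resamples the validation set with replacement `n_boot` times and computes,
#' per replicate, three JSDs on a common binning (union support, width `dt`,
#' plus an overflow bin): (i) test data vs the bootstrapped validation data
#' (the data-vs-data ceiling), (ii) the bootstrapped validation data vs a
#' model refitted to that replicate (the direct-fit baseline), and (iii) the
#' prediction vs the bootstrapped validation data. Close agreement of the
#' three distributions indicates a good prediction.
#'
#' @param test Completion-time sample (ms) held out from fitting.
#' @param validation Completion-time sample (ms) to bootstrap against.
#' @param predicted The predicted [fp_model()] (or an `fp_prediction`).
#' @param dt Bin width (ms).
#' @param n_boot Number of bootstrap replicates (>= 1).
#' @param seed Integer seed.
#' @param priors,fit_cfg Refit settings for stream (ii); refits keep the
#'   predicted model's `M` and warm-start from a fit to the full validation
#'   sample.
#' @return A tibble with columns `replicate`, `stream` (one of
#'   `"test_vs_boot"`, `"fit_vs_boot"`, `"prediction_vs_boot"`), `jsd`.
#'   Replicates whose refit fails are dropped with a message.
#' @export
evaluate_prediction <- function(test, validation, predicted, dt, n_boot = 100L,
                                seed = 1L, priors = prior_config(),
                                fit_cfg = fit_config(n_starts = 1L)) {
  if (inherits(predicted, "fp_prediction")) predicted <- predicted$model
  stopifnot_model(predicted)
  test <- coerce_times(test)
  validation <- coerce_times(validation)
  stopifnot(n_boot >= 1)
  edges <- common_bins(dt, max(test, validation))
  p_test <- hist_probs(test, edges)
  p_pred <- model_probs(predicted, edges)
  M <- predicted$M

  base_fit <- fit_mle(bin_isi(validation, dt), M, priors, fit_cfg)
  run <- function() {
    rows <- vector("list", n_boot)
    for (b in seq_len(n_boot)) {
      boot <- sample(validation, length(validation), replace = TRUE)
      p_boot <- hist_probs(boot, edges)
      refit <- tryCatch({
        cfg_b <- fit_cfg
        cfg_b$seed <- derive_seed(fit_cfg$seed, b)
        fit_mle(bin_isi(boot, dt), M, priors, cfg_b, warm = base_fit$model)
      }, error = function(e) NULL)
      if (is.null(refit)) {
        message(sprintf("replicate %d: refit failed, dropped", b))
        next
      }
      p_fit <- model_probs(refit$model, edges)
      rows[[b]] <- tibble::tibble(
        replicate = b,
        stream = c("test_vs_boot", "fit_vs_boot", "prediction_vs_boot"),
        jsd = c(jsd(p_test, p_boot), jsd(p_boot, p_fit), jsd(p_pred, p_boot))
      )
    }
    dplyr::bind_rows(rows)
  }
  withr::with_seed(seed, run())
}
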