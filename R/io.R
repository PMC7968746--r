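#' Read a completion-time sample from disk
#'
#' Plain-text files hold one positive time (ms) per line and yield a numeric
#' vector. CSV files with header `condition,value` yield a tibble keyed by
#' condition. Non-numeric or non-positive values are rejected with their
#' line number.
#'
#' @param path Path to the file.
#' @return Numeric vector (plain text) or a tibble with columns `condition`
#'   and `value` (CSV).
#' @export
read_isi <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop(sprintf("empty input file: %s", path), call. = FALSE)
  header <- tolower(gsub("\\s", "", lines[1L]))
  if (identical(header, "condition,value")) {
    body <- lines[-1L]
    if (length(body) == 0L) {
      stop(sprintf("no data rows in %s", path), call. = FALSE)
    }
    parts <- strsplit(body, ",", fixed = TRUE)
    bad <- which(lengths(parts) != 2L)
    if (length(bad)) {
      stop(sprintf("malformed CSV line %d in %s", bad[1L] + 1L, path),
           call. = FALSE)
    }
    cond <- vapply(parts, `[[`, character(1), 1L)
    val <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 2L)))
    check_values(val, path, offset = 1L)
    tibble::tibble(condition = cond, value = val)
  } else {
    val <- suppressWarnings(as.numeric(trimws(lines)))
    check_values(val, path, offset = 0L)
    val
  }
}

check_values <- function(val, path, offset) {
  bad <- which(!is.finite(val))
  if (length(bad)) {
    stop(sprintf("non-numeric value at line %d of %s", bad[1L] + offset, path),
         call. = FALSE)
  }
  neg <- which(val <= 0)
  if (length(neg)) {
    stop(sprintf("non-positive time at line %d of %s", neg[1L] + offset, path),
         call. = FALSE)
  }
  invisible(val)
}

#' Digest of a completion-time sample
#'
#' MD5 of the sample formatted at full precision; used to stamp results with
#' the identity of their input data.
#'
#' @param times Numeric sample or data frame with a `value` column.
#' @return Hex digest string.
#' @export
digest_times <- function(times) {
  times <- coerce_times(times)
  tf <- tempfile(fileext = ".txt")
  on.exit(unlink(tf))
  writeLines(sprintf("%.17g", times), tf)
  unname(tools::md5sum(tf))
}

#' Write a result object to disk
#'
#' Models, fits, selections, predictions and bounds are written as JSON with
#' full numeric precision; curves and JSD tables as CSV. Model JSON follows
#' the schema `{"M": int, "tau": [...], "L": [...], "x": [...]}` and
#' round-trips exactly through [read_model()].
#'
#' @param x The object to write.
#' @param path Output path.
#' @param ... Extra fields spliced into JSON output (e.g. seed, data digest).
#' @return `path`, invisibly.
#' @export
write_result <- function(x, path, ...) UseMethod("write_result")

write_json_full <- function(obj, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  # I(17) significant digits: doubles survive the round trip bit-exactly
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE, na = "null")
  invisible(path)
}

model_to_list <- function(model) {
  list(M = model$M, tau = as.numeric(model$tau), L = as.numeric(model$L),
       x = as.numeric(model$x))
}

#' @export
write_result.fp_model <- function(x, path, ...) {
  write_json_full(c(model_to_list(x), list(...)), path)
}

#' @export
write_result.fp_fit <- function(x, path, ...) {
  obj <- list(
    model = model_to_list(x$model), M = x$M,
    log_f = x$log_f, log_lik = x$log_lik, log_prior = x$log_prior,
    at_boundary = x$at_boundary, starts_used = x$starts_used,
    convergence = x$convergence,
    priors = unclass(x$priors), config = unclass(x$config),
    data_info = x$data_info, ...
  )
  write_json_full(obj, path)
}

#' @export
write_result.fp_selection <- function(x, path, ...) {
  per_M <- lapply(seq_len(nrow(x$per_M)), function(i) {
    row <- as.list(x$per_M[i, ])
    M <- row$M
    if (!is.null(x$fits[[M]])) {
      row$theta <- model_to_list(x$fits[[M]]$model)
      row$at_boundary <- x$fits[[M]]$at_boundary
    }
    row
  })
  obj <- list(best_M = x$best_M, M_max = x$M_max, dt = x$dt,
              per_M = per_M, priors = unclass(x$priors),
              fit_config = unclass(x$fit_cfg), is_config = unclass(x$is_cfg),
              ...)
  write_json_full(obj, path)
}

#' @export
write_result.fp_selection_multi <- function(x, path, ...) {
  obj <- list(best_M = x$best_M, M_max = x$M_max,
              totals = x$totals,
              per_condition = lapply(x$per_condition, function(s) {
                list(best_M = s$best_M, per_M = s$per_M)
              }), ...)
  write_json_full(obj, path)
}

#' @export
write_result.fp_prediction <- function(x, path, ...) {
  obj <- list(condition_new = x$condition_new, mode = x$mode,
              source_conditions = x$source_conditions, key = x$key,
              model = model_to_list(x$model), summaries = x$summaries, ...)
  write_json_full(obj, path)
}

#' @export
write_result.fp_bound <- function(x, path, ...) {
  obj <- as.list(tidy.fp_bound(x))
  obj$dominant_paths <- as.integer(x$dominant_paths)
  obj <- c(obj, list(model = model_to_list(x$decomposition$model), ...))
  write_json_full(obj, path)
}

#' @export
write_result.fp_curve <- function(x, path, ...) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @export
write_result.data.frame <- function(x, path, ...) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' Read a model written by [write_result()]
#'
#' @param path Path to a model JSON file.
#' @return An [fp_model()].
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  # accept wrappers (fits, predictions) that nest the model under $model
  if (is.null(obj$tau) && !is.null(obj$model)) obj <- obj$model
  if (is.null(obj$tau) || is.null(obj$L)) {
    stop(sprintf("%s does not hold a model (need fields tau, L, x)", path),
         call. = FALSE)
  }
  fp_model(tau = obj$tau, L = obj$L,
           x = if (is.null(obj$x)) numeric(0) else obj$x)
}
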