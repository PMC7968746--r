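#' Bin completion times on a uniform grid
#'
#' Discretizes a sample of completion times onto uniform half-open bins
#' `(i*dt, (i+1)*dt]` starting at zero and covering the largest observation,
#' mirroring the quantization of experimental recordings at the acquisition
#' resolution `dt`. Values exactly on an edge fall in the lower bin.
#'
#' @param times Positive completion times (ms), or a data frame with a
#'   `value` column.
#' @param dt Bin width (ms, > 0), the temporal resolution.
#' @return An object of class `fp_binned`: a list with `dt`, `edges`
#'   (length `K + 1`), `counts` (length `K`), and `n_total`.
#' @examples
#' bin_isi(c(0.5, 1.5, 1.7), dt = 1)
#' @export
bin_isi <- function(times, dt) {
  times <- coerce_times(times)
  if (length(times) == 0L) stop("`times` is empty", call. = FALSE)
  if (any(!is.finite(times)) || any(times <= 0)) {
    stop("all `times` must be finite and > 0", call. = FALSE)
  }
  if (length(dt) != 1L || !is.finite(dt) || dt <= 0) {
    stop("`dt` must be a single value > 0", call. = FALSE)
  }
  K <- ceiling(max(times) / dt)
  # (lo, hi] convention: values on an edge land in the lower bin
  idx <- ceiling(times / dt - 1e-12)
  idx[idx < 1L] <- 1L
  counts <- tabulate(idx, nbins = K)
  new_fp_binned(dt = dt, edges = dt * (0:K), counts = counts)
}

new_fp_binned <- function(dt, edges, counts) {
  structure(
    list(dt = dt, edges = edges, counts = as.integer(counts),
         n_total = sum(counts)),
    class = "fp_binned"
  )
}

#' @export
print.fp_binned <- function(x, ...) {
  cat(sprintf("<fp_binned> %d events in %d bins of width %g ms (span 0-%g ms)\n",
              x$n_total, length(x$counts), x$dt, max(x$edges)))
  invisible(x)
}

is_fp_binned <- function(x) inherits(x, "fp_binned")

stopifnot_binned <- function(data) {
  if (!is_fp_binned(data)) stop("`data` must be an fp_binned object", call. = FALSE)
  if (data$n_total < 1L) stop("`data` holds no events", call. = FALSE)
  invisible(data)
}

# interpret vectors, data frames with a `value` column, or fp_binned passthrough
coerce_times <- function(times) {
  if (is.data.frame(times)) {
    if (!"value" %in% names(times)) {
      stop("data frame input needs a `value` column", call. = FALSE)
    }
    times <- times$value
  }
  as.numeric(times)
}

#' Tidy a binned sample
#'
#' @param x An `fp_binned` object.
#' @param ... Unused.
#' @return A tibble with columns `bin`, `lo`, `hi`, `mid`, `count`.
#' @method tidy fp_binned
#' @export
tidy.fp_binned <- function(x, ...) {
  K <- length(x$counts)
  tibble::tibble(
    bin = seq_len(K),
    lo = x$edges[seq_len(K)],
    hi = x$edges[seq_len(K) + 1L],
    mid = (x$edges[seq_len(K)] + x$edges[seq_len(K) + 1L]) / 2,
    count = x$counts
  )
}
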