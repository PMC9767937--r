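#' BOLD time-series set
#'
#' Container for per-unit (voxel) BOLD series sharing a repetition time.
#'
#' @param data units x T numeric matrix.
#' @param tr_seconds repetition time in seconds.
#' @param dummy_frames number of initial discardable frames still present.
#' @param preprocessed logical flag set by [preprocess()].
#' @param basis orthonormal nuisance basis (T x K matrix, intercept included)
#'   that was regressed out by [preprocess()]; fitters project their model
#'   predictions through the same residualizer.
#' @return An object of class `ts_set`.
#' @export
ts_set <- function(data, tr_seconds, dummy_frames = 0L, preprocessed = FALSE,
                   basis = NULL) {
  data <- as.matrix(data)
  if (!all(is.finite(data))) stop("time series must be finite")
  structure(list(data = data, tr_seconds = tr_seconds,
                 dummy_frames = as.integer(dummy_frames),
                 preprocessed = preprocessed, basis = basis),
            class = "ts_set")
}

# Residualize columns of X against an orthonormal basis Q (no-op for NULL).
nuisance_project <- function(X, Q) {
  if (is.null(Q)) return(X)
  X - Q %*% crossprod(Q, X)
}

#' @export
print.ts_set <- function(x, ...) {
  cat(sprintf("Time-series set: %d units x %d frames, TR %.2f s%s\n",
              nrow(x$data), ncol(x$data), x$tr_seconds,
              if (x$preprocessed) " (preprocessed)" else ""))
  invisible(x)
}

#' @export
dim.ts_set <- function(x) dim(x$data)

# Discrete cosine high-pass basis. Term k has frequency k / (2 n tr). Drift
# slower than the run's fundamental frequency is indistinguishable from a
# low-order trend, so at least the two lowest cosine terms are always removed
# in addition to any term whose frequency falls below the cutoff.
dct_basis <- function(n, tr, cutoff_hz) {
  k_max <- max(2L, floor(2 * n * tr * cutoff_hz))
  t_idx <- seq_len(n) - 0.5
  vapply(seq_len(k_max), function(k) cos(pi * k * t_idx / n), numeric(n))
}

#' Preprocess BOLD time series
#'
#' Drops the initial `dummy` frames (scanner saturation), converts each series
#' to percent signal change about its mean, and detrends with a discrete
#' cosine transform high-pass filter (default cutoff 0.001 Hz; the filter
#' always removes at least the two lowest cosine terms, since within-run drift
#' slower than the run's fundamental aliases into them). Series that are
#' already in percent-signal-change units (not strictly positive raw
#' intensities) are mean-centred instead of rescaled.
#'
#' @param ts a [ts_set()].
#' @param dummy number of initial frames to discard (defaults to the set's
#'   recorded dummy count, or 8).
#' @param cutoff_hz high-pass cutoff frequency in Hz.
#' @return A preprocessed `ts_set` with `dummy_frames = 0`.
#' @export
preprocess <- function(ts, dummy = NULL, cutoff_hz = 0.001) {
  stopifnot(inherits(ts, "ts_set"))
  dummy <- dummy %||% (if (ts$dummy_frames > 0) ts$dummy_frames else 8L)
  n_tot <- ncol(ts$data)
  if (n_tot <= dummy) {
    stop(sprintf("series length %d not greater than dummy count %d", n_tot, dummy))
  }
  y <- ts$data[, (dummy + 1):n_tot, drop = FALSE]
  n <- ncol(y)
  m <- rowMeans(y)
  raw <- apply(y, 1, function(r) all(r >= 0)) & m > 0 &
    m > 3 * apply(y, 1, stats::sd)
  y[raw, ] <- 100 * (y[raw, , drop = FALSE] / m[raw] - 1)
  y[!raw, ] <- y[!raw, , drop = FALSE] - rowMeans(y[!raw, , drop = FALSE])
  X <- dct_basis(n, ts$tr_seconds, cutoff_hz)
  Q <- qr.Q(qr(cbind(1, X)))
  y <- y - (y %*% Q) %*% t(Q)
  ts_set(y, ts$tr_seconds, dummy_frames = 0L, preprocessed = TRUE, basis = Q)
}
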