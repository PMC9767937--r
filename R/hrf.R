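#' Haemodynamic response function specification
#'
#' Canonical double-gamma HRF: a gamma density peaking at `delay_peak` seconds
#' minus an undershoot gamma peaking at `delay_undershoot` seconds scaled by
#' `1/ratio`. The same kernel is shared verbatim between the BOLD simulator
#' and the pRF fitter so that noiseless round trips are exact.
#'
#' @param delay_peak time-to-peak of the positive lobe (s).
#' @param delay_undershoot time-to-peak of the undershoot (s).
#' @param ratio peak-to-undershoot amplitude ratio.
#' @param length kernel support in seconds.
#' @return An object of class `hrf_spec`.
#' @export
hrf_spec <- function(delay_peak = 5, delay_undershoot = 15, ratio = 6,
                     length = 32) {
  stopifnot(delay_peak > 0, delay_undershoot > 0, ratio > 0, length > 0)
  structure(list(delay_peak = delay_peak,
                 delay_undershoot = delay_undershoot,
                 ratio = ratio, length = length),
            class = "hrf_spec")
}

#' Discretized HRF kernel
#'
#' Samples the double-gamma at multiples of the repetition time and normalizes
#' the kernel to unit peak. Gamma shapes are chosen so the modes fall at the
#' specified delays (shape = delay + 1, rate = 1).
#'
#' @param spec an [hrf_spec()].
#' @param tr repetition time in seconds.
#' @return Numeric vector `h(0), h(tr), h(2 tr), ...`.
#' @export
hrf_kernel <- function(spec, tr) {
  stopifnot(inherits(spec, "hrf_spec"), tr > 0)
  t <- seq(0, spec$length, by = tr)
  h <- stats::dgamma(t, shape = spec$delay_peak + 1, rate = 1) -
    stats::dgamma(t, shape = spec$delay_undershoot + 1, rate = 1) / spec$ratio
  h / max(h)
}

# Causal convolution of columns of x (vector or T x K matrix) with kernel h,
# truncated to length T. A single lower-triangular Toeplitz multiply keeps the
# floating-point path identical for simulator and fitter.
conv_hrf <- function(x, h) {
  x <- as.matrix(x)
  n <- nrow(x)
  H <- matrix(0, n, n)
  for (k in seq_along(h)) {
    if (k > n) break
    idx <- seq_len(n - k + 1)
    H[cbind(idx + k - 1, idx)] <- h[k]
  }
  out <- H %*% x
  if (ncol(out) == 1) drop(out) else out
}
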