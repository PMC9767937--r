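#' Micro-probing probe lattice specification
#'
#' Micro-probing scans each voxel's response field with a dense lattice of
#' small fixed-size Gaussian probes rather than a single best-fitting
#' Gaussian, yielding a weight map over the visual field that captures
#' sub-pRF structure.
#'
#' @param spacing probe lattice spacing in degrees.
#' @param sigma_probe probe Gaussian size in degrees (fixed across probes).
#' @param radius lattice extent; probes with eccentricity beyond it are
#'   dropped.
#' @return An object of class `probe_spec`.
#' @export
probe_spec <- function(spacing = 1, sigma_probe = 0.5, radius = 7) {
  stopifnot(spacing > 0, sigma_probe > 0, radius > 0)
  v <- seq(-radius, radius, by = spacing)
  pts <- expand.grid(x = v, y = v)
  pts <- pts[sqrt(pts$x^2 + pts$y^2) <= radius, ]
  if (!nrow(pts)) stop("empty probe set")
  rownames(pts) <- NULL
  structure(list(probes = pts, sigma_probe = sigma_probe, radius = radius),
            class = "probe_spec")
}

#' Micro-probe BOLD time series
#'
#' For every probe a linear model (amplitude + baseline) is fitted to each
#' unit's series by least squares; the probe weight is the variance explained,
#' signed by the fitted amplitude and clipped at zero (anti-correlated probes
#' carry no weight). Each unit is summarized by the weight-weighted centroid
#' of the probe positions and the weighted RMS distance to it (spread). Units
#' with all-zero weights are flagged and have undefined centroids.
#'
#' @param ts a preprocessed [ts_set()] or units x T matrix.
#' @param apertures a dummy-stripped [aperture_movie].
#' @param probes a [probe_spec()].
#' @param hrf an [hrf_spec()].
#' @return An object of class `probe_map`: `weights` (units x probes),
#'   `probes` (probe positions), and `summary` (per-unit centroid, spread,
#'   total weight, flag).
#' @export
micro_probe <- function(ts, apertures, probes = probe_spec(),
                        hrf = hrf_spec()) {
  Y <- if (inherits(ts, "ts_set")) ts$data else as.matrix(ts)
  basis <- if (inherits(ts, "ts_set")) ts$basis else NULL
  stopifnot(inherits(probes, "probe_spec"))
  h <- hrf_kernel(hrf, apertures$tr_seconds)
  D <- conv_hrf(prf_drive(apertures, probes$probes$x, probes$probes$y,
                          rep(probes$sigma_probe, nrow(probes$probes))), h)
  D <- nuisance_project(as.matrix(D), basis)
  Yc <- sweep(t(Y), 2, rowMeans(Y))
  ys <- sqrt(colSums(Yc^2))
  Dm <- sweep(D, 2, colMeans(D))
  ds <- sqrt(colSums(Dm^2))
  R <- crossprod(Dm, Yc) / outer(ds, ys)    # probes x units, correlation
  R[!is.finite(R)] <- 0
  W <- t(pmax(sign(R) * R^2, 0))            # units x probes
  sum_w <- rowSums(W)
  cx <- ifelse(sum_w > 0, (W %*% probes$probes$x) / sum_w, NA_real_)
  cy <- ifelse(sum_w > 0, (W %*% probes$probes$y) / sum_w, NA_real_)
  spread <- rep(NA_real_, nrow(W))
  for (i in which(sum_w > 0)) {
    d2 <- (probes$probes$x - cx[i])^2 + (probes$probes$y - cy[i])^2
    spread[i] <- sqrt(sum(W[i, ] * d2) / sum_w[i])
  }
  structure(
    list(weights = W, probes = probes$probes,
         sigma_probe = probes$sigma_probe,
         summary = data.frame(unit = seq_len(nrow(W)), x = drop(cx),
                              y = drop(cy), spread = spread,
                              total_weight = sum_w, flagged = sum_w == 0)),
    class = "probe_map"
  )
}

#' @export
print.probe_map <- function(x, ...) {
  cat(sprintf("Probe map: %d units x %d probes (sigma %.2f deg), %d flagged\n",
              nrow(x$weights), ncol(x$weights), x$sigma_probe,
              sum(x$summary$flagged)))
  invisible(x)
}

#' Write a probe map in long CSV format
#'
#' Columns `unit_id, probe_x, probe_y, weight`; zero-weight rows are kept so
#' the table is dense.
#'
#' @param pm a `probe_map`.
#' @param file output path.
#' @export
write_probe_map <- function(pm, file) {
  n_u <- nrow(pm$weights); n_p <- ncol(pm$weights)
  out <- data.frame(unit_id = rep(seq_len(n_u), times = n_p),
                    probe_x = rep(pm$probes$x, each = n_u),
                    probe_y = rep(pm$probes$y, each = n_u),
                    weight = as.vector(pm$weights))
  utils::write.csv(out, file, row.names = FALSE)
  invisible(file)
}
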