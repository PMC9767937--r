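#' Candidate grid for coarse pRF search
#'
#' @param x,y candidate centre coordinates (degrees); the full lattice
#'   `expand.grid(x, y)` is searched.
#' @param sigmas candidate pRF sizes (degrees).
#' @return An object of class `prf_grid_spec`.
#' @export
prf_grid_spec <- function(x = seq(-8, 8, by = 0.5), y = seq(-8, 8, by = 0.5),
                          sigmas = c(0.25, 0.5, 1, 1.5, 2, 3, 4)) {
  if (!length(x) || !length(y) || !length(sigmas)) stop("empty grid")
  if (any(sigmas <= 0)) stop("candidate sigmas must be positive")
  structure(list(x = x, y = y, sigmas = sort(sigmas)), class = "prf_grid_spec")
}

# Gaussian-weighted aperture drive for centres (x0, y0, sigma) over a movie:
# n(t) = sum_pixels frame(t) * G / (analytic Gaussian mass in pixel units).
# The analytic mass (2 pi sigma^2 / pixel area) rather than the in-raster sum
# keeps receptive fields hanging off the raster from being renormalized to
# full sensitivity: a pRF far outside the stimulated field must drive nothing.
prf_drive <- function(apertures, x0, y0, sigma) {
  Fm <- frames_matrix(apertures)
  n_pix <- dim(apertures$frames)[2]
  cc <- field_coords(n_pix, apertures$field_radius)
  px <- rep(cc$x, each = n_pix)
  py <- rep(cc$y, times = n_pix)
  K <- length(x0)
  G <- matrix(0, length(px), K)
  for (k in seq_len(K)) {
    G[, k] <- exp(-((px - x0[k])^2 + (py - y0[k])^2) / (2 * sigma[k]^2))
  }
  D <- Fm %*% G
  mass <- 2 * pi * sigma^2 / cc$deg_per_pixel^2
  sweep(D, 2, mass, "/")
}

# Precompute convolved candidate drives for a grid; candidates are ordered by
# (sigma, eccentricity, y, x) so that scanning for the maximum VE implements
# the tie-break "smaller sigma, then smaller eccentricity" deterministically.
candidate_drives <- function(apertures, grid, hrf) {
  h <- hrf_kernel(hrf, apertures$tr_seconds)
  centres <- expand.grid(x0 = grid$x, y0 = grid$y)
  params <- do.call(rbind, lapply(grid$sigmas, function(s) {
    cbind(centres, sigma = s)
  }))
  params$ecc <- eccentricity(params$x0, params$y0)
  ord <- order(params$sigma, params$ecc, params$y0, params$x0)
  params <- params[ord, ]
  D <- matrix(0, dim(apertures$frames)[1], nrow(params))
  for (s in grid$sigmas) {
    idx <- which(params$sigma == s)
    D[, idx] <- prf_drive(apertures, params$x0[idx], params$y0[idx],
                          params$sigma[idx])
  }
  list(conv = conv_hrf(D, h), params = params, h = h)
}

#' Predict a BOLD time series from a pRF model
#'
#' Forward model of conventional pRF mapping: the neural drive is the overlap
#' of the (dummy-stripped) stimulus aperture with an isotropic 2-D Gaussian
#' receptive field, normalized by the Gaussian mass over the raster; the
#' predicted signal is `baseline + beta * (drive convolved with the HRF)`.
#'
#' @param model a list or one-row data frame with `x0`, `y0`, `sigma`, and
#'   optionally `beta` (default 1) and `baseline` (default 0).
#' @param apertures a dummy-stripped [aperture_movie].
#' @param hrf an [hrf_spec()].
#' @return Numeric vector of length T.
#' @export
predict_timeseries <- function(model, apertures, hrf = hrf_spec()) {
  if (is.null(model$sigma) || model$sigma <= 0) stop("sigma must be positive")
  d <- prf_drive(apertures, model$x0, model$y0, model$sigma)
  h <- hrf_kernel(hrf, apertures$tr_seconds)
  (model$baseline %||% 0) + (model$beta %||% 1) * conv_hrf(d, h)
}

# Coarse-stage VE for every unit x candidate: with an intercept and a single
# regressor, variance explained equals the squared correlation.
coarse_ve <- function(Y, Dc) {
  Yc <- sweep(t(Y), 2, rowMeans(Y))       # T x n, centred
  ys <- sqrt(colSums(Yc^2))
  Dm <- sweep(Dc, 2, colMeans(Dc))
  ds <- sqrt(colSums(Dm^2))
  R <- crossprod(Dm, Yc)                  # K x n
  R <- R / outer(ds, ys)
  R[!is.finite(R)] <- 0
  R^2
}

fit_beta_baseline <- function(y, d) {
  vd <- stats::var(d)
  if (!is.finite(vd) || vd == 0) return(c(beta = 0, baseline = mean(y)))
  b <- stats::cov(y, d) / vd
  c(beta = b, baseline = mean(y) - b * mean(d))
}

refine_prf <- function(y, apertures, h, start, basis = NULL, bounds_xy = 10,
                       bounds_sigma = c(0.05, 10)) {
  yc <- y - mean(y)
  ysd <- sqrt(sum(yc^2))
  obj <- function(p) {
    if (abs(p[1]) > bounds_xy || abs(p[2]) > bounds_xy ||
        p[3] < bounds_sigma[1] || p[3] > bounds_sigma[2]) return(2)
    d <- drop(nuisance_project(cbind(conv_hrf(prf_drive(apertures, p[1], p[2], p[3]), h)), basis))
    dc <- d - mean(d)
    dsd <- sqrt(sum(dc^2))
    if (dsd == 0) return(2)
    1 - (sum(dc * yc) / (dsd * ysd))^2
  }
  opt <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(maxit = 400, reltol = 1e-8))
  list(par = opt$par, ve = 1 - opt$value)
}

prf_model_row <- function(x0, y0, sigma, beta, baseline, ve, degenerate = FALSE) {
  data.frame(x0 = x0, y0 = y0, sigma = sigma, beta = beta,
             baseline = baseline, ve = ve,
             ecc = eccentricity(x0, y0), polar = polar_angle(x0, y0),
             degenerate = degenerate)
}

#' Fit 2-D Gaussian pRF models to BOLD time series
#'
#' The package's central estimator. For every unit (voxel) it runs a coarse
#' grid search -- for each candidate `(x0, y0, sigma)` the amplitude `beta` and
#' `baseline` are solved by least squares and the candidate maximizing the
#' variance explained (VE) is kept, ties broken toward smaller sigma and then
#' smaller eccentricity -- followed by an optional derivative-free local
#' refinement of `(x0, y0, sigma)` bounded to +/-10 degrees and sigma in
#' [0.05, 10] degrees. Refinement never degrades VE: if the local search ends
#' below the best coarse candidate, the coarse solution is kept.
#'
#' Zero-variance series do not fail; they yield a model flagged `degenerate`
#' with `ve = 0`.
#'
#' @param ts a preprocessed [ts_set()] (see [preprocess()]), or a units x T
#'   matrix already in percent-signal-change units.
#' @param apertures a dummy-stripped [aperture_movie], e.g. from
#'   [effective_aperture()] (use model `"FF"` for the full-field fit and
#'   `"SF"` to let the fitter know the simulated scotoma).
#' @param grid a [prf_grid_spec()].
#' @param hrf an [hrf_spec()].
#' @param refine logical; run the local refinement stage.
#' @param unit_ids optional unit identifiers.
#' @return An object of class `prf_fit`: the per-unit model table plus the
#'   ingredients needed by [predict.prf_fit()], [residuals.prf_fit()] and
#'   [simulate.prf_fit()].
#' @seealso [threshold_models()], [micro_probe()], [backproject_density()]
#' @export
prf_fit <- function(ts, apertures, grid = prf_grid_spec(), hrf = hrf_spec(),
                    refine = TRUE, unit_ids = NULL) {
  if (inherits(ts, "ts_set")) {
    Y <- ts$data
    basis <- ts$basis
  } else {
    Y <- as.matrix(ts)
    basis <- NULL
  }
  stopifnot(inherits(apertures, "aperture_movie"),
            inherits(grid, "prf_grid_spec"))
  if (apertures$dummy_frames > 0) {
    stop("apertures must be dummy-stripped; see effective_aperture()")
  }
  if (ncol(Y) != dim(apertures$frames)[1]) {
    stop(sprintf("series length %d does not match movie length %d",
                 ncol(Y), dim(apertures$frames)[1]))
  }
  n <- nrow(Y)
  unit_ids <- unit_ids %||% seq_len(n)
  cd <- candidate_drives(apertures, grid, hrf)
  cd$conv <- nuisance_project(cd$conv, basis)
  VE <- coarse_ve(Y, cd$conv)                         # K x n
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    y <- Y[i, ]
    if (stats::sd(y) == 0) {
      rows[[i]] <- prf_model_row(0, 0, grid$sigmas[1], 0, mean(y), 0,
                                 degenerate = TRUE)
      next
    }
    ve_i <- VE[, i]
    best <- which(ve_i == max(ve_i))[1]               # params pre-sorted for tie-break
    p <- c(cd$params$x0[best], cd$params$y0[best], cd$params$sigma[best])
    ve_best <- ve_i[best]
    if (refine) {
      r <- refine_prf(y, apertures, cd$h, p, basis = basis)
      if (is.finite(r$ve) && r$ve >= ve_best) {
        p <- r$par
        ve_best <- r$ve
      }
    }
    d <- drop(nuisance_project(cbind(conv_hrf(prf_drive(apertures, p[1], p[2], p[3]), cd$h)),
                               basis))
    bb <- fit_beta_baseline(y, d)
    rows[[i]] <- prf_model_row(p[1], p[2], p[3], bb[["beta"]],
                               bb[["baseline"]], ve_best)
  }
  models <- do.call(rbind, rows)
  models <- cbind(data.frame(unit = unit_ids), models)
  structure(
    list(models = models, ts = Y, apertures = apertures, grid = grid,
         hrf = hrf, tr_seconds = apertures$tr_seconds, refined = refine,
         call = match.call()),
    class = "prf_fit"
  )
}

#' Fit a single BOLD series
#'
#' Convenience wrapper around [prf_fit()] for one time series; returns the
#' one-row model table.
#'
#' @param y numeric vector (preprocessed percent signal change).
#' @inheritParams prf_fit
#' @export
fit_prf <- function(y, apertures, grid = prf_grid_spec(), hrf = hrf_spec(),
                    refine = TRUE) {
  fit <- prf_fit(matrix(y, nrow = 1), apertures, grid = grid, hrf = hrf,
                 refine = refine)
  fit$models
}

#' Threshold fitted pRF models
#'
#' Retains models that explain at least `ve_min` of the variance and whose
#' eccentricity lies within `ecc_range`; degenerate fits are dropped. Order is
#' preserved and the retained count reported as an attribute.
#'
#' @param models a `prf_fit` or its model data frame.
#' @param ve_min minimum variance explained (default 0.15).
#' @param ecc_range eccentricity range in degrees (default `c(0, 7)`).
#' @return The filtered model data frame with attribute `n_total`.
#' @export
threshold_models <- function(models, ve_min = 0.15, ecc_range = c(0, 7)) {
  if (inherits(models, "prf_fit")) models <- models$models
  ecc <- models$ecc %||% sqrt(models$x0^2 + models$y0^2)
  degen <- models$degenerate %||% rep(FALSE, nrow(models))
  keep <- models$ve >= ve_min &
    ecc >= ecc_range[1] & ecc <= ecc_range[2] & !degen
  out <- models[keep, , drop = FALSE]
  attr(out, "n_total") <- nrow(models)
  out
}

# ---- prf_fit methods --------------------------------------------------------

#' @export
print.prf_fit <- function(x, ...) {
  m <- x$models
  cat(sprintf("pRF fit: %d units, %d frames (TR %.2f s), %s\n",
              nrow(m), ncol(x$ts), x$tr_seconds,
              if (x$refined) "grid + refine" else "grid only"))
  cat(sprintf("  median VE %.3f; %d/%d units pass VE >= 0.15 & ecc <= 7\n",
              stats::median(m$ve), nrow(threshold_models(m)), nrow(m)))
  invisible(x)
}

#' @export
summary.prf_fit <- function(object, ve_min = 0.15, ...) {
  m <- object$models
  thr <- threshold_models(m, ve_min = ve_min)
  out <- list(
    n = nrow(m), n_pass = nrow(thr), ve_min = ve_min,
    ve = stats::quantile(m$ve, c(0.25, 0.5, 0.75)),
    sigma = stats::quantile(thr$sigma, c(0.25, 0.5, 0.75)),
    ecc = stats::quantile(thr$ecc, c(0.25, 0.5, 0.75)),
    n_degenerate = sum(m$degenerate)
  )
  class(out) <- "summary.prf_fit"
  out
}

#' @export
print.summary.prf_fit <- function(x, ...) {
  cat(sprintf("pRF fit summary: %d units (%d degenerate), %d pass VE >= %.2f\n",
              x$n, x$n_degenerate, x$n_pass, x$ve_min))
  cat(sprintf("  VE    quartiles: %.3f / %.3f / %.3f\n", x$ve[1], x$ve[2], x$ve[3]))
  cat(sprintf("  sigma quartiles: %.2f / %.2f / %.2f deg (thresholded)\n",
              x$sigma[1], x$sigma[2], x$sigma[3]))
  cat(sprintf("  ecc   quartiles: %.2f / %.2f / %.2f deg (thresholded)\n",
              x$ecc[1], x$ecc[2], x$ecc[3]))
  invisible(x)
}

#' @export
coef.prf_fit <- function(object, ...) {
  as.matrix(object$models[, c("x0", "y0", "sigma", "beta", "baseline", "ve")])
}

#' @export
predict.prf_fit <- function(object, apertures = NULL, ...) {
  apertures <- apertures %||% object$apertures
  h <- hrf_kernel(object$hrf, apertures$tr_seconds)
  m <- object$models
  D <- conv_hrf(prf_drive(apertures, m$x0, m$y0, m$sigma), h)
  D <- as.matrix(D)
  out <- sweep(D, 2, m$beta, "*")
  out <- sweep(out, 2, m$baseline, "+")
  t(out)                                  # units x T
}

#' @export
fitted.prf_fit <- function(object, ...) {
  predict(object)
}

#' @export
residuals.prf_fit <- function(object, ...) {
  object$ts - fitted(object)
}

#' @export
simulate.prf_fit <- function(object, nsim = 1, seed = NULL, ...) {
  mu <- fitted(object)
  rsd <- apply(residuals(object), 1, stats::sd)
  with_seed(seed, {
    lapply(seq_len(nsim), function(k) {
      mu + rsd * matrix(stats::rnorm(length(mu)), nrow(mu), ncol(mu))
    })
  })
}

#' Visual-field coverage plot of fitted pRFs
#'
#' Draws each retained pRF centre as a circle of radius sigma in visual-field
#' coordinates, with the stimulated-field boundary.
#'
#' @param x a `prf_fit`.
#' @param ve_min threshold applied before plotting.
#' @param ... passed to [graphics::symbols()].
#' @export
plot.prf_fit <- function(x, ve_min = 0.15, ...) {
  m <- threshold_models(x$models, ve_min = ve_min)
  r <- x$apertures$field_radius
  graphics::plot(NA, xlim = c(-r - 2, r + 2), ylim = c(-r - 2, r + 2),
                 asp = 1, xlab = "x (deg)", ylab = "y (deg)",
                 main = "pRF coverage")
  th <- seq(0, 2 * pi, length.out = 200)
  graphics::lines(r * cos(th), r * sin(th), lty = 2)
  if (nrow(m)) {
    graphics::symbols(m$x0, m$y0, circles = m$sigma, inches = FALSE,
                      add = TRUE, fg = grDevices::grey(0.3, 0.4), ...)
  }
  invisible(x)
}

#' @export
as.data.frame.prf_fit <- function(x, ...) x$models

#' Write a fitted pRF table as CSV
#'
#' Columns: `unit_id,x0,y0,sigma,beta,baseline,ve,ecc,polar`.
#'
#' @param fit a `prf_fit` or model data frame.
#' @param file output path.
#' @export
write_prf_table <- function(fit, file) {
  m <- if (inherits(fit, "prf_fit")) fit$models else fit
  out <- data.frame(unit_id = m$unit %||% seq_len(nrow(m)),
                    m[, c("x0", "y0", "sigma", "beta", "baseline",
                          "ve", "ecc", "polar")])
  utils::write.csv(out, file, row.names = FALSE)
  invisible(file)
}
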