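#' Visual-field reconstruction grid
#'
#' Regular lattice of visual-field positions within the stimulated radius at
#' which sampling-density maps are evaluated.
#'
#' @param spacing lattice spacing in degrees.
#' @param radius field radius in degrees.
#' @return An object of class `vf_grid` with `positions` (data frame `x`, `y`)
#'   and `spacing`.
#' @export
vf_grid <- function(spacing = 0.25, radius = 7) {
  v <- seq(-radius, radius, by = spacing)
  pts <- expand.grid(x = v, y = v)
  pts <- pts[sqrt(pts$x^2 + pts$y^2) <= radius, ]
  rownames(pts) <- NULL
  structure(list(positions = pts, spacing = spacing, radius = radius),
            class = "vf_grid")
}

#' Back-project pRF models onto the visual field
#'
#' The sampling density at each visual-field position is the weighted sum of
#' the Gaussian receptive fields of all retained units,
#' `density(p) = sum_v w_v exp(-|p - c_v|^2 / (2 sigma_v^2))`, normalized to a
#' maximum of 1. The default weight is each model's variance explained;
#' `"beta"` and `"count"` weighting are available.
#'
#' @param models a thresholded model data frame (see [threshold_models()]), a
#'   `prf_fit`, or a `prf_sheet` (in which case `ve` defaults to 1 and `sigma`
#'   is the ground-truth size).
#' @param grid a [vf_grid()].
#' @param weight `"ve"`, `"beta"` or `"count"`.
#' @return Numeric vector of normalized densities over `grid$positions`.
#' @export
backproject_density <- function(models, grid = vf_grid(),
                                weight = c("ve", "beta", "count")) {
  weight <- match.arg(weight)
  if (inherits(models, "prf_fit")) models <- models$models
  if (!nrow(models)) stop("no models to back-project")
  w <- switch(weight,
              ve = models$ve %||% rep(1, nrow(models)),
              beta = abs(models$beta),
              count = rep(1, nrow(models)))
  if (is.null(w)) w <- rep(1, nrow(models))
  px <- grid$positions$x; py <- grid$positions$y
  dens <- numeric(length(px))
  for (v in seq_len(nrow(models))) {
    dens <- dens + w[v] *
      exp(-((px - models$x0[v])^2 + (py - models$y0[v])^2) /
            (2 * models$sigma[v]^2))
  }
  mx <- max(dens)
  if (mx > 0) dens <- dens / mx
  dens
}

#' Convert a normalized density map to dB sensitivity
#'
#' `value = max(10 * log10(density), floor_db)`; a density of 1 maps to 0 dB
#' and zero density to the floor.
#'
#' @param density numeric vector of normalized densities (max 1).
#' @param grid the [vf_grid()] the densities live on.
#' @param floor_db sensitivity floor in dB.
#' @return An object of class `sensitivity_map` (`values`, `grid`,
#'   `floor_db`).
#' @export
to_db <- function(density, grid = NULL, floor_db = -40) {
  if (any(density < 0)) stop("densities must be non-negative")
  v <- suppressWarnings(10 * log10(density))
  v[!is.finite(v)] <- floor_db
  v <- pmax(v, floor_db)
  structure(list(values = v, grid = grid, floor_db = floor_db),
            class = "sensitivity_map")
}

#' @export
print.sensitivity_map <- function(x, ...) {
  cat(sprintf("Sensitivity map: %d positions, range [%.1f, %.1f] dB (floor %.0f)\n",
              length(x$values), min(x$values), max(x$values), x$floor_db))
  invisible(x)
}

#' Reconstruct a visual-field sensitivity map from fitted pRFs
#'
#' Convenience wrapper: threshold, back-project, convert to dB.
#'
#' @param fit a `prf_fit`, model data frame or `prf_sheet`.
#' @param grid a [vf_grid()].
#' @param ve_min,ecc_range passed to [threshold_models()] when `fit` carries a
#'   `ve` column.
#' @param floor_db sensitivity floor.
#' @param weight back-projection weighting.
#' @return A `sensitivity_map`.
#' @export
reconstruct_vf <- function(fit, grid = vf_grid(), ve_min = 0.15,
                           ecc_range = c(0, 7), floor_db = -40,
                           weight = "ve") {
  m <- if (inherits(fit, "prf_fit")) fit$models else fit
  if (!is.null(m$ve)) m <- threshold_models(m, ve_min = ve_min,
                                            ecc_range = ecc_range)
  to_db(backproject_density(m, grid, weight = weight), grid = grid,
        floor_db = floor_db)
}

deviation_levels <- function(boundaries = c(90, 95, 98, 99, 99.5)) {
  c("within",
    paste0("below@", boundaries), paste0("above@", boundaries))
}

#' Classify a sensitivity map against a normative control group
#'
#' Per visual-field position the subject's value is ranked within the
#' empirical distribution of the control maps (mid-rank on ties). The position
#' is labelled by the outermost two-sided confidence boundary it violates
#' among the `boundaries` (e.g. `below@95` when the empirical tail probability
#' falls under (100-95)/2 percent), otherwise `within`. With small control
#' groups the outer boundaries saturate at the sample extremes: a subject
#' below every control violates all boundaries and is labelled at the
#' outermost one.
#'
#' @param subject a `sensitivity_map`.
#' @param controls list of control `sensitivity_map`s on the same grid.
#' @param exclude optional index of a control to drop (the control matched to
#'   the subject).
#' @param boundaries two-sided confidence boundaries in percent.
#' @return An object of class `deviation_map`: factor `class` per position
#'   (levels `within`, `below@...`, `above@...`), the empirical `percentile`
#'   per position, and the grid.
#' @export
normative_deviation <- function(subject, controls, exclude = NULL,
                                boundaries = c(90, 95, 98, 99, 99.5)) {
  stopifnot(inherits(subject, "sensitivity_map"))
  if (!is.null(exclude)) controls <- controls[-exclude]
  m <- length(controls)
  if (m < 5) stop("need at least 5 control maps after exclusion")
  C <- vapply(controls, function(s) s$values, numeric(length(subject$values)))
  v <- subject$values
  n_less <- rowSums(C < v)
  n_tie <- rowSums(C == v)
  p <- (n_less + 0.5 * n_tie) / m
  boundaries <- sort(boundaries)
  alpha <- (1 - boundaries / 100) / 2
  cls <- rep("within", length(v))
  for (b in seq_along(boundaries)) {      # ascending: outermost wins last
    cls[p < alpha[b]] <- paste0("below@", boundaries[b])
    cls[p > 1 - alpha[b]] <- paste0("above@", boundaries[b])
  }
  structure(
    list(class = factor(cls, levels = deviation_levels(boundaries)),
         percentile = 100 * p, grid = subject$grid, boundaries = boundaries),
    class = "deviation_map"
  )
}

#' @export
print.deviation_map <- function(x, ...) {
  tab <- table(x$class)
  tab <- tab[tab > 0]
  cat("Deviation map:",
      paste(sprintf("%s %d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

# shared lattice plotting for maps on a vf_grid
vf_image <- function(grid, values, main, col, zlim = NULL) {
  xs <- sort(unique(grid$positions$x)); ys <- sort(unique(grid$positions$y))
  M <- matrix(NA_real_, length(xs), length(ys))
  M[cbind(match(grid$positions$x, xs), match(grid$positions$y, ys))] <- values
  zlim <- zlim %||% range(values, finite = TRUE)
  graphics::image(xs, ys, M, asp = 1, xlab = "x (deg)", ylab = "y (deg)",
                  main = main, col = col, zlim = zlim)
}

#' @export
plot.sensitivity_map <- function(x, ...) {
  if (is.null(x$grid)) stop("sensitivity map carries no grid")
  vf_image(x$grid, x$values, "Reconstructed VF sensitivity (dB)",
           grDevices::hcl.colors(64, "viridis"))
  invisible(x)
}

#' Plot a deviation map
#'
#' White marks positions within normal limits; darkening greys mark positions
#' below the normative band, greens above it.
#'
#' @param x a `deviation_map`.
#' @param ... unused.
#' @export
plot.deviation_map <- function(x, ...) {
  nb <- length(x$boundaries)
  pal <- c("white", grDevices::grey(seq(0.7, 0.1, length.out = nb)),
           grDevices::hcl.colors(nb, "Greens", rev = TRUE))
  vf_image(x$grid, as.integer(x$class), "VF deviation map", pal,
           zlim = c(1, 1 + 2 * nb))
  invisible(x)
}

#' Write a map as a CSV matrix
#'
#' @param map a `sensitivity_map` or `deviation_map`.
#' @param file output path.
#' @export
write_vf_map <- function(map, file) {
  vals <- if (inherits(map, "deviation_map")) as.character(map$class) else map$values
  out <- data.frame(x = map$grid$positions$x, y = map$grid$positions$y,
                    value = vals)
  utils::write.csv(out, file, row.names = FALSE)
  invisible(file)
}
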