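#' Perimetry grid of sensitivity deviations
#'
#' A perimetry grid holds per-location total-deviation sensitivity values in
#' decibels (dB) at visual-field test points, as produced by standard automated
#' perimetry (e.g. a Humphrey Field Analyzer 24-2 or 10-2 program). Deviations
#' at or below zero denote sensitivity loss; positive values denote
#' better-than-normative sensitivity. Coordinates are degrees of visual angle,
#' x positive rightward, y positive upward, origin at fixation.
#'
#' @param x,y numeric vectors of test-point coordinates in degrees.
#' @param deviation_db numeric vector of sensitivity deviations in dB.
#' @param eye one of `"left"`, `"right"`, `"binocular"`.
#' @param layout free-text layout name (e.g. `"10-2"`, `"24-2"`, `"custom"`).
#' @return An object of class `perimetry_grid`.
#' @examples
#' g <- perimetry_grid(c(-3, 3), c(3, 3), c(-5, 0), eye = "left")
#' g
#' @export
perimetry_grid <- function(x, y, deviation_db,
                           eye = c("binocular", "left", "right"),
                           layout = "custom") {
  eye <- match.arg(eye)
  x <- as.numeric(x); y <- as.numeric(y)
  deviation_db <- as.numeric(deviation_db)
  n <- length(x)
  if (n == 0L) stop("perimetry grid must contain at least one test point")
  if (length(y) != n || length(deviation_db) != n) {
    stop("x, y and deviation_db must have equal length")
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("test-point coordinates must be finite")
  }
  if (!all(is.finite(deviation_db))) stop("all deviations must be finite")
  if (any(abs(x) > 40) || any(abs(y) > 40)) {
    stop("test-point coordinates must satisfy |x|, |y| <= 40 degrees")
  }
  if (anyDuplicated(cbind(x, y))) stop("test-point coordinates must be unique")
  structure(
    list(points = data.frame(x = x, y = y), deviation_db = deviation_db,
         eye = eye, layout = layout),
    class = "perimetry_grid"
  )
}

#' @export
print.perimetry_grid <- function(x, ...) {
  cat(sprintf("Perimetry grid '%s' (%s eye): %d points, deviation range [%.1f, %.1f] dB\n",
              x$layout, x$eye, nrow(x$points),
              min(x$deviation_db), max(x$deviation_db)))
  invisible(x)
}

#' @export
length.perimetry_grid <- function(x) nrow(x$points)

#' Standard perimetry test-point layouts
#'
#' Generates the test-point lattices of common perimetry programs. `"30-2"` is
#' the 6-degree lattice of points at odd multiples of 3 degrees within 30
#' degrees eccentricity (76 points); `"24-2"` restricts it to |y| <= 21 and
#' |x| <= 21 plus the two nasal points at x = 27 (right-eye convention);
#' `"10-2"` is the 2-degree lattice at odd multiples of 1 degree within 10
#' degrees (68 points), the natural layout for a 7-degree stimulus field.
#'
#' @param name layout name: `"10-2"`, `"24-2"` or `"30-2"`.
#' @return A data frame with columns `x`, `y` (degrees).
#' @export
perimetry_layout <- function(name = c("10-2", "24-2", "30-2")) {
  name <- match.arg(name)
  if (name == "10-2") {
    v <- seq(-9, 9, by = 2)
    pts <- expand.grid(x = v, y = v)
    pts <- pts[sqrt(pts$x^2 + pts$y^2) <= 10, ]
  } else {
    v <- seq(-27, 27, by = 6)
    pts <- expand.grid(x = v, y = v)
    pts <- pts[sqrt(pts$x^2 + pts$y^2) <= 30, ]
    if (name == "24-2") {
      keep <- abs(pts$y) <= 21 & (abs(pts$x) <= 21 | (pts$x == 27 & abs(pts$y) == 3))
      pts <- pts[keep, ]
    }
  }
  rownames(pts) <- NULL
  pts
}

#' Read / write perimetry grids as CSV
#'
#' The CSV dialect is a header row `x_deg,y_deg,deviation_db` followed by one
#' test point per row; one file per eye, right-eye coordinate convention.
#'
#' @param file path to a CSV file.
#' @param eye,layout passed to [perimetry_grid()].
#' @return `read_perimetry()` returns a `perimetry_grid`;
#'   `write_perimetry()` invisibly returns `file`.
#' @export
read_perimetry <- function(file, eye = c("binocular", "left", "right"),
                           layout = "custom") {
  d <- utils::read.csv(file)
  need <- c("x_deg", "y_deg", "deviation_db")
  if (!all(need %in% names(d))) {
    stop("perimetry CSV must have columns x_deg, y_deg, deviation_db")
  }
  perimetry_grid(d$x_deg, d$y_deg, d$deviation_db, eye = match.arg(eye),
                 layout = layout)
}

#' @rdname read_perimetry
#' @param grid a `perimetry_grid`.
#' @export
write_perimetry <- function(grid, file) {
  stopifnot(inherits(grid, "perimetry_grid"))
  utils::write.csv(
    data.frame(x_deg = grid$points$x, y_deg = grid$points$y,
               deviation_db = grid$deviation_db),
    file, row.names = FALSE)
  invisible(file)
}

#' Integrate left- and right-eye perimetry into a binocular grid
#'
#' Binocular sensitivity at each test point is the better (maximum) of the two
#' eyes' deviations, reflecting binocular viewing of the stimulus.
#'
#' @param left,right `perimetry_grid` objects for the left and right eye with
#'   identical point layouts.
#' @return A binocular `perimetry_grid`.
#' @examples
#' l <- perimetry_grid(0, 3, -5, eye = "left")
#' r <- perimetry_grid(0, 3, -2, eye = "right")
#' integrate_binocular(l, r)$deviation_db  # -2
#' @export
integrate_binocular <- function(left, right) {
  stopifnot(inherits(left, "perimetry_grid"), inherits(right, "perimetry_grid"))
  if (left$eye != "left" || right$eye != "right") {
    stop("integrate_binocular() expects a left-eye and a right-eye grid")
  }
  if (nrow(left$points) != nrow(right$points)) {
    stop(sprintf("layout mismatch: left grid has %d points, right grid has %d",
                 nrow(left$points), nrow(right$points)))
  }
  ol <- order(left$points$x, left$points$y)
  or <- order(right$points$x, right$points$y)
  lx <- left$points[ol, ]; rx <- right$points[or, ]
  div <- which(lx$x != rx$x | lx$y != rx$y)
  if (length(div)) {
    stop(sprintf("layout mismatch: first divergent point left=(%g, %g) vs right=(%g, %g)",
                 lx$x[div[1]], lx$y[div[1]], rx$x[div[1]], rx$y[div[1]]))
  }
  dev <- pmax(left$deviation_db[ol], right$deviation_db[or])
  perimetry_grid(lx$x, lx$y, dev, eye = "binocular", layout = left$layout)
}

#' Convert a sensitivity deviation (dB) to a contrast multiplier
#'
#' Sensitivity loss is simulated as a local reduction of stimulus contrast on a
#' decibel power scale: `multiplier = 10^(deviation/10)` for deviations at or
#' below 0 dB, clipped to `[0, 1]`; positive deviations (better than normative)
#' map to full contrast. A 3 dB loss therefore halves stimulus contrast
#' (10^(-0.3) = 0.501).
#'
#' @param deviation_db numeric vector of sensitivity deviations in dB.
#' @param floor_db optional truncation floor: deviations below it are treated
#'   as absolute loss (multiplier 0). `NULL` (default) disables the floor.
#' @return Numeric vector of contrast multipliers in `[0, 1]`.
#' @examples
#' db_to_contrast(c(-3, 0, -10))
#' @export
db_to_contrast <- function(deviation_db, floor_db = NULL) {
  if (!all(is.finite(deviation_db))) stop("deviation_db must be finite")
  m <- 10^(pmin(deviation_db, 0) / 10)
  if (!is.null(floor_db)) m[deviation_db < floor_db] <- 0
  clamp(m, 0, 1)
}

# Interpolate grid deviations (dB) at query coordinates. Perimetry layouts are
# regular lattices, so bilinear interpolation on the inferred lattice is exact
# at the nodes and linear between them; lattice cells with no test point are
# filled from the nearest test point, and queries outside the lattice bounding
# box are clamped to its edge (nearest-edge extrapolation). Layouts that do not
# form a lattice fall back to nearest-point interpolation.
interp_deviation <- function(grid, xq, yq) {
  px <- grid$points$x; py <- grid$points$y; pv <- grid$deviation_db
  nearest <- function(xq, yq) {
    idx <- vapply(seq_along(xq), function(i) {
      which.min((px - xq[i])^2 + (py - yq[i])^2)
    }, integer(1))
    pv[idx]
  }
  ux <- sort(unique(px)); uy <- sort(unique(py))
  if (length(ux) < 2 || length(uy) < 2 ||
      length(ux) * length(uy) > 4L * length(px)) {
    return(nearest(xq, yq))
  }
  ix <- match(px, ux); iy <- match(py, uy)
  M <- matrix(NA_real_, nrow = length(uy), ncol = length(ux))
  M[cbind(iy, ix)] <- pv
  if (anyNA(M)) {
    holes <- which(is.na(M), arr.ind = TRUE)
    M[holes] <- nearest(ux[holes[, 2]], uy[holes[, 1]])
  }
  xc <- clamp(xq, ux[1], ux[length(ux)])
  yc <- clamp(yq, uy[1], uy[length(uy)])
  i <- findInterval(xc, ux, all.inside = TRUE)
  j <- findInterval(yc, uy, all.inside = TRUE)
  wx <- (xc - ux[i]) / (ux[i + 1] - ux[i])
  wy <- (yc - uy[j]) / (uy[j + 1] - uy[j])
  M[cbind(j, i)] * (1 - wx) * (1 - wy) +
    M[cbind(j, i + 1)] * wx * (1 - wy) +
    M[cbind(j + 1, i)] * (1 - wx) * wy +
    M[cbind(j + 1, i + 1)] * wx * wy
}

#' Build a contrast-attenuation mask from a perimetry grid
#'
#' Interpolates the grid's dB deviations to pixel resolution and maps them
#' pointwise through [db_to_contrast()], producing the alpha-transparency
#' contrast layer used to simulate a scotoma on a retinotopy stimulus.
#'
#' @param grid a binocular `perimetry_grid`.
#' @param geometry an [aperture_movie()] whose frames the mask must match, or a
#'   list with elements `n_pix` and `field_radius`.
#' @param floor_db optional absolute-loss floor passed to [db_to_contrast()].
#' @return An object of class `contrast_mask`: a list with `values` (H x W
#'   matrix of multipliers in `[0, 1]`, row 1 = top of the visual field),
#'   `deg_per_pixel`, `center` (pixel coordinates of fixation) and
#'   `field_radius`.
#' @export
build_contrast_mask <- function(grid, geometry, floor_db = NULL) {
  stopifnot(inherits(grid, "perimetry_grid"))
  if (grid$eye != "binocular") {
    stop("build_contrast_mask() expects a binocular grid; see integrate_binocular()")
  }
  if (inherits(geometry, "aperture_movie")) {
    n_pix <- dim(geometry$frames)[2]
    radius <- geometry$field_radius
  } else {
    n_pix <- geometry$n_pix
    radius <- geometry$field_radius
  }
  cc <- field_coords(n_pix, radius)
  qx <- rep(cc$x, each = n_pix)       # column-major over [row, col]
  qy <- rep(cc$y, times = n_pix)
  dbv <- interp_deviation(grid, qx, qy)
  vals <- matrix(db_to_contrast(dbv, floor_db = floor_db),
                 nrow = n_pix, ncol = n_pix)
  structure(
    list(values = vals, deg_per_pixel = cc$deg_per_pixel,
         center = c((n_pix + 1) / 2, (n_pix + 1) / 2), field_radius = radius),
    class = "contrast_mask"
  )
}

#' @export
print.contrast_mask <- function(x, ...) {
  cat(sprintf("Contrast mask %dx%d px (%.3f deg/px), values in [%.3f, %.3f]\n",
              nrow(x$values), ncol(x$values), x$deg_per_pixel,
              min(x$values), max(x$values)))
  invisible(x)
}

#' Export a contrast mask
#'
#' Writes the mask either as a plain CSV matrix (row 1 = top of the visual
#' field) or, when the RNifti package is available, as a 2-D NIfTI image.
#'
#' @param mask a `contrast_mask`.
#' @param file output path.
#' @param format `"csv"` or `"nifti"`.
#' @export
write_mask <- function(mask, file, format = c("csv", "nifti")) {
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.table(mask$values, file, sep = ",",
                       row.names = FALSE, col.names = FALSE)
  } else {
    if (!requireNamespace("RNifti", quietly = TRUE)) {
      stop("NIfTI export requires the RNifti package")
    }
    RNifti::writeNifti(RNifti::asNifti(mask$values), file)
  }
  invisible(file)
}

# Pixel-center coordinates (degrees) of an n_pix x n_pix raster spanning
# [-radius, radius]; x left->right along columns, y top->bottom along rows
# starting at +radius (row 1 = top).
field_coords <- function(n_pix, radius) {
  x <- seq(-radius, radius, length.out = n_pix)
  list(x = x, y = rev(x), deg_per_pixel = 2 * radius / (n_pix - 1))
}
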