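#' Simulation specification
#'
#' Parameters of the synthetic ground-truth sheets and BOLD forward model.
#' Defaults emulate the study conditions of a 7-degree drifting-bar retinotopy
#' session in early visual cortex: pRF size grows linearly with eccentricity
#' (sigma = intercept + slope * ecc, with lognormal jitter), the BOLD signal is
#' the HRF-convolved aperture overlap plus a slow cosine drift and AR(1)
#' Gaussian noise, and scotomatous damage attenuates unit gain by the local
#' contrast multiplier raised to `damage_exponent` (kappa).
#'
#' @param n_units units (voxels) per synthetic subject.
#' @param size_intercept,size_slope pRF size model (degrees, per degree).
#' @param size_jitter_sdlog lognormal sd of the multiplicative size jitter.
#' @param gain baseline unit gain (percent signal at full-field drive peak).
#' @param noise_sd stationary sd of the AR(1) noise (percent signal). The
#'   default is the package's reference noise level, at which the default
#'   fitter attains a median variance explained near 0.5.
#' @param ar1 AR(1) coefficient in `[0, 1)`.
#' @param drift_amp amplitude of the slow cosine drift (percent signal).
#' @param damage_exponent kappa; 0 disables scotomatous gain attenuation.
#' @param seed integer RNG seed.
#' @return An object of class `sim_spec`.
#' @export
sim_spec <- function(n_units = 500, size_intercept = 0.5, size_slope = 0.2,
                     size_jitter_sdlog = 0.15, gain = 1, noise_sd = 0.12,
                     ar1 = 0.3, drift_amp = 0.5, damage_exponent = 1,
                     seed = 1L) {
  stopifnot(noise_sd >= 0, ar1 >= 0, ar1 < 1, n_units > 0,
            size_intercept > 0, size_jitter_sdlog >= 0, drift_amp >= 0)
  structure(list(n_units = as.integer(n_units),
                 size_intercept = size_intercept, size_slope = size_slope,
                 size_jitter_sdlog = size_jitter_sdlog, gain = gain,
                 noise_sd = noise_sd, ar1 = ar1, drift_amp = drift_amp,
                 damage_exponent = damage_exponent, seed = as.integer(seed)),
            class = "sim_spec")
}

#' Sample a ground-truth pRF sheet
#'
#' Unit centres are uniform over the stimulated disc; sizes follow the linear
#' eccentricity model with multiplicative lognormal jitter; gains start at
#' `spec$gain`; visual-area labels V1/V2/V3 are assigned with probabilities
#' 0.6/0.25/0.15. Reproducible from `spec$seed`.
#'
#' @param spec a [sim_spec()].
#' @param field_radius stimulated field radius in degrees.
#' @return A `prf_sheet`: data frame with columns `x0, y0, sigma, gain, area`.
#' @export
sample_sheet <- function(spec = sim_spec(), field_radius = 7) {
  stopifnot(inherits(spec, "sim_spec"))
  if (spec$n_units <= 0) stop("n_units must be positive")
  with_seed(spec$seed, {
    n <- spec$n_units
    r <- field_radius * sqrt(stats::runif(n))
    phi <- stats::runif(n, 0, 2 * pi)
    x0 <- r * cos(phi); y0 <- r * sin(phi)
    ecc <- sqrt(x0^2 + y0^2)
    sigma <- (spec$size_intercept + spec$size_slope * ecc) *
      exp(stats::rnorm(n, 0, spec$size_jitter_sdlog))
    area <- sample(c("V1", "V2", "V3"), n, replace = TRUE,
                   prob = c(0.6, 0.25, 0.15))
    sheet <- data.frame(unit = seq_len(n), x0 = x0, y0 = y0, sigma = sigma,
                        gain = spec$gain, area = area)
    structure(sheet, class = c("prf_sheet", "data.frame"),
              field_radius = field_radius)
  })
}

#' Inject plasticity signatures into a ground-truth sheet
#'
#' Emulates local receptive-field reorganization: `"enlarge"` multiplies sigma
#' by `1 + magnitude` for units whose centre lies in `region`; `"shift"`
#' displaces those centres by `magnitude` degrees radially away from the
#' scotoma centre (outward along the region-boundary gradient).
#'
#' @param sheet a `prf_sheet`.
#' @param region predicate `function(x, y)` returning a logical, or a quadrant
#'   name (`"UL"`, `"UR"`, `"LL"`, `"LR"`).
#' @param mode `"shift"` or `"enlarge"`.
#' @param magnitude non-negative scalar (degrees for shift, fractional for
#'   enlarge).
#' @param center scotoma centre for shift mode; default is the centroid of the
#'   in-region units.
#' @return The modified `prf_sheet`.
#' @export
inject_plasticity <- function(sheet, region, mode = c("enlarge", "shift"),
                              magnitude, center = NULL) {
  mode <- match.arg(mode)
  if (magnitude < 0) stop("magnitude must be non-negative")
  if (is.character(region)) {
    quad <- match.arg(region, c("UL", "UR", "LL", "LR"))
    region <- function(x, y) quadrant_of(x, y) == quad
  }
  inside <- region(sheet$x0, sheet$y0)
  if (magnitude == 0 || !any(inside)) return(sheet)
  if (mode == "enlarge") {
    sheet$sigma[inside] <- sheet$sigma[inside] * (1 + magnitude)
  } else {
    center <- center %||% c(mean(sheet$x0[inside]), mean(sheet$y0[inside]))
    dx <- sheet$x0[inside] - center[1]
    dy <- sheet$y0[inside] - center[2]
    nrm <- sqrt(dx^2 + dy^2)
    nrm[nrm == 0] <- 1
    sheet$x0[inside] <- sheet$x0[inside] + magnitude * dx / nrm
    sheet$y0[inside] <- sheet$y0[inside] + magnitude * dy / nrm
  }
  sheet
}

#' Attenuate unit gains according to perimetric loss
#'
#' Each unit's gain is multiplied by `(10^(dev/10))^kappa`, where `dev` is the
#' binocular sensitivity deviation interpolated at the unit's centre -- the
#' contrast multiplier of [db_to_contrast()] raised to the damage exponent.
#' `kappa = 0` disables damage.
#'
#' @param sheet a `prf_sheet`.
#' @param grid a binocular [perimetry_grid()].
#' @param kappa damage exponent.
#' @return The damaged `prf_sheet`.
#' @export
apply_damage <- function(sheet, grid, kappa = 1) {
  stopifnot(inherits(grid, "perimetry_grid"))
  if (grid$eye != "binocular") stop("apply_damage() expects a binocular grid")
  if (kappa == 0) return(sheet)
  dev <- interp_deviation(grid, sheet$x0, sheet$y0)
  sheet$gain <- sheet$gain * db_to_contrast(dev)^kappa
  sheet
}

#' Forward-simulate BOLD time series from a ground-truth sheet
#'
#' Per unit, the neural drive is the normalized overlap of each movie frame
#' with the unit's Gaussian receptive field; the signal is the HRF-convolved
#' drive scaled by `gain` and normalized so that a sustained full-field drive
#' would peak at `gain` percent signal, plus a slow cosine drift (a random
#' unit mixture of the two lowest within-run cosine terms, amplitude
#' `drift_amp`) and AR(1) Gaussian noise with
#' stationary sd `noise_sd`. Output units are percent signal change;
#' reproducible from `spec$seed`.
#'
#' @param sheet a `prf_sheet`.
#' @param movie an [aperture_movie] (dummy frames, if present, are simulated
#'   too -- they carry blank apertures and are dropped again by
#'   [preprocess()]).
#' @param hrf an [hrf_spec()].
#' @param spec a [sim_spec()] providing the noise model and seed.
#' @return A [ts_set()] of dimension `n_units x T`.
#' @export
simulate_bold <- function(sheet, movie, hrf = hrf_spec(), spec = sim_spec()) {
  stopifnot(inherits(movie, "aperture_movie"))
  n_t <- dim(movie$frames)[1]
  if (n_t == 0) stop("empty movie")
  h <- hrf_kernel(hrf, movie$tr_seconds)
  D <- prf_drive(movie, sheet$x0, sheet$y0, sheet$sigma)   # T x n
  S <- conv_hrf(D, h)
  S <- as.matrix(S)
  ref <- max(conv_hrf(rep(1, n_t), h))
  S <- sweep(S, 2, sheet$gain / ref, "*")
  with_seed(spec$seed, {
    n <- nrow(sheet)
    # slow scanner drift: random mixture of the two lowest cosines of the
    # analysis segment (the run after dummy discard), extrapolated backward
    # over the dummy frames
    n_design <- n_t - movie$dummy_frames
    t_rel <- seq_len(n_t) - movie$dummy_frames - 0.5
    a <- matrix(stats::rnorm(2 * n), 2, n)
    a <- sweep(a, 2, sqrt(colSums(a^2)), "/")
    B <- cbind(cos(pi * t_rel / n_design), cos(2 * pi * t_rel / n_design))
    drift <- spec$drift_amp * (B %*% a)
    noise <- matrix(0, n_t, n)
    if (spec$noise_sd > 0) {
      innov_sd <- spec$noise_sd * sqrt(1 - spec$ar1^2)
      eps <- matrix(stats::rnorm(n_t * n, 0, innov_sd), n_t, n)
      noise <- apply(eps, 2, function(e) {
        as.numeric(stats::filter(e, spec$ar1, method = "recursive"))
      })
    }
    ts_set(t(S + drift + noise), movie$tr_seconds,
           dummy_frames = movie$dummy_frames)
  })
}

# Scotoma archetype perimetry grids on the 10-2 layout (binocular).
# quadrant: uniform loss over one quadrant (default UL);
# arcuate:  superior arcuate band between 3 and 9 degrees eccentricity;
# nasal_step: loss in the superior nasal wedge beyond 3 degrees (x >= 3,
#             right-eye convention);
# healthy:  all-zero deviations.
#' Scotoma archetype perimetry grid
#'
#' @param type archetype name: `"quadrant"`, `"arcuate"`, `"nasal_step"` or
#'   `"healthy"`.
#' @param depth loss depth in dB (negative).
#' @param quadrant affected quadrant for the quadrant archetype.
#' @param extent multiplicative spatial extent scaling in `[0, 1]` applied to
#'   the archetype's footprint.
#' @return A binocular `perimetry_grid` on the 10-2 layout.
#' @export
archetype_grid <- function(type = c("quadrant", "arcuate", "nasal_step", "healthy"),
                           depth = -20, quadrant = "UL", extent = 1) {
  type <- match.arg(type)
  if (depth > 0) stop("depth must be a loss (<= 0 dB)")
  pts <- perimetry_layout("10-2")
  dev <- numeric(nrow(pts))
  if (type != "healthy") {
    inside <- switch(
      type,
      quadrant = quadrant_of(pts$x, pts$y) == quadrant &
        sqrt(pts$x^2 + pts$y^2) <= 10 * extent,
      arcuate = pts$y > 0 &
        sqrt(pts$x^2 + pts$y^2) >= 3 &
        sqrt(pts$x^2 + pts$y^2) <= 3 + 6 * extent,
      nasal_step = pts$x >= 3 & pts$y > 0 &
        sqrt(pts$x^2 + pts$y^2) <= 10 * extent
    )
    dev[inside] <- depth
  }
  perimetry_grid(pts$x, pts$y, dev, eye = "binocular", layout = "10-2")
}

#' Generate a matched glaucoma/control synthetic cohort
#'
#' Mirrors the study design: `n_pairs` glaucoma-control pairs. For each pair a
#' glaucoma perimetry grid is drawn from a scotoma archetype (cycled through
#' `archetypes`, with depth drawn uniformly from `depth_range`), and three
#' datasets are simulated: the glaucoma participant (damaged sheet, optional
#' plasticity, full-field stimulus), the matched control with the simulated
#' scotoma (healthy sheet, SS stimulus), and the same control without
#' simulation (healthy sheet, full-field stimulus). Per-pair seeds are derived
#' from `spec$seed` and recorded.
#'
#' @param n_pairs number of glaucoma-control pairs (study default 19).
#' @param archetypes character vector of archetype names for [archetype_grid()].
#' @param spec a [sim_spec()].
#' @param movie base stimulus movie; default [make_lcr_movie()].
#' @param plasticity optional list `list(mode =, magnitude =)` injected into
#'   glaucoma sheets over the scotomatous region.
#' @param depth_range range of archetype depths in dB.
#' @param hrf an [hrf_spec()].
#' @return An object of class `prf_cohort`: per-pair list with elements
#'   `grid`, `glaucoma`, `control_ss`, `control_ns` (each `list(sheet, ts)`),
#'   plus the movie and a manifest of seeds.
#' @export
make_cohort <- function(n_pairs = 19, archetypes = c("quadrant", "arcuate", "nasal_step"),
                        spec = sim_spec(), movie = NULL,
                        plasticity = NULL, depth_range = c(-30, -10),
                        hrf = hrf_spec()) {
  if (n_pairs < 1) stop("n_pairs must be at least 1")
  known <- c("quadrant", "arcuate", "nasal_step", "healthy")
  if (!all(archetypes %in% known)) {
    stop("unknown archetype: ", paste(setdiff(archetypes, known), collapse = ", "))
  }
  movie <- movie %||% make_lcr_movie()
  geom <- list(n_pix = dim(movie$frames)[2], field_radius = movie$field_radius)
  pairs <- vector("list", n_pairs)
  manifest <- list(base_seed = spec$seed, pairs = list())
  for (i in seq_len(n_pairs)) {
    seed_i <- (spec$seed + 7919L * i) %% .Machine$integer.max
    arch <- archetypes[(i - 1) %% length(archetypes) + 1]
    pars <- with_seed(seed_i, list(
      depth = stats::runif(1, depth_range[1], depth_range[2]),
      quadrant = sample(c("UL", "UR", "LL", "LR"), 1)
    ))
    grid <- if (arch == "healthy") archetype_grid("healthy") else {
      archetype_grid(arch, depth = pars$depth, quadrant = pars$quadrant)
    }
    mask <- build_contrast_mask(grid, geom)
    movie_ss <- apply_scotoma(movie, mask)

    spec_g <- spec; spec_g$seed <- seed_i + 1L
    sheet_g <- sample_sheet(spec_g, field_radius = movie$field_radius)
    if (!is.null(plasticity) && plasticity$magnitude > 0) {
      region <- function(x, y) interp_deviation(grid, x, y) < -1
      sheet_g <- inject_plasticity(sheet_g, region, mode = plasticity$mode,
                                   magnitude = plasticity$magnitude)
    }
    sheet_g <- apply_damage(sheet_g, grid, kappa = spec$damage_exponent)
    spec_c <- spec; spec_c$seed <- seed_i + 2L
    sheet_c <- sample_sheet(spec_c, field_radius = movie$field_radius)

    sim_g <- spec; sim_g$seed <- seed_i + 3L
    sim_ss <- spec; sim_ss$seed <- seed_i + 4L
    sim_ns <- spec; sim_ns$seed <- seed_i + 5L
    pairs[[i]] <- list(
      pair = i, archetype = arch, depth = pars$depth, quadrant = pars$quadrant,
      grid = grid,
      glaucoma = list(sheet = sheet_g,
                      ts = simulate_bold(sheet_g, movie, hrf, sim_g)),
      control_ss = list(sheet = sheet_c,
                        ts = simulate_bold(sheet_c, movie_ss, hrf, sim_ss)),
      control_ns = list(sheet = sheet_c,
                        ts = simulate_bold(sheet_c, movie, hrf, sim_ns))
    )
    manifest$pairs[[i]] <- list(pair = i, seed = seed_i, archetype = arch,
                                depth = pars$depth, quadrant = pars$quadrant)
  }
  structure(list(pairs = pairs, movie = movie, spec = spec, hrf = hrf,
                 manifest = manifest),
            class = "prf_cohort")
}

#' @export
print.prf_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d glaucoma-control pairs, %d units/subject, seed %d\n",
              length(x$pairs), x$spec$n_units, x$spec$seed))
  invisible(x)
}
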