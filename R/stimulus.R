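#' Drifting-bar specification
#'
#' Parameters of the luminance-contrast retinotopy (LCR) bar: a high-contrast
#' flickering bar that traverses the stimulated field in equally spaced steps,
#' one step per repetition time (TR). The carrier texture (0.5 cycles/degree
#' checks, counterphase flicker) is not rendered -- pRF estimation operates on
#' contrast apertures -- but its parameters are retained as metadata.
#'
#' @param width bar width in degrees.
#' @param n_steps_full number of steps in a full pass (must be even).
#' @param directions motion directions in degrees (0 = rightward, measured
#'   counterclockwise from +x). Cardinal directions run as full passes,
#'   diagonal directions as truncated half passes followed by a blank.
#' @param contrast bar contrast as a fraction of maximum.
#' @param spatial_freq_cpd carrier spatial frequency (metadata only).
#' @return An object of class `bar_spec`.
#' @export
bar_spec <- function(width = 1.75, n_steps_full = 16,
                     directions = seq(0, 315, by = 45),
                     contrast = 1, spatial_freq_cpd = 0.5) {
  stopifnot(width > 0, n_steps_full %% 2 == 0, n_steps_full > 0,
            contrast >= 0, contrast <= 1)
  structure(list(width = width, n_steps_full = n_steps_full,
                 directions = directions, contrast = contrast,
                 spatial_freq_cpd = spatial_freq_cpd),
            class = "bar_spec")
}

new_aperture_movie <- function(frames, tr, field_radius, dummy_frames,
                               preset = "custom", mask = NULL, pristine = NULL) {
  n_pix <- dim(frames)[2]
  structure(
    list(frames = frames, tr_seconds = tr, field_radius = field_radius,
         deg_per_pixel = 2 * field_radius / (n_pix - 1),
         dummy_frames = dummy_frames, preset = preset,
         mask = mask, pristine = pristine),
    class = "aperture_movie"
  )
}

#' @export
print.aperture_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("Aperture movie '%s': %d frames (%d dummy) of %dx%d px, TR %.2f s, %.0f deg radius (%.0f s total)\n",
              x$preset, d[1], x$dummy_frames, d[2], d[3], x$tr_seconds,
              x$field_radius, movie_duration(x)))
  invisible(x)
}

#' Total movie duration in seconds
#' @param movie an `aperture_movie`.
#' @export
movie_duration <- function(movie) dim(movie$frames)[1] * movie$tr_seconds

#' Generate the drifting-bar retinotopy aperture movie (LCR)
#'
#' Builds the binary contrast aperture of the luminance-contrast retinotopy
#' run: the bar sweeps the field in `n_steps_full` equally spaced steps per
#' full pass (one step per TR). After each full pass the next direction runs a
#' truncated pass -- the bar crosses half the field, then a blank mean-luminance
#' screen is shown for the same duration. With the default 8 directions
#' (4 cardinal full passes of 16 frames interleaved with 4 diagonal truncated
#' passes of 8 bar + 8 blank frames) the design is 128 frames; `dummy_frames`
#' blank frames are prepended, giving the default run of 136 frames = 204 s at
#' TR 1.5 s.
#'
#' @param bar a [bar_spec()].
#' @param tr repetition time in seconds per frame.
#' @param n_pix raster size in pixels (default 101 x 101 over +/-7 degrees).
#' @param field_radius stimulated field radius in degrees.
#' @param dummy_frames initial discardable frames (scanner saturation).
#' @return An [aperture_movie] with values in `{0, contrast}`.
#' @examples
#' m <- make_lcr_movie(n_pix = 21)
#' dim(m$frames)      # 136 frames
#' movie_duration(m)  # 204 s
#' @export
make_lcr_movie <- function(bar = bar_spec(), tr = 1.5, n_pix = 101,
                           field_radius = 7, dummy_frames = 8) {
  stopifnot(tr > 0, n_pix > 1)
  if (bar$width >= 2 * field_radius) {
    stop("bar wider than the stimulated field")
  }
  cc <- field_coords(n_pix, field_radius)
  X <- matrix(rep(cc$x, each = n_pix), n_pix, n_pix)
  Y <- matrix(rep(cc$y, times = n_pix), n_pix, n_pix)
  in_field <- (X^2 + Y^2) <= field_radius^2
  ns <- bar$n_steps_full
  step <- 2 * field_radius / ns
  centers <- -field_radius + (seq_len(ns) - 0.5) * step
  frames_list <- list()
  for (th in bar$directions) {
    a <- th * pi / 180
    proj <- X * cos(a) + Y * sin(a)
    full <- th %% 90 == 0
    ks <- if (full) seq_len(ns) else seq_len(ns / 2)
    for (k in ks) {
      f <- matrix(0, n_pix, n_pix)
      f[in_field & abs(proj - centers[k]) <= bar$width / 2] <- bar$contrast
      frames_list[[length(frames_list) + 1L]] <- f
    }
    if (!full) {
      for (k in seq_len(ns / 2)) {
        frames_list[[length(frames_list) + 1L]] <- matrix(0, n_pix, n_pix)
      }
    }
  }
  n_design <- length(frames_list)
  frames <- array(0, dim = c(dummy_frames + n_design, n_pix, n_pix))
  for (t in seq_len(n_design)) frames[dummy_frames + t, , ] <- frames_list[[t]]
  new_aperture_movie(frames, tr, field_radius, dummy_frames,
                     preset = "lcr-default")
}

#' Generate the scotoma-localizer aperture movie
#'
#' A block-design localizer preset: alternating 8-frame on/off blocks of a
#' full-disc aperture (17 blocks = 136 design frames) preceded by
#' `dummy_frames` blanks, giving 144 frames = 216 s at TR 1.5 s. Apply a
#' contrast mask with [apply_scotoma()] to restrict stimulation to (or away
#' from) a scotoma projection zone.
#'
#' @inheritParams make_lcr_movie
#' @param block_frames frames per on/off block.
#' @export
make_localizer_movie <- function(tr = 1.5, n_pix = 101, field_radius = 7,
                                 dummy_frames = 8, block_frames = 8) {
  cc <- field_coords(n_pix, field_radius)
  X <- matrix(rep(cc$x, each = n_pix), n_pix, n_pix)
  Y <- matrix(rep(cc$y, times = n_pix), n_pix, n_pix)
  disc <- (X^2 + Y^2) <= field_radius^2
  n_design <- 17L * block_frames
  frames <- array(0, dim = c(dummy_frames + n_design, n_pix, n_pix))
  for (t in seq_len(n_design)) {
    on <- ((t - 1) %/% block_frames) %% 2 == 0
    if (on) frames[dummy_frames + t, , ][disc] <- 1
  }
  new_aperture_movie(frames, tr, field_radius, dummy_frames,
                     preset = "localizer")
}

#' Overlay a simulated scotoma on an aperture movie
#'
#' Multiplies every frame pointwise by a contrast-attenuation mask, yielding
#' the simulated-scotoma (SS) variant of the stimulus. The unattenuated
#' aperture is retained so that full-field (FF) model apertures can still be
#' derived from the returned movie.
#'
#' @param movie an [aperture_movie].
#' @param mask a `contrast_mask` from [build_contrast_mask()] with matching
#'   pixel geometry.
#' @return An `aperture_movie` with attenuated frames.
#' @export
apply_scotoma <- function(movie, mask) {
  stopifnot(inherits(movie, "aperture_movie"), inherits(mask, "contrast_mask"))
  d <- dim(movie$frames)
  if (!all(dim(mask$values) == d[2:3])) {
    stop(sprintf("mask geometry %dx%d does not match frames %dx%d",
                 nrow(mask$values), ncol(mask$values), d[2], d[3]))
  }
  pristine <- movie$pristine %||% movie$frames
  frames <- pristine * rep(mask$values, each = d[1])
  dim(frames) <- d
  new_aperture_movie(frames, movie$tr_seconds, movie$field_radius,
                     movie$dummy_frames, preset = paste0(movie$preset, "+ss"),
                     mask = mask, pristine = pristine)
}

#' Effective aperture seen by a pRF fitting model
#'
#' The full-field (FF) model fits against the undamaged binary bar aperture;
#' the scotoma-field (SF) model fits against the aperture attenuated by the
#' simulated-scotoma mask, so that the fitter "knows" the scotoma. Dummy
#' frames are stripped in both cases.
#'
#' @param movie an [aperture_movie].
#' @param model `"FF"` or `"SF"`.
#' @param mask a `contrast_mask` for the SF model; defaults to the mask stored
#'   in the movie by [apply_scotoma()], if any.
#' @return A dummy-stripped `aperture_movie`.
#' @export
effective_aperture <- function(movie, model = c("FF", "SF"), mask = NULL) {
  model <- match.arg(model)
  stopifnot(inherits(movie, "aperture_movie"))
  d <- dim(movie$frames)
  pristine <- movie$pristine %||% movie$frames
  ap <- (pristine > 0) * 1
  if (model == "SF") {
    mask <- mask %||% movie$mask
    if (is.null(mask)) stop("SF model requires a contrast mask")
    if (!all(dim(mask$values) == d[2:3])) stop("mask geometry mismatch")
    ap <- ap * rep(mask$values, each = d[1])
    dim(ap) <- d
  }
  keep <- seq_len(d[1]) > movie$dummy_frames
  new_aperture_movie(ap[keep, , , drop = FALSE], movie$tr_seconds,
                     movie$field_radius, dummy_frames = 0L,
                     preset = paste0(movie$preset, ":", model))
}

# Flatten frames to a T x (H*W) matrix (column-major pixel order, matching
# field_coords / build_contrast_mask vector layouts).
frames_matrix <- function(movie) {
  d <- dim(movie$frames)
  matrix(movie$frames, nrow = d[1], ncol = d[2] * d[3])
}
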