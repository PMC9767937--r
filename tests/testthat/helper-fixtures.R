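# Shared fixtures, built once per test run. The 41x41 raster (0.35 deg/px)
# keeps fitting fast while the stimulus design itself is at full fidelity.
.fix <- new.env()

small_movie <- function() {
  if (is.null(.fix$movie)) .fix$movie <- make_lcr_movie(n_pix = 41)
  .fix$movie
}

small_ap <- function() {
  if (is.null(.fix$ap)) .fix$ap <- effective_aperture(small_movie(), "FF")
  .fix$ap
}

small_grid <- function() {
  prf_grid_spec(x = seq(-7, 7, by = 1), y = seq(-7, 7, by = 1),
                sigmas = c(0.5, 1, 2))
}

# ground-truth sheet whose parameters all lie on small_grid() candidates
on_grid_sheet <- function() {
  data.frame(unit = 1:4,
             x0 = c(2, -3, 0, 4), y0 = c(1, -2, 4, -5),
             sigma = c(1, 2, 0.5, 1), gain = 1, area = "V1")
}

noiseless_spec <- function(n = 4) {
  sim_spec(n_units = n, noise_sd = 0, drift_amp = 0, seed = 1)
}

# quadrant scotoma grid used across modules (upper-left, uniform depth)
ul_scotoma <- function(depth = -20) {
  archetype_grid("quadrant", depth = depth, quadrant = "UL")
}
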