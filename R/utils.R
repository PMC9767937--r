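#' @keywords internal
"_PACKAGE"

# Run `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. seed = NULL runs the code on the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Polar angle convention used throughout: 0 at the upper vertical meridian,
# increasing counterclockwise, in [0, 2*pi). (0,1) -> 0, (-1,0) -> pi/2.
polar_angle <- function(x, y) {
  th <- atan2(-x, y)
  th[th < 0] <- th[th < 0] + 2 * pi
  th
}

eccentricity <- function(x, y) sqrt(x^2 + y^2)

# Quadrant from the polar angle; the boundary meridian belongs to the
# counterclockwise quadrant, so UL spans (0, pi/2] and 0 itself is UR.
quadrant_of <- function(x, y) {
  th <- polar_angle(x, y)
  q <- character(length(th))
  q[th > 0 & th <= pi / 2] <- "UL"
  q[th > pi / 2 & th <= pi] <- "LL"
  q[th > pi & th <= 3 * pi / 2] <- "LR"
  q[th > 3 * pi / 2 | th == 0] <- "UR"
  q
}
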