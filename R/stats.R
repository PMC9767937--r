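#' BOLD modulation
#'
#' The per-unit standard deviation of the (preprocessed, percent signal
#' change) BOLD series -- the responsiveness measure used throughout the
#' group analyses.
#'
#' @param ts a [ts_set()] or units x T matrix.
#' @return Numeric vector of per-unit modulations.
#' @export
bold_modulation <- function(ts) {
  Y <- if (inherits(ts, "ts_set")) ts$data else as.matrix(ts)
  apply(Y, 1, stats::sd)
}

#' Bin values by pRF eccentricity
#'
#' Averages a per-unit quantity (e.g. BOLD modulation or pRF size) within
#' half-open 1-degree eccentricity bins `[k, k+1)`, with a bootstrap 95%
#' interval per bin. Empty bins are recorded as missing, not as zero.
#'
#' @param values numeric vector aligned with `models`.
#' @param models model data frame with an `ecc` column (or a numeric vector of
#'   eccentricities).
#' @param width bin width in degrees.
#' @param limits eccentricity range covered by the bins.
#' @param nboot bootstrap replicates for the interval.
#' @param seed RNG seed for the bootstrap.
#' @return A `binned_profile` data frame: `bin_lo`, `bin_hi`, `bin_mid`,
#'   `mean`, `lo`, `hi`, `n`.
#' @export
bin_by_eccentricity <- function(values, models, width = 1, limits = c(0, 7),
                                nboot = 1000, seed = NULL) {
  ecc <- if (is.numeric(models)) models else models$ecc
  if (length(values) != length(ecc)) stop("values and models must be aligned")
  edges <- seq(limits[1], limits[2], by = width)
  lo <- edges[-length(edges)]; hi <- edges[-1]
  with_seed(seed, {
    rows <- lapply(seq_along(lo), function(b) {
      inb <- ecc >= lo[b] & ecc < hi[b]
      n <- sum(inb)
      if (n == 0) {
        return(data.frame(bin_lo = lo[b], bin_hi = hi[b],
                          bin_mid = (lo[b] + hi[b]) / 2,
                          mean = NA_real_, lo = NA_real_, hi = NA_real_, n = 0L))
      }
      v <- values[inb]
      bm <- vapply(seq_len(nboot), function(i) {
        mean(v[sample.int(n, n, replace = TRUE)])
      }, numeric(1))
      q <- stats::quantile(bm, c(0.025, 0.975), names = FALSE)
      data.frame(bin_lo = lo[b], bin_hi = hi[b], bin_mid = (lo[b] + hi[b]) / 2,
                 mean = mean(v), lo = q[1], hi = q[2], n = n)
    })
    out <- do.call(rbind, rows)
    class(out) <- c("binned_profile", "data.frame")
    out
  })
}

#' @export
plot.binned_profile <- function(x, ylab = "value", ...) {
  graphics::plot(x$bin_mid, x$mean, type = "b", pch = 16,
                 xlab = "eccentricity (deg)", ylab = ylab, ...)
  graphics::arrows(x$bin_mid, x$lo, x$bin_mid, x$hi, angle = 90, code = 3,
                   length = 0.03)
  invisible(x)
}

default_hist_edges <- function(dimension) {
  switch(dimension,
         eccentricity = seq(0, 7, by = 1),
         polar = seq(0, 2 * pi, length.out = 17),
         size = seq(0, 5, by = 0.25))
}

#' Normalized histogram of responsive-voxel pRF properties
#'
#' Histogram of thresholded (responsive) units along one pRF dimension, with
#' bin mass normalized to sum to 1. With zero models the histogram is all
#' zeros and flagged via `attr(, "empty")`.
#'
#' @param models thresholded model data frame (see [threshold_models()]).
#' @param dimension `"eccentricity"`, `"polar"` or `"size"`.
#' @param edges bin edges; defaults depend on the dimension (1-degree
#'   eccentricity bins over 0-7, 16 equal polar bins over `[0, 2pi)`,
#'   0.25-degree size bins over 0-5). Bins are half-open `[lo, hi)` with
#'   values beyond the edges clamped into the outer bins.
#' @return A `normalized_hist`: list with `dimension`, `edges`, `mass`.
#' @export
normalized_hist <- function(models, dimension = c("eccentricity", "polar", "size"),
                            edges = NULL) {
  dimension <- match.arg(dimension)
  edges <- edges %||% default_hist_edges(dimension)
  v <- switch(dimension, eccentricity = models$ecc, polar = models$polar,
              size = models$sigma)
  nb <- length(edges) - 1
  if (length(v) == 0) {
    out <- structure(list(dimension = dimension, edges = edges,
                          mass = numeric(nb)), class = "normalized_hist")
    attr(out, "empty") <- TRUE
    return(out)
  }
  idx <- findInterval(v, edges, rightmost.closed = FALSE, all.inside = TRUE)
  counts <- tabulate(idx, nbins = nb)
  structure(list(dimension = dimension, edges = edges,
                 mass = counts / sum(counts)),
            class = "normalized_hist")
}

#' @export
print.normalized_hist <- function(x, ...) {
  cat(sprintf("Normalized %s histogram: %d bins, mass %.3f\n",
              x$dimension, length(x$mass), sum(x$mass)))
  invisible(x)
}

#' Deviation between two normalized histograms
#'
#' The per-bin signed difference `a - b` and its aggregate `sum(|a - b|)`; for
#' normalized histograms the aggregate lies in `[0, 2]`.
#'
#' @param a,b `normalized_hist` objects on identical edges.
#' @return A `pair_deviation`: list with `per_bin`, `aggregate`, `edges`.
#' @export
pair_deviation <- function(a, b) {
  stopifnot(inherits(a, "normalized_hist"), inherits(b, "normalized_hist"))
  if (length(a$edges) != length(b$edges) || any(a$edges != b$edges)) {
    stop("histogram edges differ")
  }
  d <- a$mass - b$mass
  structure(list(per_bin = d, aggregate = sum(abs(d)), edges = a$edges,
                 dimension = a$dimension),
            class = "pair_deviation")
}

#' Rank a pair deviation against the baseline control-control deviations
#'
#' The deviation between a participant pair (glaucoma vs matched control, or
#' control SS vs control NS) is ranked within the baseline distribution of
#' deviations between the matched control and every other control
#' (leave-self-out). Mid-ranks are used on ties. The pair is flagged
#' significant when its percentile, `100 * rank / (n_baseline + 1)`, exceeds
#' 95 (one-sided: the pair deviates more than the baseline variability).
#' Per-bin ranks of `|difference|` are reported alongside when the baseline
#' deviations carry per-bin differences.
#'
#' @param pair a `pair_deviation` (or a single aggregate value).
#' @param baseline list of `pair_deviation`s (or numeric aggregates).
#' @param sig_percentile significance threshold on the percentile scale.
#' @return A `rank_result`: `aggregate`, `baseline`, `rank`, `percentile`,
#'   `significant`, and `per_bin_rank` when available.
#' @export
deviation_rank <- function(pair, baseline, sig_percentile = 95) {
  agg <- if (inherits(pair, "pair_deviation")) pair$aggregate else as.numeric(pair)
  base_agg <- vapply(baseline, function(b) {
    if (inherits(b, "pair_deviation")) b$aggregate else as.numeric(b)
  }, numeric(1))
  n <- length(base_agg)
  if (n < 5) stop("baseline must contain at least 5 deviations")
  rk <- 1 + sum(base_agg < agg) + 0.5 * sum(base_agg == agg)
  pct <- 100 * rk / (n + 1)
  per_bin_rank <- NULL
  if (inherits(pair, "pair_deviation") &&
      all(vapply(baseline, inherits, logical(1), "pair_deviation"))) {
    B <- vapply(baseline, function(b) abs(b$per_bin), numeric(length(pair$per_bin)))
    per_bin_rank <- vapply(seq_along(pair$per_bin), function(j) {
      1 + sum(B[j, ] < abs(pair$per_bin[j])) + 0.5 * sum(B[j, ] == abs(pair$per_bin[j]))
    }, numeric(1))
  }
  structure(list(aggregate = agg, baseline = base_agg, rank = rk,
                 percentile = pct, significant = pct > sig_percentile,
                 per_bin_rank = per_bin_rank),
            class = "rank_result")
}

#' @export
print.rank_result <- function(x, ...) {
  cat(sprintf("Deviation rank %.1f / %d (percentile %.1f)%s\n",
              x$rank, length(x$baseline) + 1, x$percentile,
              if (x$significant) " *" else ""))
  invisible(x)
}

#' Per-quadrant summary of pRF properties
#'
#' Means of pRF size, position and (optionally) BOLD modulation per
#' visual-field quadrant; quadrants are assigned from the pRF centre under the
#' polar-angle convention (a boundary meridian belongs to the
#' counterclockwise quadrant). Empty quadrants are flagged.
#'
#' @param models thresholded model data frame.
#' @param modulations optional per-unit BOLD modulation aligned with `models`.
#' @return A `quadrant_summary` data frame: `quadrant`, `n`, `mean_sigma`,
#'   `mean_x`, `mean_y`, `mean_modulation`, `empty`.
#' @export
quadrant_summary <- function(models, modulations = NULL) {
  q <- quadrant_of(models$x0, models$y0)
  quads <- c("UL", "UR", "LL", "LR")
  rows <- lapply(quads, function(qq) {
    inq <- q == qq
    data.frame(
      quadrant = qq, n = sum(inq),
      mean_sigma = if (any(inq)) mean(models$sigma[inq]) else NA_real_,
      mean_x = if (any(inq)) mean(models$x0[inq]) else NA_real_,
      mean_y = if (any(inq)) mean(models$y0[inq]) else NA_real_,
      mean_modulation = if (any(inq) && !is.null(modulations)) {
        mean(modulations[inq])
      } else NA_real_,
      empty = !any(inq))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("quadrant_summary", "data.frame")
  out
}

#' Euclidean distance between two visual-field positions
#'
#' @param p,q numeric vectors `c(x, y)` in degrees.
#' @return Distance in degrees.
#' @export
euclidean_distance <- function(p, q) {
  sqrt(sum((as.numeric(p) - as.numeric(q))^2))
}

#' Mixed-effects slope between a response and a severity measure
#'
#' Fits `y ~ x` with a random intercept and slope per subject
#' (`(1 + x | subject)`), the model used to correlate quadrant-level pRF
#' measures with disease-severity covariates. The fixed-effect slope, its
#' standard error and Satterthwaite p-value are returned together with a
#' signed r-squared (the squared marginal correlation carrying the slope's
#' sign). Degenerate designs (a single subject, or subjects without
#' replication) fall back to ordinary least squares with a warning.
#'
#' @param y,x numeric vectors.
#' @param subject subject labels aligned with `y` and `x`.
#' @return A list: `slope`, `intercept`, `se`, `p`, `r2`, `method`.
#' @export
mixed_slope <- function(y, x, subject) {
  if (length(unique(x)) < 2) stop("x is constant; no slope is identified")
  subject <- factor(subject)
  d <- data.frame(y = y, x = x, S = subject)
  per_s <- table(subject)
  use_mixed <- nlevels(subject) >= 2 && sum(per_s >= 2) >= 2
  fit <- NULL
  if (use_mixed) {
    fit <- tryCatch(
      suppressMessages(suppressWarnings(
        lmerTest::lmer(y ~ x + (1 + x | S), data = d,
                       control = lme4::lmerControl(check.conv.singular =
                         lme4::.makeCC(action = "ignore", tol = 1e-4))))),
      error = function(e) NULL)
  }
  if (is.null(fit)) {
    if (use_mixed) warning("mixed model failed; falling back to OLS")
    else warning("degenerate design; using ordinary least squares")
    lmfit <- stats::lm(y ~ x, data = d)
    co <- summary(lmfit)$coefficients
    slope <- co["x", "Estimate"]
    out <- list(slope = slope, intercept = co["(Intercept)", "Estimate"],
                se = co["x", "Std. Error"],
                p = if (nrow(d) > 2) co["x", "Pr(>|t|)"] else NA_real_,
                r2 = sign(slope) * stats::cor(d$x, d$y)^2, method = "ols")
    return(out)
  }
  co <- stats::coef(summary(fit))
  slope <- co["x", "Estimate"]
  list(slope = slope, intercept = co["(Intercept)", "Estimate"],
       se = co["x", "Std. Error"],
       p = co["x", "Pr(>|t|)"],
       r2 = sign(slope) * stats::cor(d$x, d$y)^2, method = "lmm")
}

#' Compare pRF-size distributions between groups
#'
#' Computes the median pRF size per participant and compares the medians
#' across the two groups with a Welch two-sample t-test; per-participant
#' empirical cumulative distributions are returned for plotting.
#'
#' @param sigma_by_participant named list of per-participant pRF size vectors.
#' @param groups character/factor vector of group labels aligned with the
#'   list (exactly two levels).
#' @return A list: `medians` (data frame), `t`, `df`, `p`, `ecdfs`.
#' @export
size_distribution_test <- function(sigma_by_participant, groups) {
  groups <- factor(groups)
  if (nlevels(groups) != 2) stop("exactly two groups are required")
  if (any(table(groups) < 2)) stop("each group needs at least 2 participants")
  med <- vapply(sigma_by_participant, stats::median, numeric(1))
  tt <- stats::t.test(med ~ groups)
  list(
    medians = data.frame(participant = names(sigma_by_participant) %||%
                           seq_along(med),
                         median_sigma = unname(med), group = groups),
    t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
    ecdfs = lapply(sigma_by_participant, stats::ecdf)
  )
}
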