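test_that("BOLD modulation is the series standard deviation", {
  expect_equal(bold_modulation(matrix(5, 3, 100)), rep(0, 3))
  t <- seq(0, 600, by = 0.5)
  s <- 2 * sin(2 * pi * t / 30)
  expect_equal(bold_modulation(matrix(s, 1)), 2 / sqrt(2), tolerance = 0.01)
  Y <- matrix(rnorm(200), 2, 100)
  expect_equal(bold_modulation(3 * Y), 3 * bold_modulation(Y))
})

test_that("eccentricity binning matches brute-force enumeration", {
  set.seed(6)
  ecc <- runif(120, 0, 7)
  vals <- ecc + rnorm(120, 0, 0.1)
  prof <- bin_by_eccentricity(vals, ecc, nboot = 50, seed = 1)
  for (b in seq_len(nrow(prof))) {
    inb <- ecc >= prof$bin_lo[b] & ecc < prof$bin_hi[b]
    expect_equal(prof$mean[b], mean(vals[inb]))
    expect_equal(prof$n[b], sum(inb))
  }
  # half-open convention: a unit at exactly 2.0 falls in [2, 3)
  p2 <- bin_by_eccentricity(10, 2.0, nboot = 10)
  expect_equal(p2$n[p2$bin_lo == 2], 1)
  expect_equal(p2$n[p2$bin_lo == 1], 0)
  # empty bins are missing, not zero
  p3 <- bin_by_eccentricity(c(1, 2), c(1.5, 1.7), nboot = 10)
  expect_true(is.na(p3$mean[p3$bin_lo == 5]))
  expect_error(bin_by_eccentricity(1:3, 1:2), "aligned")
})

test_that("normalized histograms carry unit mass and scale invariance", {
  mdl <- data.frame(ecc = c(1.5, 1.7, 3.2), polar = c(0.3, 1, 4),
                    sigma = c(0.5, 1, 2))
  h <- normalized_hist(mdl, "eccentricity")
  expect_equal(sum(h$mass), 1, tolerance = 1e-9)
  expect_equal(h$mass[2], 2 / 3)
  expect_equal(normalized_hist(rbind(mdl, mdl), "eccentricity")$mass, h$mass)
  single <- normalized_hist(data.frame(ecc = rep(2.5, 5)), "eccentricity")
  expect_equal(max(single$mass), 1)
  h0 <- normalized_hist(mdl[0, ], "size")
  expect_true(attr(h0, "empty"))
  expect_true(all(h0$mass == 0))
})

test_that("pair deviations behave like a bounded metric", {
  mk <- function(mass, edges = 0:2) {
    structure(list(dimension = "eccentricity", edges = edges, mass = mass),
              class = "normalized_hist")
  }
  a <- mk(c(0.5, 0.5)); b <- mk(c(0.75, 0.25))
  expect_equal(pair_deviation(a, a)$aggregate, 0)
  expect_equal(pair_deviation(a, b)$aggregate, 0.5)
  expect_equal(pair_deviation(a, b)$per_bin, c(-0.25, 0.25))
  expect_equal(pair_deviation(a, b)$aggregate, pair_deviation(b, a)$aggregate)
  expect_equal(pair_deviation(mk(c(1, 0)), mk(c(0, 1)))$aggregate, 2)
  expect_error(pair_deviation(a, mk(c(0.5, 0.5), edges = 0:2 + 1)), "edges")
})

test_that("deviation ranks run from 1 to n+1 with mid-rank ties", {
  base <- as.list(seq(0.1, 1, length.out = 18))
  low <- deviation_rank(0.05, base)
  expect_equal(low$rank, 1)
  expect_false(low$significant)
  top <- deviation_rank(2, base)
  expect_equal(top$rank, 19)
  expect_true(top$significant)
  tie <- deviation_rank(base[[9]], base)
  expect_equal(tie$rank, 1 + 8 + 0.5)
  expect_error(deviation_rank(1, base[1:4]), "at least 5")
})

test_that("quadrant summaries equal group-by means and flag empties", {
  set.seed(11)
  mdl <- data.frame(x0 = rnorm(80), y0 = rnorm(80), sigma = runif(80, 0.5, 2))
  mod <- runif(80)
  qs <- quadrant_summary(mdl, mod)
  q <- prfrecon:::quadrant_of(mdl$x0, mdl$y0)
  for (qq in c("UL", "UR", "LL", "LR")) {
    expect_equal(qs$mean_sigma[qs$quadrant == qq], mean(mdl$sigma[q == qq]))
    expect_equal(qs$mean_modulation[qs$quadrant == qq], mean(mod[q == qq]))
    expect_equal(qs$n[qs$quadrant == qq], sum(q == qq))
  }
  # four mirror-symmetric pRFs: identical sizes per quadrant
  sym <- data.frame(x0 = c(1, -1, -1, 1), y0 = c(1, 1, -1, -1), sigma = 1.5)
  qs2 <- quadrant_summary(sym)
  expect_true(all(qs2$mean_sigma == 1.5))
  ul <- quadrant_summary(data.frame(x0 = -1, y0 = 1, sigma = 1))
  expect_equal(sum(ul$empty), 3)
  expect_false(ul$empty[ul$quadrant == "UL"])
})

test_that("Euclidean distance is the plain 2-D norm", {
  expect_equal(euclidean_distance(c(1, 2), c(1, 2)), 0)
  expect_equal(euclidean_distance(c(0, 0), c(3, 4)), 5)
  expect_equal(euclidean_distance(c(2, -1), c(-3, 4)),
               euclidean_distance(c(-3, 4), c(2, -1)))
})

test_that("mixed_slope recovers exact and hierarchical slopes", {
  x <- 1:10
  w <- capture_warnings(r <- mixed_slope(2 * x, x, rep("s1", 10)))
  expect_match(w, "least squares", all = FALSE)
  expect_equal(r$slope, 2, tolerance = 1e-9)
  expect_equal(r$r2, 1, tolerance = 1e-9)
  expect_equal(r$method, "ols")
  expect_error(mixed_slope(1:4, rep(1, 4), c(1, 1, 2, 2)), "constant")

  # known fixed slope -0.3 with random subject slopes (sd 0.1)
  set.seed(16)
  S <- rep(1:12, each = 8)
  slopes <- -0.3 + rnorm(12, 0, 0.1)
  ints <- rnorm(12, 0, 0.3)
  xx <- runif(96, -10, 0)
  yy <- ints[S] + slopes[S] * xx + rnorm(96, 0, 0.2)
  fit <- mixed_slope(yy, xx, S)
  expect_equal(fit$method, "lmm")
  expect_lt(abs(fit$slope - (-0.3)), 2 * fit$se)
  expect_lt(fit$p, 0.001)
  expect_lt(fit$r2, 0)                      # sign carried onto r2
})

test_that("null slopes are covered by the confidence interval at nominal rate", {
  set.seed(15)
  cover <- replicate(60, {
    S <- rep(1:6, each = 6)
    xx <- runif(36, 0, 1)
    yy <- rnorm(36)
    f <- suppressWarnings(mixed_slope(yy, xx, S))
    abs(f$slope) < 1.96 * f$se
  })
  expect_gte(mean(cover), 0.9)
})

test_that("size distribution test matches a hand-computed Welch t", {
  sizes <- list(a1 = c(1, 1.2), a2 = c(1.1, 1.5), a3 = c(0.9, 1.0),
                b1 = c(2, 2.2), b2 = c(2.4, 2.0), b3 = c(1.8, 2.6))
  gr <- rep(c("ctl", "gla"), each = 3)
  res <- size_distribution_test(sizes, gr)
  med <- vapply(sizes, median, numeric(1))
  m1 <- med[1:3]; m2 <- med[4:6]
  tt <- (mean(m1) - mean(m2)) / sqrt(var(m1) / 3 + var(m2) / 3)
  expect_equal(res$t, tt, tolerance = 1e-9)
  expect_true(res$t < 0)                     # second group uniformly larger
  expect_equal(length(res$ecdfs), 6)

  same <- size_distribution_test(list(a = c(1, 2), b = c(1, 2),
                                      c = c(1, 3), d = c(1, 3)),
                                 c("x", "y", "x", "y"))
  expect_equal(same$t, 0)
  expect_error(size_distribution_test(sizes[1:3], c("a", "a", "b")),
               "at least 2")
})
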