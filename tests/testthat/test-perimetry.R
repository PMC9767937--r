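test_that("binocular integration takes the per-point maximum over eyes", {
  pts <- perimetry_layout("10-2")
  set.seed(42)
  dl <- -round(runif(nrow(pts), 0, 25), 1)
  dr <- -round(runif(nrow(pts), 0, 25), 1)
  l <- perimetry_grid(pts$x, pts$y, dl, eye = "left", layout = "10-2")
  r <- perimetry_grid(pts$x, pts$y, dr, eye = "right", layout = "10-2")
  b <- integrate_binocular(l, r)
  expect_equal(b$eye, "binocular")
  ord <- order(pts$x, pts$y)
  expect_equal(b$deviation_db, pmax(dl, dr)[ord])

  # identity on zero loss
  z <- integrate_binocular(
    perimetry_grid(0, 3, 0, eye = "left"),
    perimetry_grid(0, 3, 0, eye = "right"))
  expect_equal(z$deviation_db, 0)

  # single worked pair: -5 vs -2 -> -2
  b2 <- integrate_binocular(
    perimetry_grid(3, 3, -5, eye = "left"),
    perimetry_grid(3, 3, -2, eye = "right"))
  expect_equal(b2$deviation_db, -2)
})

test_that("layout mismatches are rejected with the divergent point named", {
  l <- perimetry_grid(c(0, 3), c(3, 3), c(0, 0), eye = "left")
  r1 <- perimetry_grid(0, 3, 0, eye = "right")
  expect_error(integrate_binocular(l, r1), "layout mismatch")
  r2 <- perimetry_grid(c(0, 4), c(3, 3), c(0, 0), eye = "right")
  expect_error(integrate_binocular(l, r2), "\\(4, 3\\)")
  expect_error(integrate_binocular(r2, l), "left-eye")
})

test_that("perimetry grids enforce their invariants", {
  expect_error(perimetry_grid(c(0, 0), c(1, 1), c(0, 0)), "unique")
  expect_error(perimetry_grid(45, 0, 0), "40")
  expect_error(perimetry_grid(0, 0, NA), "finite")
  expect_error(perimetry_grid(numeric(0), numeric(0), numeric(0)), "at least one")
})

test_that("dB-to-contrast follows the decibel power law", {
  expect_equal(round(db_to_contrast(-3), 2), 0.50)
  expect_equal(db_to_contrast(0), 1)
  expect_equal(db_to_contrast(-10), 0.10)
  expect_equal(db_to_contrast(5), 1)          # gains clip to full contrast
  expect_error(db_to_contrast(NaN), "finite")

  # monotone non-decreasing; commutes with binocular max
  set.seed(7)
  d1 <- sort(runif(50, -35, 5))
  expect_true(all(diff(db_to_contrast(d1)) >= 0))
  d2 <- runif(50, -35, 5)
  expect_equal(db_to_contrast(pmax(d1, d2)),
               pmax(db_to_contrast(d1), db_to_contrast(d2)))

  # optional absolute-loss floor
  expect_equal(db_to_contrast(c(-20, -10), floor_db = -15), c(0, 0.10))
})

test_that("contrast masks interpolate exactly at grid nodes", {
  pts <- perimetry_layout("10-2")
  set.seed(3)
  dev <- -round(runif(nrow(pts), 0, 20), 2)
  g <- perimetry_grid(pts$x, pts$y, dev, eye = "binocular", layout = "10-2")
  # 29 px over +/-7 deg -> 0.5 deg/px, so odd-integer nodes coincide with pixels
  mask <- build_contrast_mask(g, list(n_pix = 29, field_radius = 7))
  xs <- seq(-7, 7, length.out = 29)
  inside <- abs(pts$x) <= 7 & abs(pts$y) <= 7
  for (i in which(inside)) {
    col <- match(pts$x[i], xs)
    row <- match(pts$y[i], rev(xs))
    expect_equal(mask$values[row, col], db_to_contrast(dev[i]))
  }
  expect_true(all(mask$values >= 0 & mask$values <= 1))
})

test_that("uniform, quadrant and single-point grids give the expected masks", {
  geom <- list(n_pix = 29, field_radius = 7)
  zero <- archetype_grid("healthy")
  expect_true(all(build_contrast_mask(zero, geom)$values == 1))

  qg <- ul_scotoma(depth = -10)
  mask <- build_contrast_mask(qg, geom)
  xs <- seq(-7, 7, length.out = 29)
  # deep inside the affected quadrant ~ 0.10; opposite quadrant untouched
  expect_equal(mask$values[match(5, rev(xs)), match(-5, xs)], 0.10,
               tolerance = 1e-6)
  expect_equal(mask$values[match(-5, rev(xs)), match(5, xs)], 1)

  single <- perimetry_grid(0, 0, -10, eye = "binocular")
  m1 <- build_contrast_mask(single, geom)
  expect_true(all(abs(m1$values - 0.10) < 1e-12))

  expect_error(build_contrast_mask(perimetry_grid(0, 0, 0, eye = "left"), geom),
               "binocular")
})

test_that("perimetry CSV dialect round-trips", {
  pts <- perimetry_layout("24-2")
  g <- perimetry_grid(pts$x, pts$y, rep(-4, nrow(pts)), eye = "left",
                      layout = "24-2")
  f <- withr::local_tempfile(fileext = ".csv")
  write_perimetry(g, f)
  g2 <- read_perimetry(f, eye = "left", layout = "24-2")
  expect_equal(g2$points, g$points)
  expect_equal(g2$deviation_db, g$deviation_db)
  bad <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(a = 1), bad, row.names = FALSE)
  expect_error(read_perimetry(bad), "columns")
})

test_that("mask export writes a readable CSV matrix", {
  mask <- build_contrast_mask(ul_scotoma(), list(n_pix = 15, field_radius = 7))
  f <- withr::local_tempfile(fileext = ".csv")
  write_mask(mask, f)
  back <- as.matrix(read.csv(f, header = FALSE))
  expect_equal(unname(back), unname(mask$values), tolerance = 1e-12)
})
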