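test_that("forward prediction honours baseline, distance and translation", {
  ap <- small_ap()
  flat <- predict_timeseries(list(x0 = 1, y0 = 1, sigma = 1, beta = 0,
                                  baseline = 2.5), ap)
  expect_true(all(flat == 2.5))
  expect_error(predict_timeseries(list(x0 = 0, y0 = 0, sigma = -1), ap),
               "sigma")

  # pRF far outside all apertures: drive < 1e-3 of an in-field unit's peak
  far <- predict_timeseries(list(x0 = 14, y0 = 0, sigma = 1), ap)
  mid <- predict_timeseries(list(x0 = 0, y0 = 0, sigma = 1), ap)
  expect_lt(max(abs(far)), 1e-3 * max(abs(mid)))

  # translating aperture and centre together leaves the output unchanged
  m <- small_movie()
  shift_px <- 4                       # 1.4 deg at 0.35 deg/px
  shifted <- m
  shifted$frames <- m$frames[, , c((shift_px + 1):41, 1:shift_px)]
  ap_s <- effective_aperture(shifted, "FF")
  d <- 2 * 7 / 40 * shift_px
  a <- predict_timeseries(list(x0 = 1, y0 = -0.5, sigma = 0.8), ap)
  b <- predict_timeseries(list(x0 = 1 - d, y0 = -0.5, sigma = 0.8), ap_s)
  expect_equal(a, b, tolerance = 1e-6)
})

test_that("noiseless voxels are recovered exactly on the grid and refined below 0.05 deg", {
  m <- small_movie()
  sheet <- on_grid_sheet()
  ts <- preprocess(simulate_bold(sheet, m, spec = noiseless_spec()))
  coarse <- prf_fit(ts, small_ap(), grid = small_grid(), refine = FALSE)
  expect_equal(coarse$models$x0, sheet$x0)
  expect_equal(coarse$models$y0, sheet$y0)
  expect_equal(coarse$models$sigma, sheet$sigma)
  fine <- prf_fit(ts, small_ap(), grid = small_grid(), refine = TRUE)
  err <- sqrt((fine$models$x0 - sheet$x0)^2 + (fine$models$y0 - sheet$y0)^2)
  expect_true(all(err < 0.05))
  expect_true(all(fine$models$ve > 0.999))
  # refinement never degrades the coarse VE
  expect_true(all(fine$models$ve >= coarse$models$ve - 1e-12))
})

test_that("candidate order and duplicates do not change the fit", {
  m <- small_movie()
  ts <- preprocess(simulate_bold(on_grid_sheet(), m, spec = noiseless_spec()))
  g1 <- small_grid()
  g2 <- prf_grid_spec(x = rev(g1$x), y = sample(g1$y), sigmas = c(1, 0.5, 2, 1))
  f1 <- prf_fit(ts, small_ap(), grid = g1, refine = FALSE)
  f2 <- prf_fit(ts, small_ap(), grid = g2, refine = FALSE)
  expect_equal(coef(f1), coef(f2))
})

test_that("pure-noise series rarely pass the responsiveness threshold", {
  set.seed(31)
  Y <- matrix(rnorm(300 * 128), 300, 128)
  f <- prf_fit(Y, small_ap(), grid = prf_grid_spec(), refine = FALSE)
  expect_gte(mean(f$models$ve < 0.15), 0.99)
})

test_that("degenerate series yield flagged models, never errors", {
  Y <- rbind(rep(0, 128), rep(3, 128))
  f <- prf_fit(Y, small_ap(), grid = small_grid())
  expect_true(all(f$models$degenerate))
  expect_true(all(f$models$ve == 0))
})

test_that("thresholding keeps responsive in-range models in order", {
  mdl <- data.frame(unit = 1:4,
                    x0 = c(1, 2, 3, 5), y0 = c(0, 0, 0, 5.5),
                    sigma = 1, beta = 1, baseline = 0,
                    ve = c(0.14, 0.15, 0.9, 0.9),
                    ecc = c(1, 2, 3, 7.5), polar = 0, degenerate = FALSE)
  out <- threshold_models(mdl)
  expect_equal(out$unit, c(2, 3))
  expect_equal(attr(out, "n_total"), 4)
  empty <- threshold_models(mdl[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("fit object methods are mutually consistent", {
  m <- small_movie()
  spec <- sim_spec(n_units = 6, seed = 12)
  sheet <- sample_sheet(spec)
  ts <- preprocess(simulate_bold(sheet, m, spec = spec))
  f <- prf_fit(ts, small_ap(), grid = small_grid())
  expect_equal(dim(coef(f)), c(6, 6))
  expect_equal(residuals(f), f$ts - fitted(f))
  expect_equal(f$models$ecc, sqrt(f$models$x0^2 + f$models$y0^2),
               tolerance = 1e-9)
  s <- summary(f)
  expect_s3_class(s, "summary.prf_fit")
  expect_output(print(f), "pRF fit")
  sims <- simulate(f, nsim = 2, seed = 1)
  expect_length(sims, 2)
  expect_equal(dim(sims[[1]]), dim(f$ts))
  tf <- withr::local_tempfile(fileext = ".png")
  grDevices::png(tf); plot(f, ve_min = 0); grDevices::dev.off()
  expect_true(file.exists(tf))
  csv <- withr::local_tempfile(fileext = ".csv")
  write_prf_table(f, csv)
  expect_equal(nrow(read.csv(csv)), 6)
})

test_that("micro-probing localizes single-Gaussian voxels and flags flat ones", {
  m <- small_movie()
  sheet <- data.frame(unit = 1:2, x0 = c(3, 0), y0 = c(2, 0),
                      sigma = c(1, 1), gain = 1, area = "V1")
  ts <- preprocess(simulate_bold(sheet, m, spec = noiseless_spec()))
  pm <- micro_probe(ts, small_ap(), probe_spec(spacing = 1))
  # weights peak at the probe nearest the true centre
  for (i in 1:2) {
    best <- which.max(pm$weights[i, ])
    expect_equal(c(pm$probes$x[best], pm$probes$y[best]),
                 c(sheet$x0[i], sheet$y0[i]))
    expect_lt(abs(pm$summary$x[i] - sheet$x0[i]), 0.75)
    expect_lt(abs(pm$summary$y[i] - sheet$y0[i]), 0.75)
  }
  # centred voxel: radially symmetric weights put the centroid at fixation
  expect_lt(abs(pm$summary$x[2]), 0.3)
  expect_lt(abs(pm$summary$y[2]), 0.3)

  flat <- micro_probe(matrix(0, 1, 128), small_ap(), probe_spec(spacing = 2))
  expect_true(flat$summary$flagged)
  expect_true(is.na(flat$summary$x))
  expect_error(probe_spec(spacing = -1))
})

test_that("probe maps export in long format", {
  pm <- micro_probe(matrix(rnorm(128), 1, 128), small_ap(),
                    probe_spec(spacing = 3.5))
  f <- withr::local_tempfile(fileext = ".csv")
  write_probe_map(pm, f)
  d <- read.csv(f)
  expect_equal(nrow(d), ncol(pm$weights))
  expect_true(all(d$weight >= 0))
})
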