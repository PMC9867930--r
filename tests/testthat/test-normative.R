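test_that("Gaussian cutoffs and boundary conventions follow the percentile partition", {
  g <- raster_geometry(10, 10)
  m <- build_normative(30, 3, g)
  q01 <- 30 + qnorm(0.01) * 3
  q05 <- 30 + qnorm(0.05) * 3
  q95 <- 30 + qnorm(0.95) * 3
  q99 <- 30 + qnorm(0.99) * 3
  expect_equal(q01, 30 - 2.3263 * 3, tolerance = 1e-4)

  at <- function(v) classify_thickness(m, matrix(v, 10, 10))$categories[1, 1]
  labels <- deviation_categories()
  expect_identical(labels[at(30)], "wnl")              # mean is inside 5-95%
  expect_identical(labels[at(30 - 3 * 3)], "abn1")     # z = -3 below 1st pctile
  expect_identical(labels[at(30 + 3 * 3)], "sup99")    # z = +3 above 99th
  # exact-boundary conventions: q05/q95 within normal limits, q01 borderline,
  # q99 in the milder supernormal band
  expect_identical(labels[at(q05)], "wnl")
  expect_identical(labels[at(q95)], "wnl")
  expect_identical(labels[at(q01)], "abn5")
  expect_identical(labels[at(q99)], "sup95")
  expect_identical(labels[at(q01 - 1e-9)], "abn1")
  expect_identical(labels[at(q99 + 1e-9)], "sup99")
})

test_that("model construction validates SD positivity, fovea bounds and shape", {
  g <- raster_geometry(8, 8)
  expect_error(build_normative(30, 0, g), "strictly positive")
  sd_bad <- matrix(3, 8, 8); sd_bad[5, 2] <- -1
  expect_error(build_normative(30, sd_bad, g), "\\(5, 2\\)")
  expect_error(raster_geometry(8, 8, fovea_px = c(20, 4)), "outside")
  m <- build_normative(30, 3, g)
  expect_error(classify_thickness(m, matrix(30, 4, 4)), "shape")
})

test_that("GCIPL composition adds means exactly and composes SDs with correlation", {
  mods <- fixture_models(32)
  gcipl <- compose_gcipl(mods$gcl, mods$ipl, rho = 0.5)
  expect_equal(gcipl$mean, mods$gcl$mean + mods$ipl$mean)
  expect_equal(gcipl$sd,
               sqrt(mods$gcl$sd^2 + mods$ipl$sd^2 + mods$gcl$sd * mods$ipl$sd))
  # rho = 1 degenerates to the simple sum of SDs
  g1 <- compose_gcipl(mods$gcl, mods$ipl, rho = 1)
  expect_equal(g1$sd, mods$gcl$sd + mods$ipl$sd)
})

test_that("ridge mean surface peaks at the requested eccentricity on a fovea transect", {
  g <- raster_geometry(101, 101, fov_deg = c(15, 15))
  m <- build_normative(ridge_spec(50, 10, peak_ecc_mm = 2, width_mm = 0.9), 3, g)
  transect <- m$mean[51, ]                   # horizontal through the fovea
  x_mm <- (seq_len(101) - 51) * g$pitch_mm[2]
  peaks <- range(x_mm[transect == max(transect)])
  # analytic argmax of the ridge profile is at |x| = 2 mm
  expect_lt(abs(abs(peaks[1]) - 2), g$pitch_mm[2])
  expect_lt(abs(peaks[2] - 2), g$pitch_mm[2])
})

test_that("every finite thickness gets exactly one category and counts conserve", {
  g <- raster_geometry(25, 25)
  m <- build_normative(30, 3, g)
  set.seed(101)
  for (i in 1:5) {
    th <- matrix(rnorm(625, 30, 6), 25, 25)
    dm <- classify_thickness(m, th)
    expect_true(all(dm$categories %in% 1:5))
    expect_identical(sum(tabulate(dm$categories, 6L)), 625L)
  }
})

test_that("decreasing thickness never moves a pixel toward the supernormal side", {
  g <- raster_geometry(2, 2)
  m <- build_normative(30, 3, g)
  vals <- seq(45, 15, by = -0.25)
  cats <- vapply(vals, function(v)
    classify_thickness(m, matrix(v, 2, 2))$categories[1, 1], integer(1))
  # category order sup99 > sup95 > wnl > abn5 > abn1; recode to that scale
  scale <- c(abn1 = -2L, abn5 = -1L, wnl = 0L, sup95 = 1L, sup99 = 2L)
  expect_true(all(diff(scale[deviation_categories()[cats]]) <= 0))
})

test_that("self-drawn thickness flags 5% at each tail (Monte-Carlo calibration)", {
  g <- raster_geometry(64, 64)
  m <- build_normative(30, 3, g)
  set.seed(7)
  n_draw <- 300L            # 300 rasters x 4096 px > 1e6 draws
  lo <- hi <- numeric(n_draw)
  for (i in seq_len(n_draw)) {
    dm <- classify_thickness(m, matrix(rnorm(4096, 30, 3), 64, 64))
    lo[i] <- mean(dm$categories %in% 1:2)
    hi[i] <- mean(dm$categories %in% 4:5)
  }
  n_px <- n_draw * 4096
  se <- sqrt(0.05 * 0.95 / n_px)
  expect_lt(abs(mean(lo) - 0.05), 3 * se)
  expect_lt(abs(mean(hi) - 0.05), 3 * se)
})

test_that("missing thickness is excluded and an all-missing raster gives no extents", {
  g <- raster_geometry(6, 6)
  m <- build_normative(30, 3, g)
  th <- matrix(30, 6, 6); th[2, 3] <- -1   # sentinel
  dm <- classify_thickness(m, th)
  expect_identical(dm$categories[2, 3], 6L)
  all_missing <- classify_thickness(m, matrix(-1, 6, 6))
  expect_true(all(all_missing$categories == 6L))
  expect_error(extent_summary(all_missing), "no informative")
})

test_that("normative models round-trip through the binary + JSON serialization", {
  mods <- fixture_models(32)
  stem <- file.path(withr::local_tempdir(), "gcl")
  save_normative(mods$gcl, stem)
  back <- load_normative(stem)
  expect_equal(back$mean, mods$gcl$mean, tolerance = 1e-6)  # float32 storage
  expect_equal(back$sd, mods$gcl$sd, tolerance = 1e-6)
  expect_identical(back$layer, "GCL")
  expect_true(macdev:::same_geometry(back$geometry, mods$gcl$geometry))
})
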