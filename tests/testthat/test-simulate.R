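test_that("noiseless null eye reproduces the normative mean surfaces", {
  mods <- fixture_models(32)
  sp <- eye_spec("NORMAL", 0, noise_sd_scale = 1e-9, seed = 1)
  e <- simulate_eye(mods$gcl, mods$ipl, sp)
  expect_equal(e$gcl, mods$gcl$mean, tolerance = 1e-6)
  expect_equal(e$ipl, mods$ipl$mean, tolerance = 1e-6)
})

test_that("an arcuate superior defect thins only the superior hemifield", {
  g <- raster_geometry(64, 64)
  f <- defect_field(g, "arcuate_superior", magnitude = 20)
  expect_equal(max(f), 20)
  expect_true(all(f >= 0))
  sup <- f[1:32, ]; inf <- f[33:64, ]
  expect_gt(mean(sup), 1)                 # substantial superior loss
  expect_lt(mean(inf), 0.01 * mean(sup))  # inferior essentially untouched
  # the simulated eye's expected thinning matches the analytic split
  sp <- eye_spec("GLAUCOMA", 20, "arcuate_superior",
                 noise_sd_scale = 1e-9, seed = 2)
  mods <- fixture_models(64)
  e <- simulate_eye(mods$gcl, mods$ipl, sp, gcl_fraction = 0.6)
  expect_equal(mods$gcl$mean - e$gcl, 0.6 * f, tolerance = 1e-5)
})

test_that("same spec and seed give bit-identical rasters; OS eyes are mirrored", {
  mods <- fixture_models(32)
  sp <- eye_spec("GLAUCOMA", 10, "hemifield", seed = 9)
  e1 <- simulate_eye(mods$gcl, mods$ipl, sp)
  e2 <- simulate_eye(mods$gcl, mods$ipl, sp)
  expect_identical(e1$gcl, e2$gcl)
  expect_identical(e1$ipl, e2$ipl)
  sp_os <- eye_spec("GLAUCOMA", 10, "hemifield", laterality = "OS", seed = 9)
  e_os <- simulate_eye(mods$gcl, mods$ipl, sp_os)
  expect_identical(e_os$gcl, mirror_lr(e1$gcl))
})

test_that("eye-level noise preserves the per-pixel marginal distribution", {
  # with a between-eye common component, each pixel is still N(mean, SD^2):
  # check the standardized residual variance over many eyes
  mods <- fixture_models(32)
  set.seed(12)
  z2 <- replicate(200, {
    sp <- eye_spec("NORMAL", 0, noise_correlation = 0.5,
                   seed = sample.int(1e6, 1))
    e <- simulate_eye(mods$gcl, mods$ipl, sp)
    mean(((e$gcl - mods$gcl$mean) / mods$gcl$sd)^2)
  })
  expect_equal(mean(z2), 1, tolerance = 0.05)
})

test_that("cohort simulation is reproducible and respects group structure", {
  mods <- fixture_models(32)
  empty <- simulate_cohort(mods$gcl, mods$ipl,
                           n_per_group = c(NORMAL = 0, SUSPECT = 0, GLAUCOMA = 0))
  expect_identical(nrow(empty$manifest), 0L)

  c1 <- simulate_cohort(mods$gcl, mods$ipl,
                        n_per_group = c(NORMAL = 4, SUSPECT = 2, GLAUCOMA = 4),
                        seed = 33)
  c2 <- simulate_cohort(mods$gcl, mods$ipl,
                        n_per_group = c(NORMAL = 4, SUSPECT = 2, GLAUCOMA = 4),
                        seed = 33)
  expect_identical(c1$manifest, c2$manifest)
  expect_identical(c1$eyes, c2$eyes)
  expect_true(all(c1$manifest$defect_magnitude[c1$manifest$group == "NORMAL"] == 0))
  expect_true(all(c1$manifest$defect_magnitude[c1$manifest$group == "GLAUCOMA"] > 0))
})

test_that("a larger defect-magnitude median lowers mean global GCL thickness", {
  mods <- fixture_models(64)
  mean_global <- function(median_um) {
    ch <- simulate_cohort(mods$gcl, mods$ipl,
                          n_per_group = c(NORMAL = 0, SUSPECT = 0, GLAUCOMA = 50),
                          defect_median_um = median_um, seed = 77)
    mean(vapply(ch$eyes, function(e) global_mean(e$grid_gcl), numeric(1)))
  }
  expect_lt(mean_global(10), mean_global(2))
})

test_that("rendering paints palette colors exactly and conserves counts", {
  g <- raster_geometry(20, 20)
  pal <- default_palette()
  wnl_map <- deviation_map(matrix(3L, 20, 20), g)
  img <- render_deviation_map(wnl_map, pal)
  green <- pal$colors["wnl", ] / 255
  expect_true(all(img[, , 1] == green[1] & img[, , 2] == green[2] &
                    img[, , 3] == green[3]))

  cats <- matrix(3L, 20, 20)
  cats[cbind(c(1, 3, 5, 7, 9, 11, 13), c(2, 4, 6, 8, 10, 12, 14))] <- 1L
  img2 <- render_deviation_map(deviation_map(cats, g), pal)
  red <- pal$colors["abn1", ] / 255
  n_red <- sum(img2[, , 1] == red[1] & img2[, , 2] == red[2] &
                 img2[, , 3] == red[3])
  expect_identical(n_red, 7L)

  bad_pal <- pal
  bad_pal$colors["abn5", ] <- bad_pal$colors["abn1", ]
  expect_error(render_deviation_map(wnl_map, bad_pal), "duplicate")
})

test_that("normal eyes flag about 5% of pixels at each tail (calibration inheritance)", {
  # the between-eye noise component spreads each eye's flagged fraction, but
  # the mean across eyes must stay at the nominal 5% tail mass
  mods <- fixture_models(64)
  fr <- vapply(1:150, function(i) {
    sp <- eye_spec("NORMAL", 0, noise_sd_scale = 1, seed = 5000 + i)
    e <- simulate_eye(mods$gcl, mods$ipl, sp)
    dm <- classify_thickness(mods$gcl, e$gcl)
    c(mean(dm$categories %in% 1:2), mean(dm$categories %in% 4:5))
  }, numeric(2))
  se <- apply(fr, 1, stats::sd) / sqrt(ncol(fr))
  expect_lt(abs(mean(fr[1, ]) - 0.05), 3 * se[1])
  expect_lt(abs(mean(fr[2, ]) - 0.05), 3 * se[2])
})
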