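test_that("GCIPL grid is the elementwise layer sum with missing propagation", {
  gcl <- thickness_grid(matrix(25, 8, 8), "GCL")
  ipl <- thickness_grid(matrix(25, 8, 8), "IPL")
  expect_equal(gcipl_grid(gcl, ipl)$values, matrix(50, 8, 8))

  ipl0 <- thickness_grid(matrix(0, 8, 8), "IPL")
  expect_equal(gcipl_grid(gcl, ipl0)$values, gcl$values)

  vals <- matrix(25, 8, 8); vals[3, 4] <- NA
  ipl_na <- thickness_grid(vals, "IPL")
  out <- gcipl_grid(gcl, ipl_na)$values
  expect_true(is.na(out[3, 4]))
  expect_equal(out[-(3 + 8 * 3)], matrix(50, 8, 8)[-(3 + 8 * 3)])

  expect_error(gcipl_grid(gcl, gcl), "GCL grid and an IPL grid")
})

test_that("the default sector map satisfies the 48-cell 5+5 invariants", {
  sm <- default_sector_map()
  a <- sm$assignment
  expect_identical(sum(a != "UNUSED"), 48L)
  expect_identical(sum(a == "UNUSED"), 16L)
  expect_false(any(grepl("^S", a[5:8, ])))
  expect_false(any(grepl("^I", a[1:4, ])))
  for (k in 1:5) {
    s_cells <- which(a == paste0("S", k), arr.ind = TRUE)
    i_cells <- which(a == paste0("I", k), arr.ind = TRUE)
    # mirror symmetry Sk <-> Ik about the horizontal midline
    expect_setequal(paste(9 - s_cells[, 1], s_cells[, 2]),
                    paste(i_cells[, 1], i_cells[, 2]))
  }
})

test_that("invalid sector maps are rejected", {
  a <- default_sector_map()$assignment
  b <- a; b[1, 2] <- "UNUSED"
  expect_error(sector_map(b), "48")
  b <- a; b[5:8, ] <- a[1:4, ]             # superior labels in inferior rows
  expect_error(sector_map(b), "rows")
  b <- a; b[b == "S1"] <- "S2"; b[b == "I1"] <- "I2"
  b[1, 2] <- "S1"; b[8, 3] <- "I1"         # breaks mirror symmetry
  expect_error(sector_map(b), "mirror")
})

test_that("sector means match an enumeration oracle, incl. missing cells and mirroring", {
  sm <- default_sector_map()
  uniform <- thickness_grid(matrix(50, 8, 8))
  expect_equal(sector_means(uniform, sm),
               setNames(rep(50, 10), c(paste0("S", 1:5), paste0("I", 1:5))))

  # deterministic ramp grid: value (r-1)*8 + (c-1)
  ramp <- matrix(0, 8, 8)
  for (r in 1:8) for (c in 1:8) ramp[r, c] <- (r - 1) * 8 + (c - 1)
  g <- thickness_grid(ramp)
  expect_equal(sector_means(g, sm), bf_sector_means(ramp, sm$assignment))

  set.seed(5)
  for (i in 1:10) {
    vals <- matrix(runif(64, 10, 90), 8, 8)
    vals[sample(64, 6)] <- NA
    g <- thickness_grid(vals)
    expect_equal(sector_means(g, sm), bf_sector_means(vals, sm$assignment))
  }
  # an all-missing sector is reported missing
  vals <- matrix(50, 8, 8)
  vals[sm$assignment == "S3"] <- NA
  expect_true(is.na(sector_means(thickness_grid(vals), sm)[["S3"]]))

  # OS grid mirrored into OD orientation aggregates like its OD twin
  set.seed(6)
  od <- matrix(runif(64, 20, 80), 8, 8)
  os_acquired <- od[, 8:1]
  expect_equal(sector_means(mirror_grid(thickness_grid(os_acquired)), sm),
               sector_means(thickness_grid(od), sm))
})

test_that("global mean averages the central 6 x 6 superpixels", {
  expect_equal(global_mean(thickness_grid(matrix(62.2, 8, 8))), 62.2)

  vals <- matrix(0, 8, 8); vals[2:7, 2:7] <- 10
  expect_equal(global_mean(thickness_grid(vals)), 10)

  set.seed(7)
  vals <- matrix(runif(64, 10, 90), 8, 8)
  expect_equal(global_mean(thickness_grid(vals)), mean(vals[2:7, 2:7]))

  vals[2:7, 2:7] <- NA
  expect_true(is.na(global_mean(thickness_grid(vals))))
})

test_that("aggregation is linear and commutes with the GCIPL sum", {
  sm <- default_sector_map()
  set.seed(8)
  vals <- matrix(runif(64, 10, 90), 8, 8)
  g <- thickness_grid(vals)
  expect_equal(sector_means(thickness_grid(2 * vals + 5), sm),
               2 * sector_means(g, sm) + 5)

  ipl_vals <- matrix(runif(64, 10, 40), 8, 8)
  gcl <- thickness_grid(vals, "GCL"); ipl <- thickness_grid(ipl_vals, "IPL")
  expect_equal(sector_means(gcipl_grid(gcl, ipl), sm),
               sector_means(gcl, sm) + sector_means(ipl, sm))
})

test_that("grid and sector-map CSVs round-trip including missing fields", {
  dir <- withr::local_tempdir()
  vals <- matrix(round(runif(64, 10, 90), 2), 8, 8); vals[4, 5] <- NA
  g <- thickness_grid(vals, "IPL")
  p <- file.path(dir, "grid.csv")
  write_grid_csv(g, p)
  back <- read_grid_csv(p, layer = "IPL")
  expect_equal(back$values, vals)
  expect_identical(back$layer, "IPL")

  sm <- default_sector_map()
  p2 <- file.path(dir, "sectors.csv")
  write_sector_map_csv(sm, p2)
  expect_identical(read_sector_map_csv(p2)$assignment, sm$assignment)
})

test_that("raster-to-grid averaging matches a direct window computation", {
  g <- raster_geometry(80, 80, fov_deg = c(24, 24))  # grid spans whole raster
  cc <- pixel_coords_mm(g)
  th <- matrix(runif(6400, 20, 60), 80, 80)
  grid <- raster_to_grid(th, g, grid_fov_deg = 24)
  half <- 12 * g$mm_per_degree
  for (gr in c(1, 4, 8)) for (gc in c(2, 5, 7)) {
    in_cell <- cc$y >= -half + (gr - 1) * half / 4 & cc$y < -half + gr * half / 4 &
      cc$x >= -half + (gc - 1) * half / 4 & cc$x < -half + gc * half / 4
    expect_equal(grid$values[gr, gc], mean(th[in_cell]))
  }
})
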