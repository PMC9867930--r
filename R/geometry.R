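#' Raster geometry of a fovea-centered macular scan
#'
#' Describes the pixel raster on which thickness surfaces and deviation maps
#' live: its shape, the physical pixel pitch, and the fovea position.  The
#' Spectralis-style posterior-pole volume covers 30 degrees (horizontal) by
#' 25 degrees (vertical) of scan angle centered on the fovea; scan angle is
#' converted to millimetres on the retina at a fixed rate
#' (`mm_per_degree`, default 0.3 mm/degree).
#'
#' All rasters in this package are stored in right-eye (OD) orientation:
#' row 1 is most superior, column 1 is most temporal.  Left eyes are mirrored
#' into this convention before any analysis.
#'
#' @param rows,cols raster dimensions in pixels.
#' @param fov_deg field of view `(vertical, horizontal)` in degrees of scan
#'   angle.
#' @param mm_per_degree conversion from scan angle to retinal distance.
#' @param fovea_px fovea position `(row, col)` in pixels (1-based, may be
#'   fractional); defaults to the raster center.
#' @return An object of class `raster_geometry`: a list with `rows`, `cols`,
#'   `pitch_mm` (`(row, col)` mm per pixel), `fovea_px`, `fov_deg`,
#'   `mm_per_degree`.
#' @examples
#' g <- raster_geometry(64, 64)
#' g$pitch_mm
#' @export
raster_geometry <- function(rows = 384L, cols = 384L,
                            fov_deg = c(25, 30),
                            mm_per_degree = 0.3,
                            fovea_px = NULL) {
  rows <- as.integer(rows); cols <- as.integer(cols)
  stopifnot(rows > 0L, cols > 0L, length(fov_deg) == 2L, all(fov_deg > 0),
            mm_per_degree > 0)
  if (is.null(fovea_px)) fovea_px <- c((rows + 1) / 2, (cols + 1) / 2)
  if (fovea_px[1] < 1 || fovea_px[1] > rows ||
      fovea_px[2] < 1 || fovea_px[2] > cols) {
    stop("fovea_px (", fovea_px[1], ", ", fovea_px[2],
         ") lies outside the ", rows, " x ", cols, " raster")
  }
  pitch_mm <- c(fov_deg[1] * mm_per_degree / rows,
                fov_deg[2] * mm_per_degree / cols)
  structure(list(rows = rows, cols = cols, pitch_mm = pitch_mm,
                 fovea_px = as.numeric(fovea_px), fov_deg = as.numeric(fov_deg),
                 mm_per_degree = mm_per_degree),
            class = "raster_geometry")
}

#' @export
print.raster_geometry <- function(x, ...) {
  cat(sprintf("raster_geometry: %d x %d px, pitch %.4f x %.4f mm/px, fovea (%.1f, %.1f)\n",
              x$rows, x$cols, x$pitch_mm[1], x$pitch_mm[2],
              x$fovea_px[1], x$fovea_px[2]))
  invisible(x)
}

#' @rdname raster_geometry
#' @param x object to test.
#' @export
is_raster_geometry <- function(x) inherits(x, "raster_geometry")

same_geometry <- function(a, b, tol = 1e-9) {
  a$rows == b$rows && a$cols == b$cols &&
    all(abs(a$pitch_mm - b$pitch_mm) < tol) &&
    all(abs(a$fovea_px - b$fovea_px) < tol)
}

#' Pixel-center coordinates in millimetres relative to the fovea
#'
#' Returns matrices of the physical x (temporal -> nasal, along columns) and
#' y (superior -> inferior, along rows) coordinate of every pixel center,
#' in mm, with the fovea at the origin.  Pixel `(r, c)` has center
#' `((r - fovea_row) * pitch_row, (c - fovea_col) * pitch_col)`.
#'
#' @param geometry a [raster_geometry()].
#' @return list with `x` and `y` matrices (`rows x cols`) and the radial
#'   eccentricity `r = sqrt(x^2 + y^2)`.
#' @export
pixel_coords_mm <- function(geometry) {
  stopifnot(is_raster_geometry(geometry))
  yv <- (seq_len(geometry$rows) - geometry$fovea_px[1]) * geometry$pitch_mm[1]
  xv <- (seq_len(geometry$cols) - geometry$fovea_px[2]) * geometry$pitch_mm[2]
  x <- matrix(xv, geometry$rows, geometry$cols, byrow = TRUE)
  y <- matrix(yv, geometry$rows, geometry$cols)
  list(x = x, y = y, r = sqrt(x^2 + y^2))
}

#' Mirror a raster left-right (OS to OD orientation)
#'
#' Left-eye (OS) scans are acquired in mirror-image orientation; flipping
#' columns brings them into the package's right-eye convention.
#'
#' @param m a matrix.
#' @return the matrix with column order reversed.
#' @export
mirror_lr <- function(m) {
  stopifnot(is.matrix(m))
  m[, rev(seq_len(ncol(m))), drop = FALSE]
}

#' Average a thickness raster into the 8 x 8 posterior-pole superpixel grid
#'
#' The 8 x 8 grid of 64 superpixels covers the central 24 x 24 degrees
#' centered on the fovea (each superpixel spans 3 x 3 degrees of scan angle).
#' Each superpixel value is the unweighted mean of the raster pixels whose
#' centers fall inside it; negative raster values (the missing-data sentinel)
#' are ignored, and a superpixel with no valid pixels is `NA`.
#'
#' @param thickness raster matrix of thickness in micrometres.
#' @param geometry the [raster_geometry()] of the raster.
#' @param layer layer label for the resulting grid.
#' @param grid_fov_deg angular span of the full grid (default 24 degrees).
#' @return a [thickness_grid()].
#' @export
raster_to_grid <- function(thickness, geometry, layer = "GCL",
                           grid_fov_deg = 24) {
  stopifnot(is.matrix(thickness), is_raster_geometry(geometry),
            nrow(thickness) == geometry$rows, ncol(thickness) == geometry$cols)
  half_mm <- grid_fov_deg / 2 * geometry$mm_per_degree
  cc <- pixel_coords_mm(geometry)
  # superpixel index 1..8 along each axis; 0/9 outside the grid window
  idx <- function(u) {
    i <- floor((u + half_mm) / (2 * half_mm) * 8) + 1
    i[u >= half_mm] <- 9L   # half-open on the far edge
    i
  }
  ri <- idx(cc$y); ci <- idx(cc$x)
  keep <- ri >= 1 & ri <= 8 & ci >= 1 & ci <= 8
  vals <- thickness
  vals[vals < 0] <- NA_real_
  g <- matrix(NA_real_, 8, 8)
  ok <- keep & !is.na(vals)
  if (any(ok)) {
    cell <- (ri[ok] - 1L) * 8L + ci[ok]          # row-major cell id 1..64
    means <- tapply(vals[ok], cell, mean)
    k <- as.integer(names(means))
    g[cbind((k - 1L) %/% 8L + 1L, (k - 1L) %% 8L + 1L)] <- as.numeric(means)
  }
  thickness_grid(g, layer = layer)
}
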