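# Perifoveal elliptical annulus: specification, membership, and direct
# least-squares fitting of its boundaries from overlay pixels.

#' Elliptical annulus specification
#'
#' The perifoveal region of highest ganglion-cell density: an axis-aligned
#' (or slightly rotated) ellipse of 4.8 x 4.0 mm diameter around the fovea,
#' excluding a central oval of 1.2 x 1.0 mm diameter covering the foveola.
#' Sizes are stored as semi-axes `(a, b)` with `a` horizontal (temporal-nasal)
#' and `b` vertical, in millimetres.
#'
#' @param center_px annulus center `(row, col)` in pixels.
#' @param outer_semiaxes_mm outer ellipse semi-axes, default `c(2.4, 2.0)`.
#' @param inner_semiaxes_mm inner exclusion semi-axes, default `c(0.6, 0.5)`.
#' @param rotation_deg rotation of both ellipses, degrees (expected ~0).
#' @return object of class `annulus_spec`.
#' @examples
#' annulus_spec(c(32.5, 32.5))
#' @export
annulus_spec <- function(center_px,
                         outer_semiaxes_mm = c(2.4, 2.0),
                         inner_semiaxes_mm = c(0.6, 0.5),
                         rotation_deg = 0) {
  stopifnot(length(center_px) == 2L,
            length(outer_semiaxes_mm) == 2L, length(inner_semiaxes_mm) == 2L,
            all(outer_semiaxes_mm > 0), all(inner_semiaxes_mm > 0))
  if (!all(outer_semiaxes_mm > inner_semiaxes_mm)) {
    stop("outer semi-axes must exceed inner semi-axes componentwise")
  }
  structure(list(center_px = as.numeric(center_px),
                 outer_semiaxes_mm = as.numeric(outer_semiaxes_mm),
                 inner_semiaxes_mm = as.numeric(inner_semiaxes_mm),
                 rotation_deg = rotation_deg),
            class = "annulus_spec")
}

#' @export
print.annulus_spec <- function(x, ...) {
  cat(sprintf(
    "annulus_spec: center (%.1f, %.1f) px, outer %.2f x %.2f mm, inner %.2f x %.2f mm, rot %.1f deg\n",
    x$center_px[1], x$center_px[2],
    x$outer_semiaxes_mm[1], x$outer_semiaxes_mm[2],
    x$inner_semiaxes_mm[1], x$inner_semiaxes_mm[2], x$rotation_deg))
  invisible(x)
}

#' Annulus membership mask for a raster
#'
#' A pixel belongs to the annulus when its center (in mm relative to the
#' annulus center) lies inside or on the outer ellipse and strictly outside
#' the inner ellipse.
#'
#' @param annulus an [annulus_spec()].
#' @param geometry a [raster_geometry()].
#' @return logical matrix.
#' @export
annulus_mask <- function(annulus, geometry) {
  stopifnot(inherits(annulus, "annulus_spec"), is_raster_geometry(geometry))
  yv <- (seq_len(geometry$rows) - annulus$center_px[1]) * geometry$pitch_mm[1]
  xv <- (seq_len(geometry$cols) - annulus$center_px[2]) * geometry$pitch_mm[2]
  x <- matrix(xv, geometry$rows, geometry$cols, byrow = TRUE)
  y <- matrix(yv, geometry$rows, geometry$cols)
  th <- annulus$rotation_deg * pi / 180
  u <- x * cos(th) + y * sin(th)
  v <- -x * sin(th) + y * cos(th)
  q <- function(ax) (u / ax[1])^2 + (v / ax[2])^2
  q(annulus$outer_semiaxes_mm) <= 1 & q(annulus$inner_semiaxes_mm) > 1
}

# Direct least-squares ellipse fit (Halir & Flusser's numerically stable
# formulation of Fitzgibbon's method).  Input: x, y point coordinates.
# Output: conic coefficients (A, B, C, D, E, F) with the ellipse constraint
# 4AC - B^2 = 1.
fit_ellipse_conic <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 6L)
  mx <- mean(x); my <- mean(y)
  sc <- max(stats::sd(x), stats::sd(y), .Machine$double.eps)
  xs <- (x - mx) / sc; ys <- (y - my) / sc
  D1 <- cbind(xs^2, xs * ys, ys^2)
  D2 <- cbind(xs, ys, 1)
  S1 <- crossprod(D1); S2 <- crossprod(D1, D2); S3 <- crossprod(D2)
  T2 <- -solve(S3, t(S2))
  M <- S1 + S2 %*% T2
  # premultiply by inv(C1), C1 = [[0,0,2],[0,-1,0],[2,0,0]]
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(M)
  # pick the eigenvector with 4ac - b^2 > 0
  cond <- 4 * Re(ev$vectors[1, ]) * Re(ev$vectors[3, ]) - Re(ev$vectors[2, ])^2
  ok <- which(cond > 0)
  if (length(ok) == 0L) stop("ellipse fit failed: no elliptical solution")
  a1 <- Re(ev$vectors[, ok[1]])
  a2 <- as.numeric(T2 %*% a1)
  co <- c(a1, a2)   # in scaled coordinates
  # unscale: substitute xs = (x - mx)/sc, ys = (y - my)/sc
  A <- co[1] / sc^2
  B <- co[2] / sc^2
  C <- co[3] / sc^2
  D <- -2 * co[1] * mx / sc^2 - co[2] * my / sc^2 + co[4] / sc
  E <- -co[2] * mx / sc^2 - 2 * co[3] * my / sc^2 + co[5] / sc
  FF <- co[1] * mx^2 / sc^2 + co[2] * mx * my / sc^2 + co[3] * my^2 / sc^2 -
    co[4] * mx / sc - co[5] * my / sc + co[6]
  c(A = A, B = B, C = C, D = D, E = E, F = FF)
}

# Convert conic coefficients to geometric parameters.
conic_to_geom <- function(co) {
  if (co[["A"]] < 0) co <- -co   # eigenvector sign is arbitrary
  A <- co[["A"]]; B <- co[["B"]]; C <- co[["C"]]
  D <- co[["D"]]; E <- co[["E"]]; FF <- co[["F"]]
  den <- 4 * A * C - B^2
  if (den <= 0) stop("conic is not an ellipse")
  x0 <- (B * E - 2 * C * D) / den
  y0 <- (B * D - 2 * A * E) / den
  # translate to center: constant term there
  Fc <- A * x0^2 + B * x0 * y0 + C * y0^2 + D * x0 + E * y0 + FF
  # eigen-decompose the quadratic form [[A, B/2], [B/2, C]]
  Q <- matrix(c(A, B / 2, B / 2, C), 2, 2)
  ee <- eigen(Q, symmetric = TRUE)
  lam <- ee$values                 # decreasing
  if (any(lam <= 0) || Fc >= 0) stop("degenerate ellipse")
  axes <- sqrt(-Fc / lam)          # lam sorted decreasing -> axes increasing
  # orientation of the major axis (eigenvector of the smaller eigenvalue)
  vmaj <- ee$vectors[, 2]
  ang <- atan2(vmaj[2], vmaj[1]) * 180 / pi
  ang <- ((ang + 90) %% 180) - 90
  list(center = c(x = x0, y = y0),
       semiaxes = c(major = axes[2], minor = axes[1]),
       angle_deg = ang)
}

#' Fit the annulus boundary ellipses to overlay pixels
#'
#' Recovers the annulus geometry from a deviation-map image the way the
#' original analysis did: candidate boundary pixels (the overlay-colored
#' annulus graphics, or any supplied boundary mask) are split into outer and
#' inner sets by their normalized radial distance under a prior annulus
#' spec, and each set is fit with a direct algebraic least-squares ellipse
#' (Fitzgibbon's ellipse-specific constraint, Halir-Flusser formulation).
#'
#' @param boundary_px two-column matrix `(row, col)` of candidate boundary
#'   pixel coordinates, **or** a logical mask matrix, **or** an RGB image
#'   array in which overlay-colored pixels (per `palette`) are the
#'   candidates.
#' @param geometry a [raster_geometry()].
#' @param prior an [annulus_spec()] prior used to split candidates into
#'   outer/inner sets (membership window `radial_window` around each
#'   boundary).
#' @param palette palette whose `overlay` color marks boundary pixels when
#'   `boundary_px` is an RGB image.
#' @param radial_window half-width of the normalized-radius window used to
#'   assign candidates to a boundary (default 0.35).
#' @return fitted [annulus_spec()] with attribute `"fit"` carrying per-
#'   boundary residual diagnostics.
#' @export
fit_annulus <- function(boundary_px, geometry, prior,
                        palette = default_palette(), radial_window = 0.35) {
  stopifnot(is_raster_geometry(geometry), inherits(prior, "annulus_spec"))
  if (is.array(boundary_px) && length(dim(boundary_px)) == 3L) {
    img255 <- round(boundary_px * 255)
    m <- img255[, , 1] == palette$overlay[1] &
      img255[, , 2] == palette$overlay[2] &
      img255[, , 3] == palette$overlay[3]
    boundary_px <- which(m, arr.ind = TRUE)
  } else if (is.logical(boundary_px) && is.matrix(boundary_px)) {
    boundary_px <- which(boundary_px, arr.ind = TRUE)
  }
  stopifnot(is.matrix(boundary_px), ncol(boundary_px) == 2L)
  # mm coordinates relative to the prior center
  x <- (boundary_px[, 2] - prior$center_px[2]) * geometry$pitch_mm[2]
  y <- (boundary_px[, 1] - prior$center_px[1]) * geometry$pitch_mm[1]
  nr <- function(ax) sqrt((x / ax[1])^2 + (y / ax[2])^2)
  r_out <- nr(prior$outer_semiaxes_mm)
  r_in <- nr(prior$inner_semiaxes_mm)
  sel_out <- abs(r_out - 1) <= radial_window
  sel_in <- abs(r_in - 1) <= radial_window & !sel_out
  fit_one <- function(sel, which_b) {
    if (sum(sel) < 6L) {
      stop("annulus fit rejected: only ", sum(sel), " candidate pixels for the ",
           which_b, " boundary (need >= 6)")
    }
    co <- fit_ellipse_conic(x[sel], y[sel])
    conic_to_geom(co)
  }
  go <- fit_one(sel_out, "outer")
  gi <- fit_one(sel_in, "inner")
  # geometric semi-axes are (major, minor); map to (horizontal, vertical)
  # using the fitted angle (expected near 0 or 90)
  to_hv <- function(gg) {
    if (abs(gg$angle_deg) <= 45) {
      c(gg$semiaxes[["major"]], gg$semiaxes[["minor"]])
    } else {
      c(gg$semiaxes[["minor"]], gg$semiaxes[["major"]])
    }
  }
  center_mm <- (go$center + gi$center) / 2
  center_px <- c(prior$center_px[1] + center_mm[["y"]] / geometry$pitch_mm[1],
                 prior$center_px[2] + center_mm[["x"]] / geometry$pitch_mm[2])
  rot <- if (abs(go$angle_deg) <= 45) go$angle_deg else go$angle_deg - sign(go$angle_deg) * 90
  out <- annulus_spec(center_px,
                      outer_semiaxes_mm = to_hv(go),
                      inner_semiaxes_mm = to_hv(gi),
                      rotation_deg = rot)
  attr(out, "fit") <- list(n_outer = sum(sel_out), n_inner = sum(sel_in),
                           outer = go, inner = gi)
  out
}
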