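# Synthetic eyes, cohorts and rendered deviation-map images.
#
# The simulator provides the statistical structure the downstream analysis
# assumes: per-pixel Gaussian thickness around the normative mean, focal
# glaucomatous thinning shaped like macular RNFL-bundle (arcuate) defects,
# and five-color rendered maps with annulus and sector-line overlay.

#' Specification of one synthetic eye
#'
#' @param group `"NORMAL"`, `"SUSPECT"` or `"GLAUCOMA"`.
#' @param defect_magnitude mean focal loss at the defect core, micrometres
#'   (total across GCL + IPL).  Must be 0 for NORMAL eyes.
#' @param defect_shape `"arcuate_superior"`, `"arcuate_inferior"`,
#'   `"hemifield"` (superior) or `"diffuse"`.
#' @param noise_sd_scale multiplier on the normative SD for the Gaussian
#'   thickness noise.
#' @param noise_correlation share of noise variance common to all pixels of
#'   the eye (between-eye component); `0` gives i.i.d. pixel noise.  The
#'   per-pixel marginal SD is unchanged by this parameter.
#' @param laterality `"OD"` or `"OS"`; OS eyes are generated in OD
#'   orientation and mirrored left-right.
#' @param seed RNG seed for this eye.
#' @return object of class `eye_spec`.
#' @export
eye_spec <- function(group = "NORMAL", defect_magnitude = 0,
                     defect_shape = "arcuate_superior",
                     noise_sd_scale = 1, noise_correlation = 0.5,
                     laterality = "OD", seed = 1L) {
  group <- match.arg(group, c("NORMAL", "SUSPECT", "GLAUCOMA"))
  defect_shape <- match.arg(defect_shape, c("arcuate_superior",
                                            "arcuate_inferior",
                                            "hemifield", "diffuse"))
  laterality <- match.arg(laterality, c("OD", "OS"))
  stopifnot(defect_magnitude >= 0, noise_sd_scale > 0,
            noise_correlation >= 0, noise_correlation < 1)
  if (group == "NORMAL" && defect_magnitude != 0) {
    stop("NORMAL eyes must have defect_magnitude = 0")
  }
  structure(list(group = group, defect_magnitude = defect_magnitude,
                 defect_shape = defect_shape, noise_sd_scale = noise_sd_scale,
                 noise_correlation = noise_correlation,
                 laterality = laterality, seed = as.integer(seed)),
            class = "eye_spec")
}

#' Glaucomatous defect field on a raster
#'
#' Smooth non-negative loss field with maximum exactly `magnitude`.
#' Arcuate shapes follow an anisotropic Gaussian bump along a circular arc
#' at fixed eccentricity in one hemifield, mimicking the course of macular
#' RNFL bundles; `hemifield` is a smooth superior-hemifield step; `diffuse`
#' is spatially uniform.
#'
#' @param geometry a [raster_geometry()].
#' @param shape defect shape (see [eye_spec()]).
#' @param magnitude peak loss, micrometres.
#' @param ecc_mm eccentricity of the arcuate crest, mm.
#' @param radial_sd_mm radial Gaussian width of the arc, mm.
#' @param angular_halfwidth_deg angular half-extent of the arc, degrees.
#' @return matrix of loss values in `[0, magnitude]`.
#' @export
defect_field <- function(geometry, shape, magnitude,
                         ecc_mm = 2, radial_sd_mm = 0.8,
                         angular_halfwidth_deg = 60) {
  stopifnot(is_raster_geometry(geometry), magnitude >= 0)
  if (magnitude == 0) return(matrix(0, geometry$rows, geometry$cols))
  cc <- pixel_coords_mm(geometry)
  if (shape == "diffuse") {
    return(matrix(magnitude, geometry$rows, geometry$cols))
  }
  if (shape == "hemifield") {
    # smooth step: full loss superior (y < 0), none inferior, 0.4 mm ramp
    f <- stats::pnorm(-cc$y / 0.4)
    return(magnitude * f / max(f))
  }
  # arcuate: Gaussian in radius around ecc_mm, Gaussian in angle around the
  # hemifield's vertical meridian (superior = up = negative y)
  ang0 <- if (shape == "arcuate_superior") 90 else -90
  theta <- atan2(-cc$y, cc$x) * 180 / pi        # degrees, superior positive
  dth <- (theta - ang0 + 180) %% 360 - 180
  f <- exp(-(cc$r - ecc_mm)^2 / (2 * radial_sd_mm^2)) *
    exp(-dth^2 / (2 * (angular_halfwidth_deg / 2)^2))
  magnitude * f / max(f)
}

#' Simulate one eye's GCL and IPL thickness rasters
#'
#' Thickness is the normative mean minus a smooth defect field plus Gaussian
#' noise with per-pixel SD `noise_sd_scale * normative SD`, clipped at 0.
#' The noise of each layer splits into a between-eye common component (one
#' standard-normal draw per eye per layer, weight `sqrt(noise_correlation)`)
#' and an i.i.d. pixel component, leaving the per-pixel marginal exactly
#' `N(mean - defect, (scale * SD)^2)`.  The common components of GCL and IPL
#' share the inter-layer correlation `rho`.  The total defect is split
#' between GCL and IPL in proportion `gcl_fraction`.  OS eyes are mirrored
#' left-right after generation.
#'
#' @param model_gcl,model_ipl normative models sharing one geometry.
#' @param spec an [eye_spec()].
#' @param rho inter-layer correlation of the between-eye components.
#' @param gcl_fraction share of the defect magnitude assigned to the GCL.
#' @param ... passed to [defect_field()].
#' @return list with matrices `gcl` and `ipl` (micrometres) and the applied
#'   `defect` field (total, OD orientation pre-mirroring).
#' @export
simulate_eye <- function(model_gcl, model_ipl, spec, rho = 0.5,
                         gcl_fraction = 0.6, ...) {
  stopifnot(inherits(model_gcl, "normative_model"),
            inherits(model_ipl, "normative_model"),
            inherits(spec, "eye_spec"))
  if (!same_geometry(model_gcl$geometry, model_ipl$geometry)) {
    stop("GCL and IPL models must share raster geometry")
  }
  g <- model_gcl$geometry
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(spec$seed)
  defect <- defect_field(g, spec$defect_shape, spec$defect_magnitude, ...)
  phi <- spec$noise_correlation
  # GCL and IPL noise carry inter-layer correlation rho at both scales
  # (between-eye common component and per-pixel component), so the summed
  # GCIPL thickness matches the composed GCIPL model's SD exactly.
  zc <- rnorm(2)
  z_gcl_common <- zc[1]
  z_ipl_common <- rho * zc[1] + sqrt(1 - rho^2) * zc[2]
  n <- g$rows * g$cols
  zp_gcl <- matrix(rnorm(n), g$rows, g$cols)
  zp_ipl <- rho * zp_gcl + sqrt(1 - rho^2) * matrix(rnorm(n), g$rows, g$cols)
  noise_one <- function(model, z_common, z_pixel) {
    z <- sqrt(phi) * z_common + sqrt(1 - phi) * z_pixel
    spec$noise_sd_scale * model$sd * z
  }
  gcl <- pmax(model_gcl$mean - gcl_fraction * defect +
                noise_one(model_gcl, z_gcl_common, zp_gcl), 0)
  ipl <- pmax(model_ipl$mean - (1 - gcl_fraction) * defect +
                noise_one(model_ipl, z_ipl_common, zp_ipl), 0)
  if (spec$laterality == "OS") {
    gcl <- mirror_lr(gcl); ipl <- mirror_lr(ipl)
  }
  list(gcl = gcl, ipl = ipl, defect = defect)
}

#' Simulate a cohort of synthetic eyes
#'
#' Draws per-eye defect magnitudes from group-specific distributions and
#' generates thickness rasters plus 8 x 8 superpixel grids for every eye.
#' GLAUCOMA magnitudes are lognormal with configurable median (micrometres)
#' and log-SD; SUSPECT magnitudes mix zeros (probability `suspect_zero_prob`)
#' with a lognormal at half the glaucoma median; NORMAL eyes have no defect.
#' Defect shapes are sampled uniformly from the arcuate and hemifield shapes;
#' laterality is sampled 50/50.  Fully reproducible given `seed`.
#'
#' @param model_gcl,model_ipl normative models sharing one geometry.
#' @param n_per_group named counts, e.g.
#'   `c(NORMAL = 50, SUSPECT = 0, GLAUCOMA = 50)`.
#' @param defect_median_um median glaucomatous peak defect, micrometres.
#' @param defect_log_sd SD of log defect magnitude.
#' @param suspect_zero_prob probability a SUSPECT eye has no structural
#'   defect.
#' @param noise_sd_scale,noise_correlation,rho,gcl_fraction
#'   passed to [simulate_eye()].
#' @param seed cohort RNG seed.
#' @return object of class `cohort`: list with `manifest` (data.frame of the
#'   spec actually used per eye: eye_id, group, laterality, seed,
#'   defect_magnitude, defect_shape) and `eyes` (named list; per eye the
#'   rasters `gcl`, `ipl` and [thickness_grid()]s `grid_gcl`, `grid_ipl`).
#' @export
simulate_cohort <- function(model_gcl, model_ipl,
                            n_per_group = c(NORMAL = 50, SUSPECT = 0, GLAUCOMA = 50),
                            defect_median_um = 15, defect_log_sd = 0.6,
                            suspect_zero_prob = 0.5,
                            noise_sd_scale = 1, noise_correlation = 0.5,
                            rho = 0.5, gcl_fraction = 0.6, seed = 1L) {
  groups <- c("NORMAL", "SUSPECT", "GLAUCOMA")
  n_per_group <- n_per_group[groups]
  n_per_group[is.na(n_per_group)] <- 0L
  names(n_per_group) <- groups
  stopifnot(all(n_per_group >= 0), defect_median_um >= 0, defect_log_sd >= 0)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  shapes <- c("arcuate_superior", "arcuate_inferior", "hemifield")
  rows <- list(); specs <- list()
  k <- 0L
  for (grp in groups) {
    ng <- n_per_group[[grp]]
    if (ng == 0L) next
    for (i in seq_len(ng)) {
      k <- k + 1L
      mag <- switch(grp,
        NORMAL = 0,
        SUSPECT = if (runif(1) < suspect_zero_prob) 0 else
          stats::rlnorm(1, log(pmax(defect_median_um / 2, 1e-12)), defect_log_sd),
        GLAUCOMA = if (defect_median_um == 0) 0 else
          stats::rlnorm(1, log(defect_median_um), defect_log_sd))
      shape <- sample(shapes, 1L)
      lat <- sample(c("OD", "OS"), 1L)
      eseed <- sample.int(.Machine$integer.max, 1L)
      id <- sprintf("%s_%03d_%s", tolower(grp), i, lat)
      specs[[id]] <- eye_spec(group = grp, defect_magnitude = mag,
                              defect_shape = shape,
                              noise_sd_scale = noise_sd_scale,
                              noise_correlation = noise_correlation,
                              laterality = lat, seed = eseed)
      rows[[id]] <- data.frame(eye_id = id, group = grp, laterality = lat,
                               seed = eseed, defect_magnitude = mag,
                               defect_shape = shape,
                               stringsAsFactors = FALSE)
    }
  }
  manifest <- if (length(rows)) do.call(rbind, rows) else
    data.frame(eye_id = character(), group = character(),
               laterality = character(), seed = integer(),
               defect_magnitude = numeric(), defect_shape = character())
  rownames(manifest) <- NULL
  eyes <- lapply(specs, function(sp) {
    e <- simulate_eye(model_gcl, model_ipl, sp, rho = rho,
                      gcl_fraction = gcl_fraction)
    e$grid_gcl <- raster_to_grid(e$gcl, model_gcl$geometry, layer = "GCL")
    e$grid_ipl <- raster_to_grid(e$ipl, model_ipl$geometry, layer = "IPL")
    e
  })
  structure(list(manifest = manifest, eyes = eyes,
                 params = list(n_per_group = n_per_group,
                               defect_median_um = defect_median_um,
                               defect_log_sd = defect_log_sd,
                               noise_sd_scale = noise_sd_scale,
                               noise_correlation = noise_correlation,
                               rho = rho, gcl_fraction = gcl_fraction,
                               seed = seed)),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat("cohort:", nrow(x$manifest), "eyes (",
      paste(sprintf("%s=%d", names(table(x$manifest$group)),
                    as.integer(table(x$manifest$group))), collapse = ", "),
      ")\n")
  invisible(x)
}

#' Default five-color deviation-map palette
#'
#' Category colors of the rendered map: red (abnormal, P < 1%), yellow
#' (borderline, P < 5%), green (within normal limits), blue (supernormal,
#' P > 95%), pink (supernormal, P > 99%), grey (excluded/background), and a
#' reserved black overlay color for the annulus boundaries and sector lines.
#'
#' @return list with `colors` (6 x 3 integer matrix of 0-255 RGB rows named
#'   by category) and `overlay` (length-3 RGB for the overlay graphics).
#' @export
default_palette <- function() {
  colors <- rbind(abn1 = c(255L, 0L, 0L),
                  abn5 = c(255L, 255L, 0L),
                  wnl = c(0L, 200L, 0L),
                  sup95 = c(0L, 0L, 255L),
                  sup99 = c(255L, 105L, 180L),
                  excluded = c(128L, 128L, 128L))
  list(colors = colors, overlay = c(0L, 0L, 0L))
}

validate_palette <- function(palette) {
  stopifnot(is.list(palette), is.matrix(palette$colors),
            ncol(palette$colors) == 3L,
            all(rownames(palette$colors) %in% DEV_CATEGORIES))
  allc <- rbind(palette$colors, overlay = palette$overlay)
  d <- as.matrix(stats::dist(allc, method = "maximum"))
  diag(d) <- Inf
  if (min(d) == 0) stop("palette has duplicate colors")
  invisible(palette)
}

#' Sector overlay lines for a rendered map
#'
#' Straight line segments that divide the perifoveal annulus into sectors,
#' as drawn on device deviation-map printouts: `n` radial spokes at equal
#' angles, spanning from the inner to the outer ellipse boundary.
#'
#' @param annulus an [annulus_spec()].
#' @param geometry a [raster_geometry()].
#' @param n number of spokes.
#' @param angles_deg spoke angles (degrees, 0 = nasal direction); default
#'   equally spaced starting at 45 degrees.
#' @return matrix with columns `r0, c0, r1, c1` (pixel endpoints, one row
#'   per segment).
#' @export
sector_lines <- function(annulus, geometry, n = 4, angles_deg = NULL) {
  stopifnot(inherits(annulus, "annulus_spec"))
  if (is.null(angles_deg)) angles_deg <- 45 + (360 / n) * (seq_len(n) - 1)
  t <- angles_deg * pi / 180
  # ellipse radius at angle t for axis-aligned ellipse with semi-axes (a, b)
  erad <- function(a_mm, b_mm) 1 / sqrt((cos(t) / a_mm)^2 + (sin(t) / b_mm)^2)
  r_out <- erad(annulus$outer_semiaxes_mm[1], annulus$outer_semiaxes_mm[2])
  r_in <- erad(annulus$inner_semiaxes_mm[1], annulus$inner_semiaxes_mm[2])
  cbind(r0 = annulus$center_px[1] - (r_in * sin(t)) / geometry$pitch_mm[1],
        c0 = annulus$center_px[2] + (r_in * cos(t)) / geometry$pitch_mm[2],
        r1 = annulus$center_px[1] - (r_out * sin(t)) / geometry$pitch_mm[1],
        c1 = annulus$center_px[2] + (r_out * cos(t)) / geometry$pitch_mm[2])
}

draw_segment_px <- function(seg, rows, cols) {
  # pixels within 0.5 px of the segment, via dense parameter sampling
  len <- max(abs(seg["r1"] - seg["r0"]), abs(seg["c1"] - seg["c0"]))
  tt <- seq(0, 1, length.out = max(2L, ceiling(len * 4) + 1L))
  r <- round(seg["r0"] + tt * (seg["r1"] - seg["r0"]))
  c <- round(seg["c0"] + tt * (seg["c1"] - seg["c0"]))
  keep <- r >= 1 & r <= rows & c >= 1 & c <= cols
  unique(cbind(r = r[keep], c = c[keep]))
}

ellipse_boundary_px <- function(center_px, semiaxes_mm, geometry, n = 720L,
                                rotation_deg = 0) {
  t <- seq(0, 2 * pi, length.out = n + 1L)[-1L]
  a <- semiaxes_mm[1]; b <- semiaxes_mm[2]
  th <- rotation_deg * pi / 180
  x <- a * cos(t) * cos(th) - b * sin(t) * sin(th)
  y <- a * cos(t) * sin(th) + b * sin(t) * cos(th)
  r <- round(center_px[1] + y / geometry$pitch_mm[1])
  c <- round(center_px[2] + x / geometry$pitch_mm[2])
  keep <- r >= 1 & r <= geometry$rows & c >= 1 & c <= geometry$cols
  unique(cbind(r = r[keep], c = c[keep]))
}

#' Render a deviation map as an RGB image
#'
#' Every pixel receives the palette color of its category; the annulus
#' boundary ellipses and the sector lines are then over-drawn in the
#' reserved overlay color.  Rendering is exact: classifying the image by
#' color recovers the category of every non-overlay pixel.
#'
#' @param map a `deviation_map`.
#' @param palette palette as from [default_palette()].
#' @param annulus optional [annulus_spec()] whose boundaries to draw.
#' @param lines optional segment matrix as from [sector_lines()].
#' @return array `rows x cols x 3` of RGB values in `[0, 1]` with attribute
#'   `"overlay_px"`: logical matrix marking over-drawn pixels.
#' @export
render_deviation_map <- function(map, palette = default_palette(),
                                 annulus = NULL, lines = NULL) {
  stopifnot(inherits(map, "deviation_map"))
  validate_palette(palette)
  g <- map$geometry
  cols255 <- palette$colors[DEV_CATEGORIES[1:6], , drop = FALSE]
  img <- array(0, c(g$rows, g$cols, 3L))
  for (ch in 1:3) {
    img[, , ch] <- matrix(cols255[map$categories, ch], g$rows, g$cols) / 255
  }
  overlay <- matrix(FALSE, g$rows, g$cols)
  paint <- function(px) {
    if (length(px) == 0L || nrow(px) == 0L) return()
    overlay[px] <<- TRUE
  }
  if (!is.null(annulus)) {
    paint(ellipse_boundary_px(annulus$center_px, annulus$outer_semiaxes_mm, g,
                              rotation_deg = annulus$rotation_deg))
    paint(ellipse_boundary_px(annulus$center_px, annulus$inner_semiaxes_mm, g,
                              rotation_deg = annulus$rotation_deg))
  }
  if (!is.null(lines)) {
    for (i in seq_len(nrow(lines))) paint(draw_segment_px(lines[i, ], g$rows, g$cols))
  }
  for (ch in 1:3) {
    pl <- img[, , ch]
    pl[overlay] <- palette$overlay[ch] / 255
    img[, , ch] <- pl
  }
  attr(img, "overlay_px") <- overlay
  img
}
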