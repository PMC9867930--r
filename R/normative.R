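# Per-pixel Gaussian normative model and five-category deviation classification.

# Deviation categories.  The five thickness categories partition the real
# line at the pixel's Gaussian percentile cutoffs; EXCLUDED marks pixels with
# no thickness information (missing data, overlay graphics, background).
DEV_CATEGORIES <- c("abn1", "abn5", "wnl", "sup95", "sup99", "excluded")

#' Deviation category labels
#'
#' Category codes used throughout the package, in order from thinnest to
#' thickest plus the exclusion label:
#' `abn1` (abnormal, below the 1st percentile; red), `abn5` (borderline
#' abnormal, 1st to 5th percentile; yellow), `wnl` (within normal limits,
#' 5th to 95th; green), `sup95` (supernormal, 95th to 99th; blue), `sup99`
#' (supernormal, above the 99th; pink), and `excluded` (no thickness
#' information: missing pixels, overlay graphics, background).
#'
#' @return character vector of the six category codes.
#' @export
deviation_categories <- function() DEV_CATEGORIES

z_q01 <- stats::qnorm(0.01)   # -2.3263
z_q05 <- stats::qnorm(0.05)   # -1.6449
z_q95 <- stats::qnorm(0.95)
z_q99 <- stats::qnorm(0.99)

eval_surface <- function(spec, geometry) {
  cc <- pixel_coords_mm(geometry)
  if (is.numeric(spec) && length(spec) == 1L) {
    return(matrix(spec, geometry$rows, geometry$cols))
  }
  if (is.matrix(spec)) {
    stopifnot(nrow(spec) == geometry$rows, ncol(spec) == geometry$cols)
    return(spec)
  }
  if (is.function(spec)) {
    # spec(x_mm, y_mm) evaluated elementwise on pixel centers
    out <- spec(cc$x, cc$y)
    stopifnot(is.matrix(out), dim(out) == c(geometry$rows, geometry$cols))
    return(out)
  }
  if (is.list(spec) && identical(spec$kind, "ridge")) {
    # radially symmetric perifoveal ridge with a foveal pit:
    # m(r) = floor + (peak - floor) * exp(-(r - r0)^2 / (2 w^2))
    return(spec$floor + (spec$peak - spec$floor) *
             exp(-(cc$r - spec$peak_ecc_mm)^2 / (2 * spec$width_mm^2)))
  }
  if (is.list(spec) && identical(spec$kind, "cv")) {
    # SD proportional to a mean surface with an absolute floor
    stopifnot(is.matrix(spec$mean))
    return(pmax(spec$cv * spec$mean, spec$floor))
  }
  stop("unrecognised surface spec")
}

#' Ridge-shaped mean thickness surface specification
#'
#' Parametric description of a ganglion-cell-layer-like thickness profile:
#' a radially symmetric perifoveal ridge peaking at `peak_ecc_mm` from the
#' fovea, decaying to `floor` both at the fovea (the foveal pit, where the
#' GCL is nearly absent) and in the periphery.
#'
#' @param peak peak thickness, micrometres.
#' @param floor asymptotic thickness far from the ridge, micrometres.
#' @param peak_ecc_mm eccentricity of the ridge crest, mm.
#' @param width_mm Gaussian width of the ridge, mm.
#' @return a surface spec understood by [build_normative()].
#' @export
ridge_spec <- function(peak, floor = 8, peak_ecc_mm = 2, width_mm = 0.9) {
  stopifnot(peak > floor, floor >= 0, peak_ecc_mm > 0, width_mm > 0)
  list(kind = "ridge", peak = peak, floor = floor,
       peak_ecc_mm = peak_ecc_mm, width_mm = width_mm)
}

#' Build a per-pixel Gaussian normative thickness model
#'
#' Represents a normative database for one retinal layer as per-pixel mean
#' and SD thickness surfaces.  A pixel's percentile cutoffs are Gaussian:
#' `q_p = mean + qnorm(p) * SD`, so the 1%/5%/95%/99% cutoffs sit at
#' `mean - 2.3263 SD`, `mean - 1.6449 SD`, `mean + 1.6449 SD`,
#' `mean + 2.3263 SD`.
#'
#' Surface specs may be a scalar (constant surface), a full matrix, a
#' function `f(x_mm, y_mm)` of pixel-center coordinates relative to the
#' fovea, or a [ridge_spec()].  SD specs may additionally be
#' `list(kind = "cv", cv =, floor =, mean =)` (proportional to the mean with
#' an absolute floor).
#'
#' @param mean_spec mean surface spec (micrometres).
#' @param sd_spec SD surface spec (micrometres); must evaluate strictly
#'   positive everywhere.
#' @param geometry a [raster_geometry()].
#' @param layer one of `"GCL"`, `"IPL"`, `"GCIPL"`.
#' @return object of class `normative_model`: list with `layer`, `mean`
#'   and `sd` surfaces, and `geometry`.
#' @examples
#' g <- raster_geometry(64, 64)
#' m <- build_normative(30, 3, g, layer = "GCL")
#' range(m$mean)
#' @export
build_normative <- function(mean_spec, sd_spec, geometry, layer = "GCL") {
  stopifnot(is_raster_geometry(geometry))
  layer <- match.arg(layer, c("GCL", "IPL", "GCIPL"))
  mean_surface <- eval_surface(mean_spec, geometry)
  sd_surface <- eval_surface(sd_spec, geometry)
  if (any(!is.finite(mean_surface)) || any(mean_surface < 0)) {
    stop("mean surface must be finite and non-negative")
  }
  bad <- which(sd_surface <= 0 | !is.finite(sd_surface), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop("SD surface must be strictly positive; offending region starts at pixel (",
         bad[1, 1], ", ", bad[1, 2], ") of ", nrow(bad), " bad pixels")
  }
  structure(list(layer = layer, mean = mean_surface, sd = sd_surface,
                 geometry = geometry),
            class = "normative_model")
}

#' @export
print.normative_model <- function(x, ...) {
  cat(sprintf("normative_model (%s): %d x %d px, mean %.1f-%.1f um, SD %.2f-%.2f um\n",
              x$layer, x$geometry$rows, x$geometry$cols,
              min(x$mean), max(x$mean), min(x$sd), max(x$sd)))
  invisible(x)
}

#' Compose GCL and IPL normative models into a GCIPL model
#'
#' GCIPL thickness is the sum of GCL and IPL thickness, so the GCIPL mean
#' surface is the elementwise sum of the layer means.  The layers are
#' anatomically correlated; the composed SD follows
#' `SD = sqrt(SD_gcl^2 + SD_ipl^2 + 2 rho SD_gcl SD_ipl)` with inter-layer
#' correlation `rho` (default 0.5).
#'
#' @param model_gcl,model_ipl normative models for the GCL and IPL layers
#'   on identical geometry.
#' @param rho inter-layer thickness correlation in `[-1, 1]`.
#' @return a `normative_model` with `layer = "GCIPL"`.
#' @export
compose_gcipl <- function(model_gcl, model_ipl, rho = 0.5) {
  stopifnot(inherits(model_gcl, "normative_model"),
            inherits(model_ipl, "normative_model"),
            model_gcl$layer == "GCL", model_ipl$layer == "IPL",
            rho >= -1, rho <= 1)
  if (!same_geometry(model_gcl$geometry, model_ipl$geometry)) {
    stop("GCL and IPL models must share raster geometry")
  }
  sd <- sqrt(model_gcl$sd^2 + model_ipl$sd^2 +
               2 * rho * model_gcl$sd * model_ipl$sd)
  build_normative(model_gcl$mean + model_ipl$mean, sd,
                  model_gcl$geometry, layer = "GCIPL")
}

#' Classify a thickness raster against a normative model
#'
#' Each pixel is compared with the per-pixel Gaussian normative distribution
#' and assigned one of the five deviation categories.  With
#' `z = (thickness - mean) / SD`:
#' below the 1st percentile -> `abn1` (red); at or above the 1st but below
#' the 5th -> `abn5` (yellow); within the 5th-95th percentile interval
#' (inclusive) -> `wnl` (green); above the 95th up to and including the
#' 99th -> `sup95` (blue); above the 99th -> `sup99` (pink).  Boundary
#' values are within normal limits at q05/q95 and fall to the milder flag at
#' q01/q99 (flagging uses strict inequalities).  Negative thickness is the
#' missing-data sentinel and maps to `excluded`.
#'
#' @param model a [build_normative()] model.
#' @param thickness raster matrix of thickness (micrometres), same shape as
#'   the model.
#' @return object of class `deviation_map`: list with `categories` (integer
#'   matrix indexing [deviation_categories()]), `geometry`, `layer`.
#' @examples
#' g <- raster_geometry(4, 4)
#' m <- build_normative(30, 3, g)
#' dm <- classify_thickness(m, matrix(30 - 3 * 3, 4, 4))
#' table(category_labels(dm))
#' @export
classify_thickness <- function(model, thickness) {
  stopifnot(inherits(model, "normative_model"), is.matrix(thickness))
  if (!all(dim(thickness) == c(model$geometry$rows, model$geometry$cols))) {
    stop("thickness raster shape (", nrow(thickness), " x ", ncol(thickness),
         ") does not match the model raster (", model$geometry$rows, " x ",
         model$geometry$cols, ")")
  }
  # compare against the cutoff thickness surfaces directly so values lying
  # exactly on a percentile cutoff classify per the boundary convention
  q01 <- model$mean + z_q01 * model$sd
  q05 <- model$mean + z_q05 * model$sd
  q95 <- model$mean + z_q95 * model$sd
  q99 <- model$mean + z_q99 * model$sd
  cat_idx <- matrix(3L, nrow(thickness), ncol(thickness))  # wnl
  cat_idx[thickness < q05] <- 2L                   # abn5 ([q01, q05))
  cat_idx[thickness < q01] <- 1L                   # abn1 ((-Inf, q01))
  cat_idx[thickness > q95] <- 4L                   # sup95 ((q95, q99])
  cat_idx[thickness > q99] <- 5L                   # sup99 ((q99, Inf))
  cat_idx[is.na(thickness) | thickness < 0] <- 6L  # excluded (missing)
  deviation_map(cat_idx, model$geometry, layer = model$layer)
}

#' Construct a deviation map object
#'
#' @param categories integer matrix with values 1..6 indexing
#'   [deviation_categories()], or a character matrix of category codes.
#' @param geometry a [raster_geometry()].
#' @param layer layer label.
#' @return object of class `deviation_map`.
#' @export
deviation_map <- function(categories, geometry, layer = "GCL") {
  stopifnot(is_raster_geometry(geometry))
  if (is.character(categories)) {
    idx <- match(categories, DEV_CATEGORIES)
    if (anyNA(idx)) stop("unknown category code in matrix")
    categories <- matrix(idx, nrow(categories), ncol(categories))
  }
  stopifnot(is.matrix(categories),
            nrow(categories) == geometry$rows, ncol(categories) == geometry$cols,
            all(categories %in% 1:6))
  storage.mode(categories) <- "integer"
  structure(list(categories = categories, geometry = geometry, layer = layer),
            class = "deviation_map")
}

#' @export
print.deviation_map <- function(x, ...) {
  tab <- tabulate(x$categories, 6L)
  cat(sprintf("deviation_map (%s): %d x %d px\n", x$layer,
              x$geometry$rows, x$geometry$cols))
  cat(paste(sprintf("  %s: %d", DEV_CATEGORIES, tab), collapse = "\n"), "\n")
  invisible(x)
}

#' Category labels of a deviation map as a character matrix
#'
#' @param map a `deviation_map`.
#' @return character matrix of category codes.
#' @export
category_labels <- function(map) {
  stopifnot(inherits(map, "deviation_map"))
  matrix(DEV_CATEGORIES[map$categories],
         nrow(map$categories), ncol(map$categories))
}
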