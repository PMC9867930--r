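# Quantification of deviation maps: color parsing of rendered images and
# pixel-extent summaries over the entire scan or the perifoveal annulus.

#' Parse a rendered deviation-map image back to pixel categories
#'
#' Each pixel is assigned the category of the nearest palette color, using
#' the per-channel (Chebyshev) distance on the 0-255 scale; pixels farther
#' than `tolerance` from every palette color (overlay graphics, background,
#' annotations) become `excluded`.  The palette must be unambiguous: all
#' pairwise color distances must exceed `2 * tolerance`.
#'
#' @param image RGB array `rows x cols x 3`, values in `[0, 1]` (as read by
#'   [png::readPNG()]) or 0-255.
#' @param geometry a [raster_geometry()] for the resulting map.
#' @param palette palette as from [default_palette()]; its `overlay` color
#'   is never matched.
#' @param tolerance maximum per-channel distance for a match.
#' @param layer layer label for the map.
#' @return a `deviation_map`.
#' @export
parse_colors <- function(image, geometry, palette = default_palette(),
                         tolerance = 20, layer = "GCL") {
  stopifnot(is.array(image), length(dim(image)) == 3L, dim(image)[3] >= 3L,
            is_raster_geometry(geometry),
            dim(image)[1] == geometry$rows, dim(image)[2] == geometry$cols)
  validate_palette(palette)
  cols <- palette$colors
  d <- as.matrix(stats::dist(rbind(cols, overlay = palette$overlay),
                             method = "maximum"))
  diag(d) <- Inf
  if (min(d) <= 2 * tolerance) {
    stop("ambiguous palette: minimum pairwise color distance ", min(d),
         " must exceed 2 * tolerance = ", 2 * tolerance)
  }
  img255 <- image[, , 1:3, drop = FALSE]
  if (max(img255) <= 1) img255 <- img255 * 255
  npx <- geometry$rows * geometry$cols
  flat <- matrix(img255, npx, 3L)
  best_d <- rep(Inf, npx)
  best_k <- rep(6L, npx)
  for (k in seq_len(nrow(cols))) {
    dk <- pmax(abs(flat[, 1] - cols[k, 1]),
               abs(flat[, 2] - cols[k, 2]),
               abs(flat[, 3] - cols[k, 3]))
    better <- dk < best_d
    best_d[better] <- dk[better]
    best_k[better] <- match(rownames(cols)[k], DEV_CATEGORIES)
  }
  best_k[best_d > tolerance] <- 6L
  deviation_map(matrix(best_k, geometry$rows, geometry$cols),
                geometry, layer = layer)
}

#' Pixel-extent summary of a deviation map
#'
#' Counts the pixels of each flagged category inside a region — the entire
#' rectangular scan or an elliptical annulus — and reports each as a
#' percentage of the region's informative pixels.  With the default
#' `denominator = "exclude"`, `excluded` pixels (overlay graphics, missing
#' data) are removed from the denominator; `"raw"` keeps every region pixel
#' in it.  Categories are reported disjoint by default (`abn5` is the
#' 1-5% band); `cumulative = TRUE` reports `abn5` as everything below the
#' 5th percentile and `sup95` as everything above the 95th.
#'
#' @param map a `deviation_map`.
#' @param region `"entire_scan"` or an [annulus_spec()].
#' @param denominator `"exclude"` (default) or `"raw"`.
#' @param cumulative report cumulative tail extents instead of disjoint
#'   bands.
#' @return object of class `extent_summary`: list with `region`, `pct`
#'   (named `abn1, abn5, wnl, sup95, sup99`), `n_total_px` (denominator),
#'   `n_excluded_px`, `counts`, `denominator`, `cumulative`.
#' @examples
#' g <- raster_geometry(10, 10)
#' m <- build_normative(30, 3, g)
#' dm <- classify_thickness(m, matrix(30, 10, 10))
#' extent_summary(dm)$pct
#' @export
extent_summary <- function(map, region = "entire_scan",
                           denominator = c("exclude", "raw"),
                           cumulative = FALSE) {
  stopifnot(inherits(map, "deviation_map"))
  denominator <- match.arg(denominator)
  if (inherits(region, "annulus_spec")) {
    mask <- annulus_mask(region, map$geometry)
    region_name <- "central_ellipse"
  } else {
    region <- match.arg(region, "entire_scan")
    mask <- matrix(TRUE, map$geometry$rows, map$geometry$cols)
    region_name <- "entire_scan"
  }
  cats <- map$categories[mask]
  counts <- tabulate(cats, 6L)
  names(counts) <- DEV_CATEGORIES
  n_region <- length(cats)
  n_excl <- counts[["excluded"]]
  n_total <- if (denominator == "exclude") n_region - n_excl else n_region
  if (n_total == 0L) {
    stop("extent undefined: region contains no ",
         if (denominator == "exclude") "informative " else "", "pixels")
  }
  pct <- 100 * counts[1:5] / n_total
  if (cumulative) {
    pct[["abn5"]] <- pct[["abn1"]] + pct[["abn5"]]
    pct[["sup95"]] <- pct[["sup95"]] + pct[["sup99"]]
  }
  structure(list(region = region_name, pct = pct,
                 n_total_px = n_total, n_excluded_px = as.integer(n_excl),
                 n_region_px = n_region, counts = counts,
                 denominator = denominator, cumulative = cumulative),
            class = "extent_summary")
}

#' @export
print.extent_summary <- function(x, ...) {
  cat(sprintf("extent_summary (%s, denominator = %s%s): %d px (%d excluded)\n",
              x$region, x$denominator,
              if (x$cumulative) ", cumulative" else "",
              x$n_total_px, x$n_excluded_px))
  cat(paste(sprintf("  %s: %.2f%%", names(x$pct), x$pct), collapse = "\n"), "\n")
  invisible(x)
}
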