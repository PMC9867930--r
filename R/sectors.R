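# 8 x 8 posterior-pole superpixel grids and their aggregation into the
# 5 superior + 5 inferior macular sectors and the global (18 x 18 degree)
# average.

#' An 8 x 8 posterior-pole thickness grid
#'
#' One eye's layer thickness exported as 64 superpixels centered on the
#' fovea, each spanning 3 x 3 degrees of scan angle.  Grids are stored in
#' right-eye (OD) orientation: row 1 is most superior, column 1 most
#' temporal.  Missing superpixels are `NA`.
#'
#' @param values 8 x 8 numeric matrix, micrometres; entries must be
#'   non-negative or `NA`.
#' @param layer `"GCL"`, `"IPL"` or `"GCIPL"`.
#' @return object of class `thickness_grid`.
#' @export
thickness_grid <- function(values, layer = "GCL") {
  stopifnot(is.matrix(values), all(dim(values) == c(8L, 8L)))
  layer <- match.arg(layer, c("GCL", "IPL", "GCIPL"))
  if (any(values < 0, na.rm = TRUE)) {
    stop("grid entries must be non-negative or NA")
  }
  structure(list(values = values, layer = layer), class = "thickness_grid")
}

#' @export
print.thickness_grid <- function(x, ...) {
  cat(sprintf("thickness_grid (%s), um:\n", x$layer))
  print(round(x$values, 1))
  invisible(x)
}

#' Mirror a left-eye grid into right-eye orientation
#'
#' @param grid a [thickness_grid()] acquired on a left eye (OS).
#' @return the grid with columns reversed (OD orientation).
#' @export
mirror_grid <- function(grid) {
  stopifnot(inherits(grid, "thickness_grid"))
  thickness_grid(mirror_lr(grid$values), layer = grid$layer)
}

#' Combine GCL and IPL grids into a GCIPL grid
#'
#' GCIPL thickness is the sum of the GCL and IPL thicknesses; the sum is
#' elementwise, and a superpixel missing in either layer is missing in the
#' result.
#'
#' @param gcl,ipl [thickness_grid()]s with layers `"GCL"` and `"IPL"`.
#' @return a `thickness_grid` with `layer = "GCIPL"`.
#' @export
gcipl_grid <- function(gcl, ipl) {
  stopifnot(inherits(gcl, "thickness_grid"), inherits(ipl, "thickness_grid"))
  if (gcl$layer != "GCL" || ipl$layer != "IPL") {
    stop("gcipl_grid needs a GCL grid and an IPL grid (got ",
         gcl$layer, " + ", ipl$layer, ")")
  }
  thickness_grid(gcl$values + ipl$values, layer = "GCIPL")
}

#' Default 5 + 5 macular sector map
#'
#' Assignment of the central 48 superpixels to 5 superior (S1-S5) and 5
#' inferior (I1-I5) macular sectors; the outermost temporal and nasal
#' columns (16 superpixels) are unused.  The arrangement follows the
#' arcuate course of macular nerve-fiber bundles — sectors sweep from the
#' temporal periphery (S1/I1) toward the nasal and paracentral region
#' (S5/I5) — and is mirror-symmetric about the horizontal midline.  The
#' exact published membership is only available as a figure, so this map is
#' a documented approximation; supply your own via [sector_map()] /
#' [read_sector_map_csv()] to override it.
#'
#' @return object of class `sector_map`.
#' @examples
#' default_sector_map()
#' @export
default_sector_map <- function() {
  sup <- rbind(c("S1", "S1", "S1", "S2", "S2", "S2"),
               c("S1", "S1", "S2", "S2", "S3", "S3"),
               c("S4", "S4", "S3", "S3", "S3", "S5"),
               c("S4", "S4", "S4", "S5", "S5", "S5"))
  m <- matrix("UNUSED", 8, 8)
  m[1:4, 2:7] <- sup
  m[5:8, 2:7] <- sub("S", "I", sup[4:1, ])
  sector_map(m, provenance = "macdev default (approximate 5+5 arcuate sectors)")
}

#' Construct and validate a sector map
#'
#' @param assignment 8 x 8 character matrix with entries `S1`-`S5`,
#'   `I1`-`I5` or `UNUSED`.
#' @param provenance free-text origin of the map.
#' @return object of class `sector_map`.
#' @details Invariants enforced: exactly 48 labeled cells and 16 `UNUSED`;
#'   superior sectors confined to rows 1-4 and inferior to rows 5-8; the
#'   assignment is mirror-symmetric about the horizontal midline
#'   (`Sk` at `(r, c)` iff `Ik` at `(9 - r, c)`).
#' @export
sector_map <- function(assignment, provenance = "user") {
  stopifnot(is.matrix(assignment), all(dim(assignment) == c(8L, 8L)),
            is.character(assignment))
  labels <- c(paste0("S", 1:5), paste0("I", 1:5))
  if (!all(assignment %in% c(labels, "UNUSED"))) {
    stop("sector labels must be S1-S5, I1-I5 or UNUSED")
  }
  if (sum(assignment != "UNUSED") != 48L) {
    stop("exactly 48 superpixels must carry sector labels")
  }
  if (any(grepl("^S", assignment[5:8, ])) || any(grepl("^I", assignment[1:4, ]))) {
    stop("superior sectors must occupy rows 1-4 only, inferior rows 5-8 only")
  }
  flip <- assignment[8:1, , drop = FALSE]
  swap <- matrix(chartr("SI", "IS", flip), 8L, 8L)
  swap[flip == "UNUSED"] <- "UNUSED"
  if (!identical(swap, unname(assignment))) {
    stop("sector map must be mirror-symmetric about the horizontal midline")
  }
  structure(list(assignment = assignment, provenance = provenance),
            class = "sector_map")
}

#' @export
print.sector_map <- function(x, ...) {
  cat("sector_map (", x$provenance, "):\n", sep = "")
  print(x$assignment, quote = FALSE)
  invisible(x)
}

#' Sector mean thicknesses
#'
#' Averages a grid's superpixels within each sector of a sector map.  Each
#' sector mean is the unweighted average of its non-missing member
#' superpixels; a sector whose members are all missing is `NA`.
#'
#' @param grid a [thickness_grid()].
#' @param map a [sector_map()]; default [default_sector_map()].
#' @return named numeric vector `S1..S5, I1..I5` of micrometre means.
#' @examples
#' g <- thickness_grid(matrix(50, 8, 8))
#' sector_means(g)
#' @export
sector_means <- function(grid, map = default_sector_map()) {
  stopifnot(inherits(grid, "thickness_grid"), inherits(map, "sector_map"))
  labels <- c(paste0("S", 1:5), paste0("I", 1:5))
  vapply(labels, function(lb) {
    v <- grid$values[map$assignment == lb]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
}

#' Global macular mean thickness (central 18 x 18 degrees)
#'
#' The unweighted mean of the central 6 x 6 = 36 superpixels.  Each
#' superpixel spans 3 degrees, so the central 6 x 6 block covers the
#' 18 x 18 degree macular region the global average refers to; the full
#' 8 x 8 grid spans 24 degrees.
#'
#' @param grid a [thickness_grid()].
#' @return mean thickness in micrometres, or `NA` if every central
#'   superpixel is missing.
#' @export
global_mean <- function(grid) {
  stopifnot(inherits(grid, "thickness_grid"))
  v <- grid$values[2:7, 2:7]
  if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
}
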