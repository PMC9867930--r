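# Plain-text and image I/O: grid CSVs, sector-map CSVs, palette JSON,
# normative-model serialization, PNG round-trip.

#' Read / write an 8 x 8 grid CSV
#'
#' Grid CSVs are 8 comma-separated numeric rows (micrometres), no header;
#' missing superpixels are empty fields.
#'
#' @param path file path.
#' @param layer layer label for the grid read.
#' @return [read_grid_csv()] returns a [thickness_grid()];
#'   [write_grid_csv()] returns `path` invisibly.
#' @export
read_grid_csv <- function(path, layer = "GCL") {
  m <- as.matrix(utils::read.csv(path, header = FALSE,
                                 colClasses = "numeric", na.strings = c("", "NA")))
  dimnames(m) <- NULL
  if (!all(dim(m) == c(8L, 8L))) {
    stop("grid CSV must be 8 rows x 8 columns, got ",
         nrow(m), " x ", ncol(m))
  }
  thickness_grid(m, layer = layer)
}

#' @rdname read_grid_csv
#' @param grid a [thickness_grid()].
#' @export
write_grid_csv <- function(grid, path) {
  stopifnot(inherits(grid, "thickness_grid"))
  utils::write.table(grid$values, path, sep = ",", na = "",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write a sector map CSV
#'
#' 8 rows of 8 comma-separated labels (`S1`-`S5`, `I1`-`I5`, `UNUSED`).
#'
#' @param path file path.
#' @param provenance provenance string to attach on read.
#' @return a [sector_map()] (read) or `path` invisibly (write).
#' @export
read_sector_map_csv <- function(path, provenance = path) {
  m <- as.matrix(utils::read.csv(path, header = FALSE,
                                 colClasses = "character"))
  dimnames(m) <- NULL
  m[] <- trimws(m)
  sector_map(m, provenance = provenance)
}

#' @rdname read_sector_map_csv
#' @param map a [sector_map()].
#' @export
write_sector_map_csv <- function(map, path) {
  stopifnot(inherits(map, "sector_map"))
  utils::write.table(map$assignment, path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Save / load a normative model
#'
#' The model is stored as two float binaries (mean and SD surfaces,
#' little-endian 32-bit, row-major) plus a JSON sidecar carrying the layer,
#' raster shape and geometry, under a common path stem.
#'
#' @param model a `normative_model`.
#' @param stem path stem; writes `<stem>.mean.bin`, `<stem>.sd.bin`,
#'   `<stem>.json`.
#' @return the stem (save) or a `normative_model` (load).
#' @export
save_normative <- function(model, stem) {
  stopifnot(inherits(model, "normative_model"))
  g <- model$geometry
  hdr <- list(layer = model$layer, rows = g$rows, cols = g$cols,
              pitch_mm = g$pitch_mm, fovea_px = g$fovea_px,
              fov_deg = g$fov_deg, mm_per_degree = g$mm_per_degree,
              dtype = "float32le", order = "row-major")
  jsonlite::write_json(hdr, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA)
  wb <- function(m, p) {
    con <- file(p, "wb"); on.exit(close(con))
    writeBin(as.numeric(t(m)), con, size = 4L, endian = "little")
  }
  wb(model$mean, paste0(stem, ".mean.bin"))
  wb(model$sd, paste0(stem, ".sd.bin"))
  invisible(stem)
}

#' @rdname save_normative
#' @export
load_normative <- function(stem) {
  hdr <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  g <- raster_geometry(hdr$rows, hdr$cols, fov_deg = hdr$fov_deg,
                       mm_per_degree = hdr$mm_per_degree,
                       fovea_px = hdr$fovea_px)
  rb <- function(p) {
    con <- file(p, "rb"); on.exit(close(con))
    v <- readBin(con, "numeric", n = hdr$rows * hdr$cols, size = 4L,
                 endian = "little")
    matrix(v, hdr$rows, hdr$cols, byrow = TRUE)
  }
  build_normative(rb(paste0(stem, ".mean.bin")), rb(paste0(stem, ".sd.bin")),
                  g, layer = hdr$layer)
}

#' Write / read a rendered deviation map as 8-bit RGB PNG
#'
#' @param image RGB array in `[0, 1]` as from [render_deviation_map()].
#' @param path file path.
#' @return `path` invisibly (write); RGB array in `[0, 1]` (read).
#' @export
write_map_png <- function(image, path) {
  stopifnot(is.array(image), length(dim(image)) == 3L)
  png::writePNG(image[, , 1:3, drop = FALSE], path)
  invisible(path)
}

#' @rdname write_map_png
#' @export
read_map_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  img[, , 1:3, drop = FALSE]
}

#' Write / read a palette as JSON
#'
#' @param palette palette as from [default_palette()].
#' @param path file path.
#' @export
write_palette_json <- function(palette, path) {
  validate_palette(palette)
  obj <- list(colors = apply(palette$colors, 1, identity, simplify = FALSE),
              overlay = palette$overlay)
  jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_palette_json
#' @export
read_palette_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  colors <- do.call(rbind, obj$colors)
  storage.mode(colors) <- "integer"
  validate_palette(list(colors = colors, overlay = as.integer(obj$overlay)))
}

# Small stable content hash (polynomial rolling hash over the serialized
# object), for run provenance headers.  Not cryptographic.
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2L))
  h <- 0
  for (b in bytes) h <- (h * 131 + b + 1) %% 2147483647
  sprintf("%08x", h)
}

write_table_csv <- function(df, path, meta = character()) {
  con <- file(path, "w"); on.exit(close(con))
  for (m in meta) writeLines(paste0("# ", m), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}
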