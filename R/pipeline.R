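# End-to-end pipeline: simulate -> classify -> render -> parse -> annulus /
# Hough -> extents -> sectors -> statistics, with reproducible configuration.

#' Pipeline run configuration
#'
#' Collects every knob of an end-to-end run into one serializable list.
#' Any subset of fields may be supplied; the rest take the defaults below.
#' A polynomial hash of the full configuration is stamped on every output
#' file for provenance.
#'
#' @param seed master RNG seed.
#' @param raster_px raster size (square), pixels.
#' @param n_per_group named eye counts per group.
#' @param defect_median_um,defect_log_sd glaucoma defect-magnitude
#'   distribution (lognormal, micrometres).
#' @param noise_sd_scale,noise_correlation,rho,gcl_fraction simulator
#'   parameters, see [simulate_eye()] and [simulate_cohort()].
#' @param gcl_mean,ipl_mean [ridge_spec()]s (or other surface specs) for the
#'   normative means.
#' @param gcl_sd_cv,sd_floor_um normative SD as a fraction of the mean with
#'   an absolute floor.
#' @param annulus_prior function of a [raster_geometry()] returning the
#'   annulus prior; default centers the standard 4.8 x 4.0 / 1.2 x 1.0 mm
#'   annulus on the fovea.
#' @param n_sector_lines spokes drawn on rendered maps.
#' @param hough [hough_params()].
#' @param palette color palette.
#' @param color_tolerance per-channel tolerance for [parse_colors()].
#' @param denominator `"exclude"` or `"raw"` (extent denominators).
#' @param cumulative cumulative extent reporting flag.
#' @param sector_map a [sector_map()].
#' @param render should maps be rendered to PNG and re-parsed (the full
#'   image pathway)?  If `FALSE`, extents are computed from the category
#'   rasters directly.
#' @param out_dir optional output directory; `NULL` keeps everything in
#'   memory.
#' @return a `run_config` list.
#' @export
run_config <- function(seed = 1L, raster_px = 64L,
                       n_per_group = c(NORMAL = 10, SUSPECT = 0, GLAUCOMA = 10),
                       defect_median_um = 15, defect_log_sd = 0.6,
                       noise_sd_scale = 1, noise_correlation = 0.5,
                       rho = 0.5, gcl_fraction = 0.6,
                       gcl_mean = ridge_spec(peak = 52, floor = 10,
                                             peak_ecc_mm = 2, width_mm = 0.9),
                       ipl_mean = ridge_spec(peak = 42, floor = 18,
                                             peak_ecc_mm = 1.8, width_mm = 1.2),
                       gcl_sd_cv = 0.10, sd_floor_um = 1.5,
                       annulus_prior = NULL, n_sector_lines = 4L,
                       hough = hough_params(), palette = default_palette(),
                       color_tolerance = 20, denominator = "exclude",
                       cumulative = FALSE, sector_map = default_sector_map(),
                       render = TRUE, out_dir = NULL) {
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' Scalar fields of [run_config()] (`seed`, `raster_px`, `n_per_group`,
#' `defect_median_um`, `defect_log_sd`, `noise_sd_scale`,
#' `noise_correlation`, `rho`, `gcl_fraction`, `gcl_sd_cv`, `sd_floor_um`,
#' `n_sector_lines`, `color_tolerance`, `denominator`, `cumulative`,
#' `render`, `out_dir`) may be given in the file; ridge surface specs are
#' nested maps with `peak`, `floor`, `peak_ecc_mm`, `width_mm`; a
#' `sector_map_csv` entry loads the sector map from CSV.  Unspecified
#' fields take the package defaults.
#'
#' @param path YAML file path.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  scalars <- c("seed", "raster_px", "defect_median_um", "defect_log_sd",
               "noise_sd_scale", "noise_correlation", "rho", "gcl_fraction",
               "gcl_sd_cv", "sd_floor_um", "n_sector_lines",
               "color_tolerance", "denominator", "cumulative", "render",
               "out_dir")
  for (nm in intersect(scalars, names(y))) args[[nm]] <- y[[nm]]
  if (!is.null(y$n_per_group)) args$n_per_group <- unlist(y$n_per_group)
  for (nm in c("gcl_mean", "ipl_mean")) {
    if (!is.null(y[[nm]])) args[[nm]] <- do.call(ridge_spec, y[[nm]])
  }
  if (!is.null(y$sector_map_csv)) {
    args$sector_map <- read_sector_map_csv(y$sector_map_csv)
  }
  do.call(run_config, args)
}

#' Build the pipeline's normative models from a configuration
#'
#' @param config a [run_config()].
#' @return list with `geometry`, `gcl`, `ipl`, `gcipl` models.
#' @export
build_models <- function(config) {
  g <- raster_geometry(config$raster_px, config$raster_px)
  sd_of <- function(mean_spec) {
    list(kind = "cv", cv = config$gcl_sd_cv, floor = config$sd_floor_um,
         mean = eval_surface(mean_spec, g))
  }
  gcl <- build_normative(config$gcl_mean, sd_of(config$gcl_mean), g, "GCL")
  ipl <- build_normative(config$ipl_mean, sd_of(config$ipl_mean), g, "IPL")
  list(geometry = g, gcl = gcl, ipl = ipl,
       gcipl = compose_gcipl(gcl, ipl, rho = config$rho))
}

default_annulus_prior <- function(geometry) {
  annulus_spec(geometry$fovea_px)
}

# Per-eye deviation-map extents for one layer, via the configured pathway.
eye_extents <- function(devmap, config, annulus_prior, geometry) {
  if (config$render) {
    lines <- sector_lines(annulus_prior, geometry, n = config$n_sector_lines)
    img <- render_deviation_map(devmap, config$palette,
                                annulus = annulus_prior, lines = lines)
    parsed <- parse_colors(img, geometry, config$palette,
                           tolerance = config$color_tolerance,
                           layer = devmap$layer)
    fitted <- fit_annulus(img, geometry, annulus_prior,
                          palette = config$palette)
    cleaned <- remove_overlay_lines(parsed, config$hough)
  } else {
    fitted <- annulus_prior
    cleaned <- devmap
  }
  list(scan = extent_summary(cleaned, "entire_scan",
                             denominator = config$denominator,
                             cumulative = config$cumulative),
       ellipse = extent_summary(cleaned, fitted,
                                denominator = config$denominator,
                                cumulative = config$cumulative),
       annulus = fitted)
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> classify -> render -> parse -> annulus fit / Hough
#' line removal -> extent quantification -> sector aggregation -> cohort
#' statistics on a synthetic cohort, reproducibly for a given configuration.
#' When `config$out_dir` is set, the cohort manifest, per-eye feature table,
#' summary tables (and rendered PNG maps) are written there, every CSV
#' stamped with the configuration hash and seed.
#'
#' @param config a [run_config()].
#' @return list with `manifest`, `features` (per-eye feature data.frame),
#'   `tables` ([cohort_tables()], `NULL` if a group is too small), `models`,
#'   `config`, `config_hash`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  hash <- config_hash(unclass(config)[setdiff(names(config), "out_dir")])
  models <- build_models(config)
  g <- models$geometry
  annulus_prior <- if (is.null(config$annulus_prior))
    default_annulus_prior(g) else config$annulus_prior(g)

  cohort <- simulate_cohort(models$gcl, models$ipl,
                            n_per_group = config$n_per_group,
                            defect_median_um = config$defect_median_um,
                            defect_log_sd = config$defect_log_sd,
                            noise_sd_scale = config$noise_sd_scale,
                            noise_correlation = config$noise_correlation,
                            rho = config$rho,
                            gcl_fraction = config$gcl_fraction,
                            seed = config$seed)

  out_dir <- config$out_dir
  if (!is.null(out_dir)) {
    dir.create(file.path(out_dir, "maps"), showWarnings = FALSE,
               recursive = TRUE)
  }

  feat_rows <- vector("list", nrow(cohort$manifest))
  for (i in seq_len(nrow(cohort$manifest))) {
    id <- cohort$manifest$eye_id[i]
    eye <- cohort$eyes[[id]]
    res <- try({
      # analysis is performed in OD orientation; OS rasters were mirrored at
      # simulation time, and so were their grids
      grid_gcipl <- gcipl_grid(eye$grid_gcl, eye$grid_ipl)
      dm_gcl <- classify_thickness(models$gcl, eye$gcl)
      dm_gcipl <- classify_thickness(models$gcipl, eye$gcl + eye$ipl)
      ex_gcl <- eye_extents(dm_gcl, config, annulus_prior, g)
      ex_gcipl <- eye_extents(dm_gcipl, config, annulus_prior, g)
      if (!is.null(out_dir) && config$render) {
        lines <- sector_lines(annulus_prior, g, n = config$n_sector_lines)
        write_map_png(render_deviation_map(dm_gcl, config$palette,
                                           annulus_prior, lines),
                      file.path(out_dir, "maps", paste0(id, "_gcl.png")))
      }
      sm_gcl <- sector_means(eye$grid_gcl, config$sector_map)
      sm_gcipl <- sector_means(grid_gcipl, config$sector_map)
      row <- c(list(eye_id = id, group = cohort$manifest$group[i]),
               as.list(stats::setNames(c(global_mean(eye$grid_gcl), sm_gcl),
                                       paste0("gcl_", thickness_measures()))),
               as.list(stats::setNames(c(global_mean(grid_gcipl), sm_gcipl),
                                       paste0("gcipl_", thickness_measures()))))
      for (rg in c("scan", "ellipse")) {
        for (ct in extent_cutoffs()) {
          row[[paste0("gcl_", rg, "_", ct)]] <- ex_gcl[[rg]]$pct[[ct]]
          row[[paste0("gcipl_", rg, "_", ct)]] <- ex_gcipl[[rg]]$pct[[ct]]
        }
        row[[paste0("gcl_", rg, "_n_total_px")]] <- ex_gcl[[rg]]$n_total_px
        row[[paste0("gcl_", rg, "_n_excluded_px")]] <- ex_gcl[[rg]]$n_excluded_px
      }
      as.data.frame(row)
    }, silent = TRUE)
    if (inherits(res, "try-error")) {
      stop("pipeline stage failed for eye ", id, ": ",
           attr(res, "condition")$message)
    }
    feat_rows[[i]] <- res
  }
  features <- if (length(feat_rows)) do.call(rbind, feat_rows) else
    data.frame(eye_id = character(), group = character())

  tables <- NULL
  n_case <- sum(features$group == "GLAUCOMA")
  n_ctrl <- sum(features$group != "GLAUCOMA")
  if (n_case >= 2L && n_ctrl >= 2L) {
    tables <- cohort_tables(features)
  }

  meta <- c(paste0("config_hash: ", hash), paste0("seed: ", config$seed),
            paste0("package: macdev ",
                   as.character(utils::packageVersion("macdev"))))
  if (!is.null(out_dir)) {
    write_table_csv(cohort$manifest, file.path(out_dir, "manifest.csv"), meta)
    write_table_csv(features, file.path(out_dir, "features.csv"), meta)
    if (!is.null(tables)) write_cohort_tables(tables, out_dir, meta)
  }
  list(manifest = cohort$manifest, features = features, tables = tables,
       models = models, config = config, config_hash = hash)
}
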