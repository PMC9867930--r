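# Cohort summary tables: per-measure AUROCs with DeLong layer contrasts and
# group comparisons of deviation-map extents.

thickness_measures <- function() c("global", paste0("S", 1:5), paste0("I", 1:5))
extent_regions <- function() c(scan = "entire_scan", ellipse = "central_ellipse")
extent_cutoffs <- function() c("abn1", "abn5", "sup95", "sup99")

required_feature_columns <- function() {
  c("eye_id", "group",
    paste0("gcl_", thickness_measures()),
    paste0("gcipl_", thickness_measures()),
    as.vector(outer(c("gcl", "gcipl"),
                    as.vector(outer(names(extent_regions()), extent_cutoffs(),
                                    paste, sep = "_")),
                    paste, sep = "_")))
}

#' Cohort summary tables of layer performance
#'
#' Builds the three summary tables of a GCL-versus-GCIPL comparison from a
#' per-eye feature table:
#'
#' * `thickness_auroc` — AUROC of each global/sectoral thickness measure for
#'   discriminating cases from controls, for GCL and GCIPL, with the DeLong
#'   test of each GCL-vs-GCIPL contrast (lower thickness indicates disease).
#' * `extent_groups` — group mean and SD of each deviation-map extent
#'   (abnormal 1% and 5%, supernormal 95% and 99%; entire scan and central
#'   ellipse) per layer, with unpaired Wilcoxon rank-sum group comparisons
#'   and paired signed-rank GCL-vs-GCIPL contrasts within each group.
#' * `extent_auroc` — AUROC of each extent measure with DeLong GCL-vs-GCIPL
#'   contrasts (higher abnormal extent indicates disease; lower supernormal
#'   extent indicates disease).
#'
#' @param features data.frame with one row per eye: `eye_id`, `group`, the
#'   thickness measures `gcl_global`, `gcl_S1`..`gcl_I5` (same for `gcipl_`)
#'   and the extent measures `<layer>_<region>_<cutoff>` with layer in
#'   `gcl, gcipl`, region in `scan, ellipse`, cutoff in
#'   `abn1, abn5, sup95, sup99` (percent).
#' @param case_group group treated as diseased (default `"GLAUCOMA"`).
#' @param control_groups groups pooled as controls.
#' @param sup_orientation orientation for supernormal extents; glaucomatous
#'   thinning depletes supernormal pixels, so the default is
#'   `"lower_value_indicates_disease"`.
#' @param holm apply a Holm adjustment to each table's DeLong/Wilcoxon
#'   p-value column (off by default).
#' @return object of class `cohort_tables`: list of the three data.frames
#'   plus `meta` (group sizes).
#' @export
cohort_tables <- function(features, case_group = "GLAUCOMA",
                          control_groups = c("NORMAL", "SUSPECT"),
                          sup_orientation = "lower_value_indicates_disease",
                          holm = FALSE) {
  stopifnot(is.data.frame(features))
  missing_cols <- setdiff(required_feature_columns(), names(features))
  if (length(missing_cols) > 0L) {
    stop("feature table is missing required columns: ",
         paste(missing_cols, collapse = ", "))
  }
  is_case <- features$group %in% case_group
  is_ctrl <- features$group %in% control_groups
  if (sum(is_case) < 2L || sum(is_ctrl) < 2L) {
    stop("need at least 2 case and 2 control eyes (got ", sum(is_case),
         " / ", sum(is_ctrl), ")")
  }
  sub <- features[is_case | is_ctrl, , drop = FALSE]
  case <- sub$group %in% case_group

  # Table of thickness AUROCs with DeLong layer contrasts
  th <- do.call(rbind, lapply(thickness_measures(), function(ms) {
    gcl <- sub[[paste0("gcl_", ms)]]
    gcipl <- sub[[paste0("gcipl_", ms)]]
    a1 <- auroc(gcl[case], gcl[!case], "lower_value_indicates_disease")
    a2 <- auroc(gcipl[case], gcipl[!case], "lower_value_indicates_disease")
    dl <- delong_test(gcl, gcipl, case, "lower_value_indicates_disease")
    data.frame(measure = ms, auc_gcl = a1$auc, se_gcl = sqrt(a1$variance),
               auc_gcipl = a2$auc, se_gcipl = sqrt(a2$variance),
               delong_z = dl$z, delong_p = dl$p)
  }))

  # Group means of extents with Wilcoxon comparisons
  eg <- list(); ea <- list()
  for (rg in names(extent_regions())) {
    for (ct in extent_cutoffs()) {
      gcl <- sub[[paste0("gcl_", rg, "_", ct)]]
      gcipl <- sub[[paste0("gcipl_", rg, "_", ct)]]
      eg[[paste(rg, ct)]] <- data.frame(
        region = extent_regions()[[rg]], cutoff = ct,
        gcl_case_mean = mean(gcl[case]), gcl_case_sd = stats::sd(gcl[case]),
        gcl_control_mean = mean(gcl[!case]), gcl_control_sd = stats::sd(gcl[!case]),
        gcipl_case_mean = mean(gcipl[case]), gcipl_case_sd = stats::sd(gcipl[case]),
        gcipl_control_mean = mean(gcipl[!case]), gcipl_control_sd = stats::sd(gcipl[!case]),
        p_group_gcl = wilcoxon_group(gcl[case], gcl[!case])$p,
        p_group_gcipl = wilcoxon_group(gcipl[case], gcipl[!case])$p,
        p_layer_case = wilcoxon_group(gcl[case], gcipl[case], paired = TRUE)$p,
        p_layer_control = wilcoxon_group(gcl[!case], gcipl[!case], paired = TRUE)$p)
      orient <- if (ct %in% c("abn1", "abn5"))
        "higher_value_indicates_disease" else sup_orientation
      a1 <- auroc(gcl[case], gcl[!case], orient)
      a2 <- auroc(gcipl[case], gcipl[!case], orient)
      dl <- delong_test(gcl, gcipl, case, orient)
      ea[[paste(rg, ct)]] <- data.frame(
        region = extent_regions()[[rg]], cutoff = ct, orientation = orient,
        auc_gcl = a1$auc, se_gcl = sqrt(a1$variance),
        auc_gcipl = a2$auc, se_gcipl = sqrt(a2$variance),
        delong_z = dl$z, delong_p = dl$p)
    }
  }
  eg <- do.call(rbind, eg); rownames(eg) <- NULL
  ea <- do.call(rbind, ea); rownames(ea) <- NULL
  rownames(th) <- NULL
  if (holm) {
    th$delong_p <- stats::p.adjust(th$delong_p, "holm")
    ea$delong_p <- stats::p.adjust(ea$delong_p, "holm")
    for (cl in grep("^p_", names(eg), value = TRUE)) {
      eg[[cl]] <- stats::p.adjust(eg[[cl]], "holm")
    }
  }
  structure(list(thickness_auroc = th, extent_groups = eg, extent_auroc = ea,
                 meta = list(n_case = sum(case), n_control = sum(!case),
                             case_group = case_group,
                             control_groups = control_groups, holm = holm)),
            class = "cohort_tables")
}

#' @export
print.cohort_tables <- function(x, ...) {
  cat(sprintf("cohort_tables: %d cases vs %d controls\n\nThickness AUROCs:\n",
              x$meta$n_case, x$meta$n_control))
  print(x$thickness_auroc, digits = 3)
  cat("\nExtent group comparison:\n")
  print(x$extent_groups, digits = 3)
  cat("\nExtent AUROCs:\n")
  print(x$extent_auroc, digits = 3)
  invisible(x)
}

#' Write cohort tables to CSV files with a provenance header
#'
#' @param tables a [cohort_tables()] object.
#' @param dir output directory (created if absent).
#' @param meta character vector of provenance lines (e.g. config hash and
#'   seed) written as `#` comments atop each CSV.
#' @return the directory, invisibly.
#' @export
write_cohort_tables <- function(tables, dir, meta = character()) {
  stopifnot(inherits(tables, "cohort_tables"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_table_csv(tables$thickness_auroc,
                  file.path(dir, "table_thickness_auroc.csv"), meta)
  write_table_csv(tables$extent_groups,
                  file.path(dir, "table_extent_groups.csv"), meta)
  write_table_csv(tables$extent_auroc,
                  file.path(dir, "table_extent_auroc.csv"), meta)
  invisible(dir)
}
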