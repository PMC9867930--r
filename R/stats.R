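# Discrimination statistics: Mann-Whitney AUROC with DeLong variance,
# the DeLong paired comparison of two correlated AUROCs, and Wilcoxon
# group tests.

orient_scores <- function(x, orientation) {
  # After orientation, HIGHER oriented score = more disease-like.
  switch(orientation,
         lower_value_indicates_disease = -x,
         higher_value_indicates_disease = x,
         stop("orientation must be 'lower_value_indicates_disease' or 'higher_value_indicates_disease'"))
}

# Placement (structural component) vectors of the Mann-Whitney kernel:
# v10[i] = P-hat(control ranks below case i), v01[j] likewise per control.
delong_placements <- function(case, control) {
  cmp <- outer(case, control, function(a, b) (a > b) + 0.5 * (a == b))
  list(v10 = rowMeans(cmp), v01 = colMeans(cmp), auc = mean(cmp))
}

#' AUROC with DeLong variance
#'
#' Area under the ROC curve via the Mann-Whitney construction: the mean over
#' all case-control pairs of 1 if the case's oriented score exceeds the
#' control's, 0.5 on ties, 0 otherwise.  The variance is DeLong's:
#' `var(V10)/m + var(V01)/n` from the per-case and per-control placement
#' components (`m` cases, `n` controls).
#'
#' @param case_scores,control_scores numeric vectors (no NAs).
#' @param orientation `"lower_value_indicates_disease"` (e.g. thickness) or
#'   `"higher_value_indicates_disease"` (e.g. abnormal extent).
#' @return object of class `auroc`: list with `auc`, `variance`, `n_case`,
#'   `n_control`, `orientation`.
#' @examples
#' auroc(c(1, 3), c(2, 4), "lower_value_indicates_disease")$auc  # 0.75
#' @export
auroc <- function(case_scores, control_scores,
                  orientation = "lower_value_indicates_disease") {
  if (length(case_scores) == 0L || length(control_scores) == 0L) {
    stop("both score groups must be non-empty")
  }
  stopifnot(!anyNA(case_scores), !anyNA(control_scores))
  ca <- orient_scores(case_scores, orientation)
  co <- orient_scores(control_scores, orientation)
  pl <- delong_placements(ca, co)
  m <- length(ca); n <- length(co)
  v10 <- if (m > 1L) stats::var(pl$v10) else 0
  v01 <- if (n > 1L) stats::var(pl$v01) else 0
  structure(list(auc = pl$auc, variance = v10 / m + v01 / n,
                 n_case = m, n_control = n, orientation = orientation),
            class = "auroc")
}

#' @export
print.auroc <- function(x, ...) {
  cat(sprintf("AUROC = %.3f (SE %.3f; %d cases vs %d controls)\n",
              x$auc, sqrt(x$variance), x$n_case, x$n_control))
  invisible(x)
}

#' DeLong test comparing two correlated AUROCs
#'
#' Compares the AUROCs of two measures observed on the same eyes, using the
#' nonparametric method of DeLong: the covariance of the two AUCs is
#' estimated from the shared placement components,
#' `S = S10/m + S01/n` with `S10` the covariance of the per-case placements
#' and `S01` of the per-control placements, and
#' `z = (auc_a - auc_b) / sqrt(var_a + var_b - 2 cov_ab)` is referred to the
#' standard normal (two-sided).
#'
#' @param scores_a,scores_b the two measures, each over the same eyes in
#'   the same order.
#' @param is_case logical vector: `TRUE` for cases (diseased eyes).
#' @param orientation orientation applied to both measures, or a length-2
#'   vector giving each measure its own orientation.
#' @return object of class `delong_comparison`: list with `auc_a`, `auc_b`,
#'   `cov` (2 x 2), `z`, `p`, `degenerate`.
#' @export
delong_test <- function(scores_a, scores_b, is_case,
                        orientation = "lower_value_indicates_disease") {
  stopifnot(length(scores_a) == length(scores_b),
            length(scores_a) == length(is_case), is.logical(is_case),
            !anyNA(scores_a), !anyNA(scores_b), !anyNA(is_case))
  m <- sum(is_case); n <- sum(!is_case)
  if (m < 2L || n < 2L) stop("need at least 2 cases and 2 controls")
  if (length(orientation) == 1L) orientation <- rep(orientation, 2L)
  a <- orient_scores(scores_a, orientation[1])
  b <- orient_scores(scores_b, orientation[2])
  pa <- delong_placements(a[is_case], a[!is_case])
  pb <- delong_placements(b[is_case], b[!is_case])
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  S <- s10 / m + s01 / n
  denom2 <- S[1, 1] + S[2, 2] - 2 * S[1, 2]
  degenerate <- !(denom2 > 0)
  if (degenerate || pa$auc == pb$auc) {
    z <- 0; p <- 1
  } else {
    z <- (pa$auc - pb$auc) / sqrt(denom2)
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(auc_a = pa$auc, auc_b = pb$auc, cov = S, z = z, p = p,
                 n_case = m, n_control = n, degenerate = degenerate),
            class = "delong_comparison")
}

#' @export
print.delong_comparison <- function(x, ...) {
  cat(sprintf("DeLong comparison: AUC_A = %.3f vs AUC_B = %.3f, z = %.3f, p = %.4g%s\n",
              x$auc_a, x$auc_b, x$z, x$p,
              if (x$degenerate) " (degenerate variance)" else ""))
  invisible(x)
}

#' Wilcoxon group comparison
#'
#' Two-sided Wilcoxon test: the rank-sum (Mann-Whitney) form for two
#' independent groups, or the signed-rank form for paired within-eye
#' contrasts (e.g. GCL vs GCIPL on the same eyes).  Uses the exact null
#' distribution when both groups have at most 25 observations and the data
#' are tie-free, and the tie-corrected normal approximation (with continuity
#' correction) otherwise.  All-zero paired differences are degenerate and
#' reported as `p = 1`.
#'
#' @param values1,values2 numeric vectors; equal length when `paired`.
#' @param paired logical.
#' @param exact_max largest per-group size for which the exact distribution
#'   is used (ties permitting).
#' @return list with `statistic`, `p`, `method`, `degenerate`.
#' @export
wilcoxon_group <- function(values1, values2, paired = FALSE, exact_max = 25L) {
  stopifnot(is.numeric(values1), is.numeric(values2),
            !anyNA(values1), !anyNA(values2))
  if (paired) {
    stopifnot(length(values1) == length(values2))
    d <- values1 - values2
    if (all(d == 0)) {
      return(list(statistic = 0, p = 1,
                  method = "Wilcoxon signed rank (degenerate)",
                  degenerate = TRUE))
    }
  }
  ties <- anyDuplicated(c(values1, if (!paired) values2)) > 0 ||
    (paired && anyDuplicated(abs(values1 - values2)[values1 != values2]) > 0)
  use_exact <- max(length(values1), length(values2)) <= exact_max && !ties &&
    !(paired && any(values1 == values2))
  wt <- suppressWarnings(
    stats::wilcox.test(values1, values2, paired = paired,
                       exact = use_exact, correct = TRUE)
  )
  list(statistic = unname(wt$statistic), p = wt$p.value, method = wt$method,
       degenerate = FALSE)
}
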