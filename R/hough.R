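# Straight-line Hough transform: detection and removal of the sector
# overlay lines drawn across the annulus on deviation maps.

#' Hough transform configuration
#'
#' @param theta_res_deg angular accumulator resolution, degrees.
#' @param rho_res_px radial accumulator resolution, pixels.
#' @param peak_frac peak threshold as a fraction of the maximum accumulator
#'   count; peaks below `peak_frac * max` are not reported.
#' @param min_votes absolute minimum votes for a line.
#' @param dilate_px dilation radius around a detected line: pixels within
#'   `0.5 + dilate_px` of the line are treated as lying on it.
#' @param max_lines maximum number of lines to extract.
#' @return list of parameters for [hough_lines()].
#' @export
hough_params <- function(theta_res_deg = 1, rho_res_px = 1,
                         peak_frac = 0.5, min_votes = 10L,
                         dilate_px = 1, max_lines = 16L) {
  stopifnot(theta_res_deg > 0, rho_res_px > 0, peak_frac > 0, peak_frac <= 1,
            dilate_px >= 0, max_lines >= 1)
  list(theta_res_deg = theta_res_deg, rho_res_px = rho_res_px,
       peak_frac = peak_frac, min_votes = as.integer(min_votes),
       dilate_px = dilate_px, max_lines = as.integer(max_lines))
}

#' Detect straight lines in a binary mask
#'
#' Standard (rho, theta) line Hough transform: each mask pixel votes for all
#' lines `rho = c * cos(theta) + r * sin(theta)` through it; accumulator
#' peaks at or above `peak_frac` of the initial maximum (and `min_votes`)
#' are extracted greedily, removing each line's supporting pixels before
#' searching for the next peak.
#'
#' @param mask logical matrix; `TRUE` pixels vote.
#' @param params a [hough_params()].
#' @return matrix with one row per detected line and columns `theta_deg`,
#'   `rho_px`, `votes`; zero rows when no line reaches threshold.
#' @export
hough_lines <- function(mask, params = hough_params()) {
  stopifnot(is.logical(mask), is.matrix(mask))
  empty <- matrix(numeric(0), 0, 3,
                  dimnames = list(NULL, c("theta_deg", "rho_px", "votes")))
  pts <- which(mask, arr.ind = TRUE)
  if (nrow(pts) == 0L) return(empty)
  thetas <- seq(0, 180 - params$theta_res_deg, by = params$theta_res_deg)
  th <- thetas * pi / 180
  # x = column, y = row (pixel units)
  rho <- outer(pts[, 2], cos(th)) + outer(pts[, 1], sin(th))  # n x ntheta
  diag_len <- sqrt(nrow(mask)^2 + ncol(mask)^2)
  rbin <- round(rho / params$rho_res_px)
  off <- ceiling(diag_len / params$rho_res_px) + 1L
  nbin_r <- 2L * off + 1L
  lin <- (col(rbin) - 1L) * nbin_r + (rbin + off + 1L)   # accumulator index
  acc <- tabulate(lin, nbins = nbin_r * length(th))
  threshold <- max(params$min_votes, params$peak_frac * max(acc))
  alive <- rep(TRUE, nrow(pts))
  out <- empty
  for (i in seq_len(params$max_lines)) {
    acc_now <- tabulate(lin[alive, , drop = FALSE], nbins = nbin_r * length(th))
    best <- which.max(acc_now)
    votes <- acc_now[best]
    if (votes < threshold) break
    ti <- (best - 1L) %/% nbin_r + 1L
    ri <- (best - 1L) %% nbin_r + 1L
    rho_val <- (ri - off - 1L) * params$rho_res_px
    # refine rho on the supporting pixels and retire them
    d <- pts[, 2] * cos(th[ti]) + pts[, 1] * sin(th[ti]) - rho_val
    support <- alive & abs(d) <= params$rho_res_px
    rho_ref <- rho_val + mean(d[support])
    out <- rbind(out, c(thetas[ti], rho_ref, votes))
    alive[abs(pts[, 2] * cos(th[ti]) + pts[, 1] * sin(th[ti]) - rho_ref) <=
            (0.5 + params$dilate_px)] <- FALSE
    if (!any(alive)) break
  }
  colnames(out) <- c("theta_deg", "rho_px", "votes")
  out
}

line_band_mask <- function(lines, rows, cols, width_px) {
  m <- matrix(FALSE, rows, cols)
  if (nrow(lines) == 0L) return(m)
  r <- matrix(seq_len(rows), rows, cols)
  c <- matrix(seq_len(cols), rows, cols, byrow = TRUE)
  for (i in seq_len(nrow(lines))) {
    th <- lines[i, "theta_deg"] * pi / 180
    d <- abs(c * cos(th) + r * sin(th) - lines[i, "rho_px"])
    m <- m | d <= width_px
  }
  m
}

# Chebyshev binary dilation by radius d (square structuring element).
dilate_mask <- function(m, d) {
  if (d <= 0) return(m)
  out <- m
  nr <- nrow(m); nc <- ncol(m)
  for (dr in -d:d) {
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    ro <- rs - dr
    for (dc in -d:d) {
      if (dr == 0 && dc == 0) next
      cs <- max(1, 1 + dc):min(nc, nc + dc)
      co <- cs - dc
      out[rs, cs] <- out[rs, cs] | m[ro, co]
    }
  }
  out
}

#' Remove sector overlay lines from a deviation map
#'
#' Detects the straight sector-divider lines with a Hough transform on a
#' pixel mask (by default the map's `excluded` pixels, which is where
#' overlay graphics land after color parsing) and reassigns the pixels that
#' reside on the detected lines — each line's supporting mask pixels,
#' dilated by `dilate_px` — to `excluded`, so the lines drop out of extent
#' denominators.  No pixel farther than the dilation radius from a line
#' pixel is touched; detecting zero lines returns the map unchanged.
#'
#' @param map a `deviation_map`.
#' @param params a [hough_params()].
#' @param mask optional logical matrix of candidate line pixels; default is
#'   the map's `excluded` pixels.
#' @param restrict optional logical matrix; only pixels where `restrict` is
#'   `TRUE` may be reassigned (e.g. an [annulus_mask()], since the sector
#'   lines live inside the annulus).
#' @return the map with line-band pixels reassigned to `excluded`, with
#'   attribute `"lines"` (the [hough_lines()] matrix).
#' @export
remove_overlay_lines <- function(map, params = hough_params(), mask = NULL,
                                 restrict = NULL) {
  stopifnot(inherits(map, "deviation_map"))
  if (is.null(mask)) mask <- map$categories == 6L
  stopifnot(is.logical(mask), all(dim(mask) == dim(map$categories)))
  lines <- hough_lines(mask, params)
  cat_idx <- map$categories
  if (nrow(lines) > 0L) {
    band <- line_band_mask(lines, nrow(cat_idx), ncol(cat_idx),
                           width_px = 0.5 + params$rho_res_px / 2)
    support <- band & mask          # mask pixels residing on detected lines
    footprint <- dilate_mask(support, as.integer(round(params$dilate_px)))
    if (!is.null(restrict)) footprint <- footprint & restrict
    cat_idx[footprint] <- 6L
  }
  out <- deviation_map(cat_idx, map$geometry, layer = map$layer)
  attr(out, "lines") <- lines
  out
}
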