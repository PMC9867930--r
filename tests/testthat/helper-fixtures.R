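# Shared fixtures and independent brute-force oracles.

fixture_models <- local({
  cache <- new.env()
  function(n = 64L) {
    key <- as.character(n)
    if (is.null(cache[[key]])) {
      cache[[key]] <- build_models(run_config(raster_px = n))
    }
    cache[[key]]
  }
})

# Brute-force AUROC by explicit pair counting (oriented scores: higher =
# disease-ward).
bf_auc <- function(case, control) {
  s <- 0
  for (x in case) for (y in control) {
    s <- s + if (x > y) 1 else if (x == y) 0.5 else 0
  }
  s / (length(case) * length(control))
}

# Independent evaluation of the DeLong structural components and z statistic
# via explicit loops (oriented scores).
bf_delong <- function(a, b, is_case) {
  ca <- which(is_case); co <- which(!is_case)
  m <- length(ca); n <- length(co)
  comp <- function(s) {
    v10 <- numeric(m); v01 <- numeric(n)
    for (i in seq_len(m)) {
      acc <- 0
      for (j in seq_len(n)) {
        acc <- acc + (if (s[ca[i]] > s[co[j]]) 1 else if (s[ca[i]] == s[co[j]]) 0.5 else 0)
      }
      v10[i] <- acc / n
    }
    for (j in seq_len(n)) {
      acc <- 0
      for (i in seq_len(m)) {
        acc <- acc + (if (s[ca[i]] > s[co[j]]) 1 else if (s[ca[i]] == s[co[j]]) 0.5 else 0)
      }
      v01[j] <- acc / m
    }
    list(v10 = v10, v01 = v01, auc = mean(v10))
  }
  pa <- comp(a); pb <- comp(b)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  S <- s10 / m + s01 / n
  den <- S[1, 1] + S[2, 2] - 2 * S[1, 2]
  z <- if (den > 0) (pa$auc - pb$auc) / sqrt(den) else 0
  list(auc_a = pa$auc, auc_b = pb$auc, z = z,
       p = if (den > 0) 2 * stats::pnorm(-abs(z)) else 1)
}

# Brute-force sector means by enumerating the assignment matrix.
bf_sector_means <- function(values, assignment) {
  labels <- c(paste0("S", 1:5), paste0("I", 1:5))
  out <- stats::setNames(rep(NA_real_, 10L), labels)
  for (lb in labels) {
    acc <- c()
    for (r in 1:8) for (c in 1:8) {
      if (assignment[r, c] == lb && !is.na(values[r, c])) {
        acc <- c(acc, values[r, c])
      }
    }
    if (length(acc)) out[lb] <- mean(acc)
  }
  out
}

# Rasterize a 1-px line segment through (r0, c0) at angle ang_deg, length
# 2*half_len, clipped to the raster; returns unique pixel coordinates.
draw_test_line <- function(r0, c0, ang_deg, half_len, rows, cols) {
  th <- ang_deg * pi / 180
  tt <- seq(-half_len, half_len, by = 0.25)
  r <- round(r0 + tt * sin(th)); c <- round(c0 + tt * cos(th))
  keep <- r >= 1 & r <= rows & c >= 1 & c <= cols
  unique(cbind(r[keep], c[keep]))
}
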