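test_that("AUROC equals explicit pair counting on worked examples", {
  # cases {1, 3}, controls {2, 4}, lower value indicates disease:
  # pairs (1,2) 1, (1,4) 1, (3,2) 0, (3,4) 1 -> 0.75
  expect_equal(auroc(c(1, 3), c(2, 4), "lower_value_indicates_disease")$auc, 0.75)

  sep <- auroc(c(1, 2), c(5, 6), "lower_value_indicates_disease")
  expect_equal(sep$auc, 1)
  expect_equal(sep$variance, 0)

  tied <- auroc(c(2, 2, 2), c(2, 2), "lower_value_indicates_disease")
  expect_equal(tied$auc, 0.5)

  expect_error(auroc(numeric(0), c(1, 2)), "non-empty")
})

test_that("AUROC matches the brute-force oracle on random tied instances", {
  set.seed(61)
  for (i in 1:100) {
    m <- sample(2:10, 1); n <- sample(2:10, 1)
    case <- sample(1:6, m, replace = TRUE) + sample(c(0, 0.5), m, replace = TRUE)
    control <- sample(1:6, n, replace = TRUE)
    a <- auroc(case, control, "higher_value_indicates_disease")
    expect_identical(a$auc, bf_auc(case, control))
    # complement identity: swapping the roles reflects the AUC around 0.5
    expect_equal(a$auc + auroc(control, case, "higher_value_indicates_disease")$auc, 1)
  }
})

test_that("AUROC is invariant under strictly monotone transforms", {
  set.seed(62)
  case <- rnorm(15, 1); control <- rnorm(20)
  a0 <- auroc(case, control, "higher_value_indicates_disease")$auc
  for (f in list(function(x) 3 * x - 7, exp, function(x) atan(x) + x^3 / 50)) {
    expect_equal(auroc(f(case), f(control), "higher_value_indicates_disease")$auc, a0)
  }
  # orientation flip mirrors the AUC for tie-free data
  expect_equal(auroc(case, control, "lower_value_indicates_disease")$auc, 1 - a0)
})

test_that("DeLong variance matches pROC and bootstrap resampling", {
  skip_if_not_installed("pROC")
  set.seed(63)
  case <- rnorm(50, 0.8); control <- rnorm(50)
  mine <- auroc(case, control, "higher_value_indicates_disease")
  r <- pROC::roc(rep(c(1, 0), each = 50), c(case, control), quiet = TRUE,
                 direction = "<")
  expect_equal(mine$auc, as.numeric(pROC::auc(r)))
  expect_equal(mine$variance, pROC::var(r, method = "delong"))
  boot <- replicate(1000, {
    bf_case <- sample(case, replace = TRUE)
    bf_control <- sample(control, replace = TRUE)
    auroc(bf_case, bf_control, "higher_value_indicates_disease")$auc
  })
  expect_equal(stats::var(boot), mine$variance, tolerance = 0.35)
})

test_that("DeLong comparison agrees with an independent oracle and with pROC", {
  # small fixed paired dataset, 5 cases vs 5 controls, overlapping groups
  a <- c(10.2, 8.7, 12.6, 9.1, 6.5, 11.8, 9.0, 10.9, 13.0, 11.1)
  b <- c(9.8, 11.6, 8.1, 8.8, 7.9, 11.2, 12.9, 8.6, 12.2, 10.4)
  is_case <- rep(c(TRUE, FALSE), each = 5)
  mine <- delong_test(a, b, is_case, "lower_value_indicates_disease")
  oracle <- bf_delong(-a, -b, is_case)
  expect_equal(mine$auc_a, oracle$auc_a)
  expect_equal(mine$auc_b, oracle$auc_b)
  expect_equal(mine$z, oracle$z)
  expect_equal(mine$p, oracle$p)

  skip_if_not_installed("pROC")
  r1 <- pROC::roc(is_case, a, quiet = TRUE, direction = ">")
  r2 <- pROC::roc(is_case, b, quiet = TRUE, direction = ">")
  pr <- pROC::roc.test(r1, r2, method = "delong", paired = TRUE)
  expect_equal(abs(mine$z), abs(as.numeric(pr$statistic)))
  expect_equal(mine$p, pr$p.value)
})

test_that("DeLong self-comparison is exactly null and antisymmetric", {
  set.seed(64)
  x <- rnorm(30); is_case <- rep(c(TRUE, FALSE), 15)
  self <- delong_test(x, x, is_case)
  expect_identical(self$z, 0)
  expect_identical(self$p, 1)
  expect_true(self$degenerate)

  y <- x + rnorm(30, sd = 0.5)
  ab <- delong_test(x, y, is_case, "higher_value_indicates_disease")
  ba <- delong_test(y, x, is_case, "higher_value_indicates_disease")
  expect_equal(ab$z, -ba$z)
  expect_equal(ab$p, ba$p)
})

test_that("Wilcoxon group tests give exact small-sample p-values and flags", {
  same <- wilcoxon_group(c(1, 2, 3), c(1, 2, 3), paired = TRUE)
  expect_true(same$degenerate)
  expect_identical(same$p, 1)

  # 3 vs 3, complete separation: W at its minimum, exact two-sided p = 0.1
  w <- wilcoxon_group(c(1, 2, 3), c(10, 11, 12))
  expect_identical(unname(w$statistic), 0)
  expect_equal(w$p, 0.1)

  # power rises with the shift in a small Monte-Carlo
  set.seed(65)
  rej <- function(shift) {
    mean(replicate(300, {
      wilcoxon_group(rnorm(30, shift), rnorm(30))$p < 0.05
    }))
  }
  expect_gt(rej(1), rej(0))
})
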