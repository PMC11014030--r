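test_that("Bland-Altman degenerates gracefully on perfect agreement", {
  x <- c(1, 2, 3, 4, 5)
  ba <- bland_altman(x, x)
  expect_equal(ba$bias, 0)
  expect_equal(c(ba$loa_lower, ba$loa_upper), c(0, 0))
  expect_equal(ba$pct_within_loa, 100)
  expect_true(ba$degenerate)
  expect_error(bland_altman(1:2, 2:1), ">= 3")
})

test_that("Bland-Altman is calibrated against normal theory", {
  set.seed(123)
  n <- 2e4
  m <- rnorm(n, 50, 5)
  d <- rnorm(n)
  ba <- bland_altman(m + d / 2, m - d / 2, n_mc = 400, seed = 3)
  expect_equal(ba$bias, 0, tolerance = 0.02)
  expect_equal(ba$loa_lower, -1.96, tolerance = 0.03)
  expect_equal(ba$loa_upper, 1.96, tolerance = 0.03)
  expect_gt(ba$pct_within_loa, 94.3)
  expect_lt(ba$pct_within_loa, 95.7)
  expect_gt(ba$normality_p, 0.05)
  expect_identical(ba$bias_test, "t")
  expect_gt(ba$bias_p, 0.01)
  # LoA symmetric about the bias; bias is the exact mean difference
  expect_equal(ba$loa_upper - ba$bias, ba$bias - ba$loa_lower)
  expect_equal(ba$bias, mean(d))
})

test_that("clinical verdicts use the limits as a percent of the grand mean", {
  set.seed(9)
  m <- rnorm(200, 100, 2)
  d <- rnorm(200, 0, 3)          # LoA about +/-6% of the grand mean
  x <- m + d / 2; y <- m - d / 2
  wide <- bland_altman(x, y, clinical_interval_pct = 35, n_mc = 200)
  narrow <- bland_altman(x, y, clinical_interval_pct = 2, n_mc = 200)
  expect_true(wide$passes_clinical)
  expect_false(narrow$passes_clinical)
})

test_that("Lilliefors statistic matches hand computation and nortest", {
  h <- c(0.1, 0.8, 0.5, 0.3, 0.9)
  z <- sort((h - mean(h)) / stats::sd(h))
  p <- stats::pnorm(z); i <- seq_along(h)
  d_hand <- max(i / 5 - p, p - (i - 1) / 5)
  expect_equal(lilliefors(h, n_mc = 10)$statistic, d_hand)
  skip_if_not_installed("nortest")
  set.seed(6)
  s <- rnorm(80)
  expect_equal(lilliefors(s, n_mc = 10)$statistic,
               unname(nortest::lillie.test(s)$statistic))
})

test_that("Lilliefors accepts normal and rejects uniform samples", {
  set.seed(17)
  expect_gt(lilliefors(rnorm(500), n_mc = 2000, seed = 4)$p_value, 0.05)
  expect_lt(lilliefors(runif(500), n_mc = 2000, seed = 4)$p_value, 0.01)
  expect_error(lilliefors(rep(1, 10)), "constant")
  expect_error(lilliefors(rnorm(3)), "n >= 4")
  # seeded: reproducible p-values
  s <- rnorm(60)
  expect_identical(lilliefors(s, 500, seed = 11)$p_value,
                   lilliefors(s, 500, seed = 11)$p_value)
})

test_that("bias test routes by normality and short-circuits on zeros", {
  expect_equal(bias_test(rep(0, 10), 0.5), list(test = "none", p_value = 1))
  expect_equal(bias_test(c(-1, 0, 1), 0.5)$p_value, 1)
  set.seed(8)
  d <- rnorm(50)
  expect_identical(bias_test(d, normality_p = 0.5)$test, "t")
  expect_identical(bias_test(d, normality_p = 0.01)$test, "wilcoxon")
  shifted <- d + 10 * stats::sd(d)
  expect_lt(bias_test(shifted, 0.5)$p_value, 1e-3)
})

test_that("ICC(A,1) agrees with a brute-force ANOVA oracle", {
  # duplicated column: perfect absolute agreement
  M <- cbind(c(1, 3, 5, 9), c(1, 3, 5, 9))
  expect_equal(icc_two_way_mixed(M)$icc, 1)
  # 4x2 hand matrix against explicit sums of squares
  H <- matrix(c(1, 3, 5, 7, 2, 4, 6, 8), 4, 2)
  or <- local({
    n <- 4; k <- 2; g <- mean(H)
    ssr <- k * sum((rowMeans(H) - g)^2)
    ssc <- n * sum((colMeans(H) - g)^2)
    sse <- sum((H - g)^2) - ssr - ssc
    msp <- ssr / (n - 1); msc <- ssc / (k - 1); mse <- sse / ((n - 1) * (k - 1))
    (msp - mse) / (msp + (k - 1) * mse + k / n * (msc - mse))
  })
  expect_equal(icc_two_way_mixed(H)$icc, or, tolerance = 1e-12)
  # random matrices against stats::aov mean squares, to 1e-10
  set.seed(14)
  for (r in 1:20) {
    M <- matrix(rnorm(20, 10, 2), 10, 2)
    df <- data.frame(y = c(M), subj = factor(rep(1:10, 2)),
                     sess = factor(rep(1:2, each = 10)))
    ms <- summary(stats::aov(y ~ subj + sess, df))[[1]][["Mean Sq"]]
    or <- (ms[1] - ms[3]) / (ms[1] + ms[3] + 0.2 * (ms[2] - ms[3]))
    expect_equal(icc_two_way_mixed(M)$icc, or, tolerance = 1e-10)
  }
})

test_that("ICC is shift-invariant, subject-relabel-equivariant and bounded", {
  set.seed(15)
  M <- matrix(rnorm(40, 5, 1.5), 20, 2)
  r1 <- icc_two_way_mixed(M)
  expect_equal(icc_two_way_mixed(M + 100)$icc, r1$icc, tolerance = 1e-9)
  perm <- sample(nrow(M))
  expect_equal(icc_two_way_mixed(M[perm, ])$icc, r1$icc, tolerance = 1e-12)
  expect_true(r1$ci95[1] <= r1$icc && r1$icc <= r1$ci95[2])
  expect_error(icc_two_way_mixed(matrix(1, 5, 2)), "zero total variance")
  expect_error(icc_two_way_mixed(matrix(c(1, NA, 2, 3), 2, 2)), "complete")
})

test_that("ICC recovers the generating variance ratio", {
  est <- vapply(1:40, function(r)
    icc_two_way_mixed(simulate_paired_metrics(200, 2, 0.8, seed = r))$icc, 0)
  expect_equal(mean(est), 0.8, tolerance = 0.05)
})

test_that("ICC labels use strict thresholds", {
  expect_identical(interpret_icc(0.86), "excellent")
  expect_identical(interpret_icc(0.77), "satisfactory")
  expect_identical(interpret_icc(0.70), "poor")
  expect_identical(interpret_icc(0.801), "excellent")
})

test_that("compliance pools counts and reproduces the worked percentages", {
  # 2058 completed out of 4968 expected -> 41.4%
  tab <- data.frame(age = rep(c(30, 60, 80), c(34, 90, 14)),
                    expected_count = 36, completed_count = 0)
  tab$completed_count <- c(rep(15, 34), rep(15, 90), rep(15, 13), 198)
  tab$completed_count <- pmin(tab$completed_count, 36)
  # construct exactly 2058 total instead
  tab$completed_count <- rep(14, 138)
  tab$completed_count[1:126] <- 15
  expect_equal(sum(tab$completed_count), 2058)
  expect_equal(sum(tab$expected_count), 4968)
  res <- compliance_analysis(tab)
  expect_equal(round(res$overall_pct, 1), 41.4)
  # overall equals the expected-count-weighted mean of per-patient rates
  w <- tab$expected_count
  expect_equal(res$overall_pct,
               sum(w * (100 * tab$completed_count / w)) / sum(w))
})

test_that("full compliance yields 100% and a non-significant ANOVA", {
  tab <- data.frame(age = c(20, 30, 50, 60, 80, 85),
                    expected_count = 36, completed_count = 36)
  res <- suppressWarnings(compliance_analysis(tab))
  expect_equal(res$overall_pct, 100)
  expect_false(isTRUE(res$anova_p < 0.05))
})

test_that("a stronger middle band is detected at the Bonferroni threshold", {
  tab <- simulate_compliance(n_per_band = c(50, 50, 50),
                             mean_pct_per_band = c(40, 60, 40),
                             sd_pct = 12, seed = 3)
  res <- compliance_analysis(tab, n_mc = 500)
  expect_lt(res$anova_p, 0.05)
  pw <- res$pairwise
  mid <- pw$group_a == "46-75" | pw$group_b == "46-75"
  expect_true(all(pw$significant[mid]))
  expect_true(all(pw$p_value[mid] < 0.017))
})

test_that("patients with zero expected recordings are excluded with warning", {
  tab <- data.frame(age = c(30, 31, 60, 61, 80, 81),
                    expected_count = c(0, 36, 36, 36, 36, 36),
                    completed_count = c(0, 30, 18, 20, 12, 14))
  expect_warning(res <- compliance_analysis(tab), "zero expected")
  expect_identical(nrow(res$per_patient), 5L)
})
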