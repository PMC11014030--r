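#' Lilliefors normality test with Monte Carlo p-value
#'
#' Kolmogorov-Smirnov statistic against a normal distribution whose mean
#' and standard deviation are estimated from the sample,
#' `D = max(|ECDF - Phi_hat|)`. Because the parameters are estimated, the
#' usual KS null does not apply; the p-value is obtained from a seeded
#' Monte Carlo null of `n_mc` standard-normal samples of the same size,
#' `p = (1 + #(D_null >= D)) / (n_mc + 1)`.
#'
#' @param x Numeric sample, `n >= 4`, non-constant.
#' @param n_mc Number of Monte Carlo replicates (default 10000).
#' @param seed RNG seed for the null draws (default 1).
#' @return List with `statistic`, `p_value`, `n`, `n_mc`.
#' @export
lilliefors <- function(x, n_mc = 10000, seed = 1) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 4L) stop("Lilliefors test needs n >= 4", call. = FALSE)
  if (stats::sd(x) == 0)
    stop("constant sample: normality test undefined", call. = FALSE)
  stat <- lillie_stat(x)
  null <- with_seed(seed, vapply(seq_len(n_mc),
                                 function(i) lillie_stat(stats::rnorm(n)), 0))
  list(statistic = stat, p_value = (1 + sum(null >= stat)) / (n_mc + 1),
       n = n, n_mc = n_mc)
}

lillie_stat <- function(x) {
  n <- length(x)
  z <- sort((x - mean(x)) / stats::sd(x))
  p <- stats::pnorm(z)
  i <- seq_len(n)
  max(i / n - p, p - (i - 1) / n)
}

#' One-sample bias test routed by normality
#'
#' A one-sample t-test when the differences look normal
#' (`normality_p >= alpha`), otherwise a one-sample Wilcoxon signed-rank
#' test against zero. All-zero differences short-circuit to p = 1.
#'
#' @param d Difference sample.
#' @param normality_p p-value of a normality test on `d`.
#' @param alpha Routing threshold (default 0.05).
#' @return List with `test` (`"t"`, `"wilcoxon"` or `"none"`) and `p_value`.
#' @export
bias_test <- function(d, normality_p, alpha = 0.05) {
  if (length(d) < 3L) stop("bias test needs n >= 3", call. = FALSE)
  if (all(d == 0)) return(list(test = "none", p_value = 1))
  if (normality_p >= alpha) {
    list(test = "t", p_value = stats::t.test(d)$p.value)
  } else {
    list(test = "wilcoxon",
         p_value = stats::wilcox.test(d, mu = 0, exact = FALSE)$p.value)
  }
}

#' Bland-Altman agreement analysis with clinical limits
#'
#' Pairwise differences `d = x - y` are summarized by their mean (bias) and
#' the limits of agreement `bias +/- 1.96 sd(d)`, with t-based 95% CIs for
#' the bias and the standard Bland-Altman standard-error formula
#' `sd * sqrt(1/n + z^2 / (2(n-1)))` for each limit. A least-squares trend
#' of `d` on the pairwise mean `(x + y)/2` checks for proportional error,
#' normality of `d` is assessed by the Monte Carlo [lilliefors()] test,
#' and a fixed bias is tested by [bias_test()]. When a clinical interval is
#' supplied, the measurements pass when both limits of agreement, expressed
#' as a percentage of the grand mean, lie within it and at least 90% of the
#' differences fall inside the limits.
#'
#' @param x,y Paired measurements (equal length, `n >= 3` complete pairs).
#' @param clinical_interval_pct Clinical agreement half-width in percent of
#'   the grand mean, or `NULL` to skip the verdict.
#' @param conf_level CI level (default 0.95).
#' @param n_mc Monte Carlo replicates for the normality test (default
#'   1000).
#' @param seed Seed for the normality null (default 1).
#' @return Object of class `scg_blandaltman`.
#' @export
bland_altman <- function(x, y, clinical_interval_pct = NULL,
                         conf_level = 0.95, n_mc = 1000, seed = 1) {
  if (length(x) != length(y)) stop("x and y must be paired", call. = FALSE)
  cc <- stats::complete.cases(x, y)
  x <- x[cc]; y <- y[cc]
  n <- length(x)
  if (n < 3L) stop("Bland-Altman needs >= 3 complete pairs", call. = FALSE)
  d <- x - y
  m <- (x + y) / 2
  bias <- mean(d)
  s <- stats::sd(d)
  z <- stats::qnorm(0.975)
  loa <- bias + c(-1, 1) * z * s
  tq <- stats::qt(1 - (1 - conf_level) / 2, n - 1)
  bias_ci <- bias + c(-1, 1) * tq * s / sqrt(n)
  se_loa <- s * sqrt(1 / n + z^2 / (2 * (n - 1)))
  loa_ci <- list(lower = loa[1L] + c(-1, 1) * tq * se_loa,
                 upper = loa[2L] + c(-1, 1) * tq * se_loa)
  pct_within <- 100 * mean(d >= loa[1L] & d <= loa[2L])
  degenerate <- s == 0
  if (!degenerate) {
    fit <- stats::lm(d ~ m)
    sm <- summary(fit)$coefficients
    trend_slope <- sm[2L, 1L]
    trend_p <- sm[2L, 4L]
  } else trend_slope <- trend_p <- NA_real_
  normality_p <- if (!degenerate)
    lilliefors(d, n_mc = n_mc, seed = seed)$p_value else NA_real_
  bias_t <- bias_test(d, if (is.na(normality_p)) 1 else normality_p)
  nz <- m != 0
  bias_pct <- if (any(nz)) mean(100 * d[nz] / m[nz]) else NA_real_
  grand <- mean(m)
  loa_pct <- if (grand != 0) 100 * loa / grand else c(NA_real_, NA_real_)
  passes <- if (is.null(clinical_interval_pct)) NA else {
    all(is.finite(loa_pct)) && all(abs(loa_pct) <= clinical_interval_pct) &&
      pct_within >= 90
  }
  structure(
    list(n = n, bias = bias, bias_ci95 = bias_ci, sd_d = s,
         loa_lower = loa[1L], loa_upper = loa[2L], loa_ci95s = loa_ci,
         pct_within_loa = pct_within, normality_p = normality_p,
         bias_test = bias_t$test, bias_p = bias_t$p_value,
         trend_slope = trend_slope, trend_p = trend_p,
         bias_pct = bias_pct, loa_pct = loa_pct, grand_mean = grand,
         clinical_interval_pct = clinical_interval_pct,
         passes_clinical = passes, degenerate = degenerate),
    class = "scg_blandaltman")
}

#' @export
print.scg_blandaltman <- function(x, ...) {
  cat(sprintf("<Bland-Altman> n=%d  bias %.4g [%.4g, %.4g]\n", x$n, x$bias,
              x$bias_ci95[1L], x$bias_ci95[2L]))
  cat(sprintf("  LoA [%.4g, %.4g], %.1f%% of differences within\n",
              x$loa_lower, x$loa_upper, x$pct_within_loa))
  cat(sprintf("  normality p %.3g; bias test (%s) p %.3g; trend p %.3g\n",
              x$normality_p, x$bias_test, x$bias_p, x$trend_p))
  if (!is.null(x$clinical_interval_pct))
    cat(sprintf("  clinical interval +/-%g%%: %s\n", x$clinical_interval_pct,
                if (isTRUE(x$passes_clinical)) "PASS" else "FAIL"))
  invisible(x)
}

#' Bland-Altman plot
#'
#' Differences against pairwise means with bias and limits of agreement.
#' Requires the original pairs.
#'
#' @param ba An `scg_blandaltman` result.
#' @param x,y The paired measurements it was computed from.
#' @param ... Passed to [graphics::plot()].
#' @export
plot_bland_altman <- function(ba, x, y, ...) {
  cc <- stats::complete.cases(x, y)
  d <- x[cc] - y[cc]; m <- (x[cc] + y[cc]) / 2
  graphics::plot(m, d, xlab = "pairwise mean", ylab = "difference", ...)
  graphics::abline(h = ba$bias, col = "steelblue")
  graphics::abline(h = c(ba$loa_lower, ba$loa_upper), col = "firebrick",
                   lty = 2)
  invisible(ba)
}

#' Two-way mixed-model intraclass correlation (absolute agreement)
#'
#' Single-measure ICC for absolute agreement under a two-way model without
#' interaction (McGraw-Wong ICC(A,1)): subjects are rows, the k sessions /
#' devices are the fixed columns. From the two-way ANOVA mean squares
#' (between-subjects MSp, between-sessions MSc, residual MSe),
#' \deqn{ICC = \frac{MS_p - MS_e}{MS_p + (k-1) MS_e +
#'   \frac{k}{n}(MS_c - MS_e)}}
#' with the 95% CI obtained by the McGraw-Wong F-distribution method.
#'
#' @param data n x k numeric matrix (or data frame), complete.
#' @param conf_level Confidence level (default 0.95).
#' @return Object of class `scg_icc` with `icc`, `ci95`,
#'   `ms_between_subjects`, `ms_between_sessions`, `ms_error`, `n`, `k`,
#'   `label`.
#' @export
icc_two_way_mixed <- function(data, conf_level = 0.95) {
  M <- as.matrix(data)
  if (anyNA(M)) stop("ICC requires a complete matrix", call. = FALSE)
  n <- nrow(M); k <- ncol(M)
  if (n < 2L || k < 2L)
    stop("ICC needs at least 2 subjects and 2 sessions", call. = FALSE)
  grand <- mean(M)
  rm <- rowMeans(M); cm <- colMeans(M)
  ss_total <- sum((M - grand)^2)
  if (ss_total == 0) stop("zero total variance: ICC undefined",
                          call. = FALSE)
  ss_r <- k * sum((rm - grand)^2)
  ss_c <- n * sum((cm - grand)^2)
  ss_e <- ss_total - ss_r - ss_c
  msp <- ss_r / (n - 1)
  msc <- ss_c / (k - 1)
  mse <- ss_e / ((n - 1) * (k - 1))
  icc <- (msp - mse) / (msp + (k - 1) * mse + k / n * (msc - mse))
  # McGraw-Wong CI for ICC(A,1)
  alpha <- 1 - conf_level
  a <- k * icc / (n * (1 - icc))
  b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
  nu <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  fl <- stats::qf(1 - alpha / 2, n - 1, nu)
  fu <- stats::qf(1 - alpha / 2, nu, n - 1)
  lower <- n * (msp - fl * mse) /
    (fl * (k * msc + (k * n - k - n) * mse) + n * msp)
  upper <- n * (fu * msp - mse) /
    (k * msc + (k * n - k - n) * mse + n * fu * msp)
  if (!is.finite(lower)) lower <- NA_real_
  if (!is.finite(upper)) upper <- NA_real_
  structure(
    list(icc = icc, ci95 = c(lower, upper), ms_between_subjects = msp,
         ms_between_sessions = msc, ms_error = mse, n = n, k = k,
         label = interpret_icc(icc)),
    class = "scg_icc")
}

#' @export
print.scg_icc <- function(x, ...) {
  cat(sprintf("<ICC(A,1)> %.3f [%.3f, %.3f] (%s; n=%d, k=%d)\n", x$icc,
              x$ci95[1L], x$ci95[2L], x$label, x$n, x$k))
  invisible(x)
}

#' Qualitative ICC interpretation
#'
#' `"excellent"` above 0.8, `"satisfactory"` above 0.7, otherwise `"poor"`
#' (strict inequalities).
#'
#' @param icc Numeric ICC value.
#' @return Character label.
#' @export
interpret_icc <- function(icc) {
  if (!is.finite(icc)) stop("ICC must be finite", call. = FALSE)
  if (icc > 0.8) "excellent" else if (icc > 0.7) "satisfactory" else "poor"
}

#' At-home compliance analysis by age group
#'
#' Per-patient compliance is `100 * completed / expected`; the overall rate
#' pools the counts, `100 * sum(completed) / sum(expected)` (a weighted
#' mean of the per-patient percentages with expected counts as weights).
#' Patients are grouped into the age bands `<46`, `46-75` and `>75` years
#' and compared by one-way ANOVA; when the ANOVA is significant at
#' `alpha`, pairwise comparisons use an independent t-test when both groups
#' pass the Lilliefors normality check, otherwise a Mann-Whitney U test,
#' with a Bonferroni-adjusted significance threshold of `p < 0.017` for the
#' three comparisons.
#'
#' @param table A compliance table, see [read_compliance()].
#' @param age_breaks Upper bounds of the first two bands (default
#'   `c(45, 75)`).
#' @param alpha ANOVA significance level (default 0.05).
#' @param p_threshold Bonferroni pairwise threshold (default 0.017).
#' @param n_mc,seed Monte Carlo settings for the normality checks.
#' @return Object of class `scg_compliance` with `overall_pct`,
#'   `group_pcts`, `group_n`, `anova_p`, `pairwise` (data frame), and the
#'   per-patient data.
#' @export
compliance_analysis <- function(table, age_breaks = c(45, 75),
                                alpha = 0.05, p_threshold = 0.017,
                                n_mc = 2000, seed = 1) {
  table <- read_compliance(table)
  drop <- table$expected_count == 0
  if (any(drop)) {
    warning(sprintf("excluding %d patient(s) with zero expected recordings",
                    sum(drop)))
    table <- table[!drop, , drop = FALSE]
  }
  pct <- 100 * table$completed_count / table$expected_count
  band_labels <- c(sprintf("<%d", age_breaks[1L] + 1L),
                   sprintf("%d-%d", age_breaks[1L] + 1L, age_breaks[2L]),
                   sprintf(">%d", age_breaks[2L]))
  group <- cut(table$age, c(-Inf, age_breaks, Inf), labels = band_labels)
  overall <- 100 * sum(table$completed_count) / sum(table$expected_count)
  group_pcts <- vapply(split(seq_along(pct), group), function(i)
    if (length(i)) 100 * sum(table$completed_count[i]) /
      sum(table$expected_count[i]) else NA_real_, 0)
  group_n <- as.integer(table(group))
  present <- levels(group)[tabulate(group, nbins = 3L) >= 2L]
  anova_p <- NA_real_
  pairwise <- data.frame(group_a = character(0), group_b = character(0),
                         test = character(0), p_value = numeric(0),
                         significant = logical(0))
  if (length(present) >= 2L) {
    sub <- group %in% present
    fit <- stats::aov(pct[sub] ~ droplevels(group[sub]))
    anova_p <- summary(fit)[[1L]][["Pr(>F)"]][1L]
    if (is.finite(anova_p) && anova_p < alpha) {
      combos <- utils::combn(present, 2L)
      for (j in seq_len(ncol(combos))) {
        ga <- combos[1L, j]; gb <- combos[2L, j]
        xa <- pct[group == ga]; xb <- pct[group == gb]
        if (length(xa) < 2L || length(xb) < 2L) {
          warning(sprintf("skipping %s vs %s: too few patients", ga, gb))
          next
        }
        normal <- function(v)
          length(v) >= 4L && stats::sd(v) > 0 &&
            lilliefors(v, n_mc = n_mc, seed = seed)$p_value >= alpha
        if (normal(xa) && normal(xb)) {
          tst <- "t"; p <- stats::t.test(xa, xb)$p.value
        } else {
          tst <- "mann-whitney"
          p <- stats::wilcox.test(xa, xb, exact = FALSE)$p.value
        }
        pairwise <- rbind(pairwise,
                          data.frame(group_a = ga, group_b = gb, test = tst,
                                     p_value = p,
                                     significant = p < p_threshold))
      }
    }
  } else {
    warning("fewer than two age bands with >= 2 patients: ANOVA skipped")
  }
  structure(
    list(overall_pct = overall, group_pcts = group_pcts, group_n = group_n,
         anova_p = anova_p, pairwise = pairwise, p_threshold = p_threshold,
         per_patient = data.frame(age = table$age, group = group,
                                  compliance_pct = pct)),
    class = "scg_compliance")
}

#' @export
print.scg_compliance <- function(x, ...) {
  cat(sprintf("<compliance> overall %.1f%% (n=%d)\n", x$overall_pct,
              nrow(x$per_patient)))
  for (i in seq_along(x$group_pcts))
    cat(sprintf("  %-6s %.1f%% (n=%d)\n", names(x$group_pcts)[i],
                x$group_pcts[i], x$group_n[i]))
  cat(sprintf("  ANOVA p %.3g\n", x$anova_p))
  if (nrow(x$pairwise))
    for (i in seq_len(nrow(x$pairwise)))
      cat(sprintf("  %s vs %s (%s): p %.3g%s\n", x$pairwise$group_a[i],
                  x$pairwise$group_b[i], x$pairwise$test[i],
                  x$pairwise$p_value[i],
                  if (x$pairwise$significant[i]) " *" else ""))
  invisible(x)
}
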