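#' Bland-Altman agreement analysis
#'
#' Agreement between paired measurements via the mean difference and limits of
#' agreement. Differences are `x - y` in unit mode or
#' `100 * (x - y) / mean(x, y)` per pair in percent mode. Limits are
#' `d +/- loa_factor * s` (1.96 by default for the 95% interval; 2.0 available
#' as an option). The mean-difference confidence interval uses the t
#' distribution; a Shapiro-Wilk p-value for the normality of the differences
#' is attached as an advisory (the analysis is always computed).
#'
#' @param x,y paired measurements (test and retest, or method and reference).
#' @param percent express differences as percentages of the pairwise mean.
#' @param alpha significance level for the mean-difference CI.
#' @param loa_factor multiplier for the limits of agreement (1.96 or 2).
#' @return An object of class `bland_altman`: `mean_diff`, `sd_diff`,
#'   `loa_lower`, `loa_upper`, `mean_diff_ci`, `percent_mode`, `normality_p`,
#'   `degenerate` (TRUE when all differences are identical), `differences`,
#'   `means`.
#' @export
bland_altman <- function(x, y, percent = FALSE, alpha = 0.05,
                         loa_factor = 1.96) {
  stopifnot(length(x) == length(y), length(x) >= 3,
            all(is.finite(x)), all(is.finite(y)),
            alpha > 0, alpha < 1, loa_factor > 0)
  m <- (x + y) / 2
  if (percent) {
    zero <- which(abs(m) < .Machine$double.eps)
    if (length(zero) > 0)
      stop(sprintf("zero pairwise mean at index(es) %s: percent differences undefined",
                   paste(zero, collapse = ", ")))
    d <- 100 * (x - y) / m
  } else {
    d <- x - y
  }
  n <- length(d)
  md <- mean(d)
  s <- stats::sd(d)
  degenerate <- s < .Machine$double.eps * max(1, abs(md))
  se <- s / sqrt(n)
  tq <- stats::qt(1 - alpha / 2, df = n - 1)
  norm_p <- if (degenerate) NA_real_ else
    tryCatch(stats::shapiro.test(d)$p.value, error = function(e) NA_real_)
  structure(list(mean_diff = md, sd_diff = s,
                 loa_lower = md - loa_factor * s,
                 loa_upper = md + loa_factor * s,
                 mean_diff_ci = c(md - tq * se, md + tq * se),
                 percent_mode = percent,
                 normality_p = norm_p,
                 degenerate = degenerate,
                 differences = d, means = m),
            class = "bland_altman")
}

#' Intraclass correlation, two-way model, absolute agreement, single measure
#'
#' ICC(A,1): from the two-way ANOVA mean squares,
#' `(MS_R - MS_E) / (MS_R + (k-1) MS_E + (k/n) (MS_C - MS_E))`, with the
#' standard F-based confidence bounds and an F test of ICC = 0. Mean squares
#' are computed directly from the data sums of squares.
#'
#' @param data numeric matrix, n subjects x k raters/sessions, no missing
#'   cells.
#' @param alpha significance level for the confidence interval.
#' @return An object of class `icc_result`: `icc`, `ci`, `model`, `p_value`,
#'   `ms` (the mean squares), `degenerate`.
#' @export
icc_absolute <- function(data, alpha = 0.05) {
  data <- as.matrix(data)
  n <- nrow(data); k <- ncol(data)
  stopifnot(n >= 3, k >= 2, all(is.finite(data)))
  grand <- mean(data)
  row_m <- rowMeans(data)
  col_m <- colMeans(data)
  SSR <- k * sum((row_m - grand)^2)
  SSC <- n * sum((col_m - grand)^2)
  SST <- sum((data - grand)^2)
  SSE <- SST - SSR - SSC
  MSR <- SSR / (n - 1)
  MSC <- SSC / (k - 1)
  MSE <- SSE / ((n - 1) * (k - 1))
  if (SST < .Machine$double.eps * max(1, grand^2))
    return(structure(list(icc = NA_real_, ci = c(NA_real_, NA_real_),
                          model = "two-way mixed, absolute agreement, single measure",
                          p_value = NA_real_,
                          ms = c(MSR = MSR, MSC = MSC, MSE = MSE),
                          degenerate = TRUE),
                     class = "icc_result"))
  icc <- (MSR - MSE) / (MSR + (k - 1) * MSE + (k / n) * (MSC - MSE))
  Fvalue <- MSR / MSE
  p <- stats::pf(Fvalue, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)
  # Satterthwaite df for the absolute-agreement CI (McGraw & Wong)
  Fj <- MSC / MSE
  vn <- (k - 1) * (n - 1) *
    (k * icc * Fj + n * (1 + (k - 1) * icc) - k * icc)^2
  vd <- (n - 1) * k^2 * icc^2 * Fj^2 +
    (n * (1 + (k - 1) * icc) - k * icc)^2
  v <- vn / vd
  FL <- stats::qf(1 - alpha / 2, n - 1, v)
  FU <- stats::qf(1 - alpha / 2, v, n - 1)
  lb <- (n * (MSR - FL * MSE)) /
    (FL * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
  ub <- (n * (FU * MSR - MSE)) /
    (k * MSC + (k * n - k - n) * MSE + n * FU * MSR)
  if (!is.finite(lb)) lb <- NA_real_
  if (!is.finite(ub)) ub <- NA_real_
  structure(list(icc = icc, ci = c(lb, ub),
                 model = "two-way mixed, absolute agreement, single measure",
                 p_value = p,
                 ms = c(MSR = MSR, MSC = MSC, MSE = MSE),
                 degenerate = FALSE),
            class = "icc_result")
}

#' Error summaries between paired measurements
#'
#' Root mean square difference, median and interquartile range of the
#' absolute differences, and the mean and SD of the absolute percentage
#' difference relative to the reference `y`.
#'
#' @param x measurements; `y` reference values (non-zero for the percentage
#'   terms).
#' @param y reference measurements.
#' @return list with `rmsd`, `median_abs_diff`, `iqr_abs_diff`,
#'   `mean_abs_pct`, `sd_abs_pct`.
#' @export
error_summaries <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 1,
            all(is.finite(x)), all(is.finite(y)))
  if (any(abs(y) < .Machine$double.eps))
    stop("zero reference value: absolute percentage difference undefined")
  d <- x - y
  ad <- abs(d)
  pct <- 100 * ad / abs(y)
  list(rmsd = sqrt(mean(d^2)),
       median_abs_diff = stats::median(ad),
       iqr_abs_diff = stats::IQR(ad),
       mean_abs_pct = mean(pct),
       sd_abs_pct = stats::sd(pct))
}

#' Sample size for detecting a correlation
#'
#' Two-tailed test of H0: correlation = 0 via the Fisher z transformation:
#' `n = ((z_{1-alpha/2} + z_power) / atanh(r))^2 + 3`, inflated by the given
#' fraction for attrition and rounded up once at the end. With r = 0.7,
#' alpha = 0.05, power = 0.8 and 10% inflation this yields 15.
#'
#' @param r anticipated correlation coefficient (0 < |r| < 1).
#' @param alpha two-tailed significance level.
#' @param power target power (1 - beta).
#' @param inflation fractional inflation of the preliminary sample size.
#' @return integer sample size.
#' @export
sample_size_correlation <- function(r, alpha = 0.05, power = 0.8,
                                    inflation = 0.10) {
  if (!is.finite(r) || r == 0 || abs(r) >= 1)
    stop("r must satisfy 0 < |r| < 1")
  stopifnot(alpha > 0, alpha < 1, power > 0, power < 1, inflation >= 0)
  cz <- atanh(abs(r))
  n0 <- ((stats::qnorm(1 - alpha / 2) + stats::qnorm(power)) / cz)^2 + 3
  as.integer(ceiling(n0 * (1 + inflation)))
}

#' Bland-Altman plot
#'
#' Mean-difference plot with the bias line, limits of agreement, and the
#' mean-difference confidence band, in base graphics.
#'
#' @param ba a [bland_altman()] result.
#' @param main plot title.
#' @param xlab,ylab axis labels; defaults depend on `percent_mode`.
#' @return invisibly, `ba`.
#' @export
plot_bland_altman <- function(ba, main = "Bland-Altman",
                              xlab = "Mean of paired measurements",
                              ylab = NULL) {
  stopifnot(inherits(ba, "bland_altman"))
  if (is.null(ylab))
    ylab <- if (ba$percent_mode) "Difference (%)" else "Difference"
  ylim <- range(ba$differences, ba$loa_lower, ba$loa_upper)
  plot(ba$means, ba$differences, pch = 19, xlab = xlab, ylab = ylab,
       main = main, ylim = ylim + c(-0.1, 0.1) * diff(ylim))
  graphics::abline(h = ba$mean_diff, col = "blue", lwd = 2)
  graphics::abline(h = c(ba$loa_lower, ba$loa_upper), col = "red", lty = 2)
  graphics::abline(h = ba$mean_diff_ci, col = "blue", lty = 3)
  graphics::abline(h = 0, col = "grey50")
  invisible(ba)
}
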