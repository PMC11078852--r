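test_that("Bland-Altman limits follow the closed form and an oracle", {
  # differences {-1, 0, 1}: mean 0, sd 1, limits +/- 1.96
  x <- c(9, 10, 11); y <- c(10, 10, 10)
  ba <- bland_altman(x, y)
  expect_equal(ba$mean_diff, 0)
  expect_equal(ba$sd_diff, 1)
  expect_equal(c(ba$loa_lower, ba$loa_upper), c(-1.96, 1.96))
  expect_true(ba$loa_lower <= ba$mean_diff && ba$mean_diff <= ba$loa_upper)

  # the 2s variant is available
  ba2 <- bland_altman(x, y, loa_factor = 2)
  expect_equal(c(ba2$loa_lower, ba2$loa_upper), c(-2, 2))

  # identical pairs collapse the limits and are flagged
  bd <- bland_altman(y, y)
  expect_true(bd$degenerate)
  expect_equal(c(bd$loa_lower, bd$loa_upper), c(0, 0))

  # random data: limits equal an independently coded mean +/- 1.96 sd
  set.seed(51)
  for (i in 1:10) {
    a <- rnorm(20, 10, 2); b <- a + rnorm(20, 0.3, 0.8)
    bar <- bland_altman(a, b)
    d <- a - b
    m <- sum(d) / length(d)
    s <- sqrt(sum((d - m)^2) / (length(d) - 1))
    expect_equal(bar$mean_diff, m)
    expect_equal(bar$loa_lower, m - 1.96 * s)
    expect_equal(bar$loa_upper, m + 1.96 * s)
    expect_true(bar$mean_diff_ci[1] < m && m < bar$mean_diff_ci[2])
    expect_true(is.finite(bar$normality_p))
    # swapping the inputs negates the bias and mirrors the limits
    swapped <- bland_altman(b, a)
    expect_equal(swapped$mean_diff, -bar$mean_diff)
    expect_equal(swapped$loa_lower, -bar$loa_upper)
    expect_equal(swapped$loa_upper, -bar$loa_lower)
  }

  # percent mode rejects zero pairwise means, naming the offender
  expect_error(bland_altman(c(1, -1, 2), c(-1, 1, 2), percent = TRUE), "2")
  bp <- bland_altman(c(10, 12, 8), c(9, 13, 8), percent = TRUE)
  expect_equal(bp$differences,
               100 * (c(10, 12, 8) - c(9, 13, 8)) / c(9.5, 12.5, 8))
})

test_that("ICC(A,1) equals the ANOVA mean-squares oracle", {
  # identical columns with between-subject spread: perfect agreement
  m <- cbind(c(4, 8, 15, 16, 23, 42), c(4, 8, 15, 16, 23, 42))
  r <- icc_absolute(m)
  expect_equal(r$icc, 1)

  # integer toy matrix against an independent aov-based computation
  toy <- cbind(c(9, 6, 8, 7, 10, 6), c(2, 1, 4, 1, 5, 2))
  rt <- icc_absolute(toy)
  expect_equal(rt$icc, icc_aov_oracle(toy), tolerance = 1e-12)
  expect_true(rt$ci[1] <= rt$icc && rt$icc <= rt$ci[2])
  expect_lte(rt$icc, 1)

  set.seed(52)
  for (i in 1:5) {
    mat <- matrix(rnorm(8 * 3, 10, 3), 8, 3) + rnorm(8, 0, 2)
    expect_equal(icc_absolute(mat)$icc, icc_aov_oracle(mat),
                 tolerance = 1e-10)
  }

  # independent noise: near-zero agreement at large n
  set.seed(53)
  noise <- cbind(rnorm(200), rnorm(200))
  expect_lt(abs(icc_absolute(noise)$icc), 0.2)

  # invariance to common shift and positive scaling
  expect_equal(icc_absolute(toy + 100)$icc, rt$icc, tolerance = 1e-9)
  expect_equal(icc_absolute(toy * 3.7)$icc, rt$icc, tolerance = 1e-9)

  # flat data is degenerate, not an arbitrary number
  expect_true(icc_absolute(matrix(5, 6, 2))$degenerate)

  # simulated test-retest with known variance components recovers the
  # analytic ICC sigma_b^2 / (sigma_b^2 + sigma_w^2)
  set.seed(54)
  subj <- rnorm(500, 0, 2)
  obs <- cbind(subj + rnorm(500), subj + rnorm(500))
  expect_equal(icc_absolute(obs)$icc, 4 / 5, tolerance = 0.05)
})

test_that("error summaries match their definitions", {
  z <- error_summaries(c(1, 2, 3), c(1, 2, 3))
  expect_equal(unlist(z[c("rmsd", "median_abs_diff", "iqr_abs_diff",
                          "mean_abs_pct")]),
               c(rmsd = 0, median_abs_diff = 0, iqr_abs_diff = 0,
                 mean_abs_pct = 0))

  # differences {3, 4}: RMSD = sqrt((9 + 16) / 2)
  e <- error_summaries(c(13, 24), c(10, 20))
  expect_equal(e$rmsd, sqrt(12.5))
  expect_equal(e$median_abs_diff, 3.5)

  set.seed(55)
  a <- rnorm(30, 12, 3); b <- rnorm(30, 12, 3)
  eo <- error_summaries(a, b)
  expect_equal(eo$rmsd, sqrt(sum((a - b)^2) / 30))
  expect_equal(eo$median_abs_diff, median(abs(a - b)))
  expect_equal(eo$mean_abs_pct, mean(100 * abs(a - b) / abs(b)))

  expect_error(error_summaries(c(1, 2), c(1, 0)), "zero reference")
})

test_that("the correlation sample-size calculation is reproduced", {
  expect_identical(sample_size_correlation(0.7, 0.05, 0.8, 0.10), 15L)
  expect_lte(sample_size_correlation(0.99), 5L)
  # monotone: weaker anticipated correlation needs more subjects
  expect_gt(sample_size_correlation(0.5), sample_size_correlation(0.7))
  # monotone in alpha and power
  expect_gte(sample_size_correlation(0.7, alpha = 0.01),
             sample_size_correlation(0.7, alpha = 0.05))
  expect_gte(sample_size_correlation(0.7, power = 0.9),
             sample_size_correlation(0.7, power = 0.8))
  expect_error(sample_size_correlation(0), "r must")
  expect_error(sample_size_correlation(1), "r must")
})
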