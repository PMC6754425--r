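paper_labels <- function() {
  list(cin = c(rep("CIN", 27), rep("CNS", 28)),
       rsp = c(rep("PR", 16), rep("SD", 10), "PD",
               rep("PR", 9), rep("SD", 16), rep("PD", 3)))
}

test_that("the response table dichotomizes PR vs SD+PD", {
  pl <- paper_labels()
  tab <- build_table(pl$cin, pl$rsp)
  expect_equal(unclass(tab)[1:2, 1:2],
               matrix(c(16L, 9L, 11L, 19L), 2, 2,
                      dimnames = list(c("CIN", "CNS"),
                                      c("responder", "non_responder"))))
  raw <- attr(tab, "raw")
  expect_equal(as.vector(raw), c(16L, 9L, 10L, 16L, 1L, 3L))

  expect_error(build_table(character(0), character(0)), "empty cohort")
  expect_error(build_table(c("CIN", "LOW"), c("PR", "PR")),
               "unknown instability")
  expect_error(build_table(c("CIN", "CNS"), c("PR", "CR")),
               "unknown response")
  all_pr <- build_table(c("CIN", "CNS"), c("PR", "PR"))
  expect_true(attr(all_pr, "untestable"))
})

test_that("the Pearson chi-square reproduces its closed form and tail", {
  tab <- build_table(paper_labels()$cin, paper_labels()$rsp)
  res <- pearson_chi2(tab)
  # closed form n(ad-bc)^2 / (r1 r2 c1 c2), computed independently
  a <- 16; b <- 11; c <- 9; d <- 19; n <- a + b + c + d
  closed <- n * (a * d - b * c)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
  expect_equal(res$statistic, closed, tolerance = 1e-12)
  expect_equal(res$df, 1L)
  expect_equal(round(res$p_value, 3), 0.043)
  # agreement with the standard implementation, uncorrected
  ct <- suppressWarnings(chisq.test(unclass(tab)[1:2, 1:2],
                                    correct = FALSE))
  expect_equal(res$statistic, unname(ct$statistic), tolerance = 1e-12)
  expect_equal(res$p_value, ct$p.value, tolerance = 1e-12)

  # Yates correction is available but off by default
  yates <- pearson_chi2(tab, correct = TRUE)
  expect_gt(yates$p_value, 0.05)
  expect_gt(yates$p_value, res$p_value)
})

test_that("chi-square behaves as a test statistic should", {
  prop <- matrix(c(10, 20, 5, 10), 2)  # proportional rows
  res <- pearson_chi2(prop)
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$p_value, 1)

  set.seed(14)
  last_p <- NULL
  for (r in 1:20) {
    tab <- matrix(rpois(4, 15) + 1, 2)
    res <- pearson_chi2(tab)
    # independent quadrature oracle for the chi-square(1) upper tail
    oracle <- integrate(function(x) exp(-x / 2) / sqrt(2 * pi * x),
                        lower = res$statistic, upper = Inf,
                        rel.tol = 1e-12)$value
    expect_equal(res$p_value, oracle, tolerance = 1e-8)
    # row/column swap invariance
    expect_equal(pearson_chi2(tab[2:1, ])$statistic, res$statistic,
                 tolerance = 1e-12)
    expect_equal(pearson_chi2(tab[, 2:1])$statistic, res$statistic,
                 tolerance = 1e-12)
    expect_true(res$p_value > 0 && res$p_value <= 1)
  }
  # p monotone decreasing in the statistic
  stats <- c(0.5, 1, 2, 4, 8)
  ps <- pchisq(stats, 1, lower.tail = FALSE)
  expect_true(all(diff(ps) < 0))

  expect_error(pearson_chi2(matrix(c(0, 0, 3, 4), 2)), "zero row or column")
})

test_that("response rates match the printed percentages", {
  tab <- build_table(paper_labels()$cin, paper_labels()$rsp)
  rr <- response_rates(tab)
  expect_equal(rr$percent, c(59, 32))
  expect_equal(rr$rate, c(16 / 27, 9 / 28), tolerance = 1e-12)
  zero <- matrix(c(0L, 5L, 7L, 5L), 2,
                 dimnames = list(c("CIN", "CNS"), NULL))
  expect_equal(response_rates(zero)$percent[1], 0)
  expect_error(response_rates(matrix(c(0L, 5L, 0L, 5L), 2)), "empty row")
})

test_that("trajectory summaries count the printed longitudinal fractions", {
  cutoff <- 56.60
  # 15 responders, 14 of whom drop below the cutoff at PR
  resp <- lapply(1:15, function(i)
    patient_timeline(paste0("r", i), c("BL", "PR"),
                     c(70, if (i <= 14) 40 else 60), cutoff))
  # 25 progressors, 13 of whom re-rise at PD
  prog <- lapply(1:25, function(i)
    patient_timeline(paste0("p", i), c("BL", "SD", "PD"),
                     c(70, 40, if (i <= 13) 55 else 35), cutoff))
  summ <- trajectory_summary(c(resp, prog), cutoff)
  expect_equal(summ$pr_below_cutoff$k, 14L)
  expect_equal(summ$pr_below_cutoff$n, 15L)
  expect_equal(round(100 * summ$pr_below_cutoff$fraction), 93)
  expect_equal(summ$pd_elevated$k, 13L)
  expect_equal(summ$pd_elevated$n, 25L)
  expect_equal(round(100 * summ$pd_elevated$fraction), 52)
  # every PD score here stays under its baseline
  expect_equal(summ$pd_below_baseline$fraction, 1)

  flat <- trajectory_summary(list(
    patient_timeline("f", c("BL", "PD"), c(50, 50), cutoff)), cutoff)
  expect_equal(flat$pd_elevated$fraction, 0)
  expect_equal(flat$pd_below_baseline$fraction, 0)

  expect_error(patient_timeline("x", c("PR", "PD"), c(1, 2)), "start at BL")
  expect_error(trajectory_summary(list()), "no timelines")
})

test_that("pattern concordance is a Pearson correlation on log ratios", {
  y <- c(rep(0.4, 30), rep(-0.3, 30), rep(0, 40))
  a <- profile_from_log2(y)
  a$smoothing <- "segmented"
  expect_equal(pattern_concordance(a, a), 1)
  b <- profile_from_log2(-y)
  b$smoothing <- "segmented"
  expect_equal(pattern_concordance(a, b), -1)
  flat <- profile_from_log2(rep(0.2, 100))
  expect_warning(expect_true(is.na(pattern_concordance(a, flat))),
                 "zero variance")
  short <- profile_from_log2(rep(0, 10))
  expect_error(pattern_concordance(a, short), "different grids")
})
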