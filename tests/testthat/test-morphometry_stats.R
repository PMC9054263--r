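test_that("descriptive statistics use the population-SD convention", {
  tab <- morphometry_fixture()
  st <- descriptive_stats(tab)
  g <- function(m, col) st[[col]][st$measure == m]
  # spot values recomputed by hand from the subject rows
  expect_equal(g("ivc_max", "mean"), mean(c(2.85, 3.04, 3.30, 2.40)))
  expect_equal(g("ivc_max", "sd"), sd_population(c(2.85, 3.04, 3.30, 2.40)))
  expect_equal(round(g("ivc_max", "mean"), 2), 2.90)
  expect_equal(round(g("ivc_max", "sd"), 2), 0.33)
  expect_equal(round(g("ra_axis_major", "mean"), 2), 4.23)
  expect_equal(round(g("ra_axis_major", "sd"), 2), 0.68)
  # ages: 58.3 +/- 3.5 at one decimal (mean 58.25 prints as 58.3)
  expect_lt(abs(g("age", "mean") - 58.3), 0.05 + 1e-12)
  expect_equal(round(g("age", "sd"), 1), 3.5)
  # sample convention differs by sqrt(n/(n-1))
  ss <- descriptive_stats(tab, sd = "sample")
  expect_equal(ss$sd[ss$measure == "ivc_max"],
               g("ivc_max", "sd") * sqrt(4 / 3))
  # identical values: zero SD
  expect_equal(sd_population(rep(2.2, 6)), 0)
})

test_that("coefficient of variation is scale-invariant", {
  ivc_min <- c(0.53, 1.38, 0.90, 0.55)
  expect_equal(round(coefficient_of_variation(ivc_min), 2), 0.41)
  expect_equal(coefficient_of_variation(rep(1.7, 5)), 0)
  expect_equal(coefficient_of_variation(3.7 * ivc_min),
               coefficient_of_variation(ivc_min), tolerance = 1e-14)
})

test_that("min/max variability comparison reproduces the vein-table values", {
  cmp <- compare_min_max_variability(morphometry_fixture())
  expect_equal(nrow(cmp$per_vessel), 8)           # 8 veins, RA axes excluded
  expect_equal(round(cmp$mean_cv_min, 2), 0.33)
  expect_equal(round(cmp$mean_cv_max, 2), 0.17)
  expect_equal(round(cmp$p_normal_cc, 2), 0.02)
  expect_equal(cmp$p_exact, 0.015625)
  expect_true(all(cmp$per_vessel$cv_min > 0))
})

test_that("Wilcoxon signed-rank enumeration and approximation are correct", {
  # n = 5, all positive differences: exact two-sided P = 2/32
  w5 <- wilcoxon_signed_rank(c(1, 2, 3, 4, 5), method = "exact")
  expect_equal(w5$p_value, 2 / 32)
  expect_equal(w5$statistic, 15)
  # n = 8, extreme negative: W = 0 gives 2/256
  w8 <- wilcoxon_signed_rank(-(1:8), method = "exact")
  expect_equal(w8$statistic, 0)
  expect_equal(w8$p_value, 2 / 256)
  # symmetric pairs: statistic at the null centre, P = 1
  d <- c(0.4, -0.4, 1.1, -1.1)
  ws <- wilcoxon_signed_rank(d, method = "exact")
  expect_equal(ws$statistic, length(d) * (length(d) + 1) / 4)
  expect_equal(ws$p_value, 1)
  expect_equal(wilcoxon_signed_rank(rep(0, 4))$p_value, 1)  # zeros dropped
  expect_error(wilcoxon_signed_rank(rnorm(26), method = "exact"), "n <= 25")
})

test_that("both Wilcoxon methods agree with each other and with wilcox.test", {
  set.seed(31)
  for (n in c(8, 11, 15)) {
    x <- rnorm(n); y <- x + 0.4 + rnorm(n, 0, 0.7)
    cc <- wilcoxon_signed_rank(x, y, "normal_cc")
    ex <- wilcoxon_signed_rank(x, y, "exact")
    expect_lt(abs(cc$p_value - ex$p_value), 0.02)
    ref_cc <- wilcox.test(x, y, paired = TRUE, exact = FALSE, correct = TRUE)
    expect_equal(cc$p_value, ref_cc$p.value, tolerance = 1e-10)
    ref_ex <- wilcox.test(x, y, paired = TRUE, exact = TRUE)
    expect_equal(ex$p_value, ref_ex$p.value, tolerance = 1e-10)
  }
})

test_that("Student's t handles textbook and degenerate cases", {
  a <- c(5.1, 4.9, 6.0, 5.5, 5.3)
  expect_equal(students_t_test(a, a, paired = TRUE)$p_value, 1)
  expect_equal(students_t_test(a, a, paired = TRUE)$t, 0)
  # hand-computed pooled two-sample t
  b <- c(4.2, 4.8, 5.0, 4.4, 4.1)
  sp2 <- (4 * var(a) + 4 * var(b)) / 8
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 5 + 1 / 5))
  p_hand <- 2 * pt(-abs(t_hand), 8)
  res <- students_t_test(a, b)
  expect_equal(res$t, t_hand, tolerance = 1e-10)
  expect_equal(res$p_value, p_hand, tolerance = 1e-10)
  expect_equal(res$df, 8)
  # constant nonzero difference with zero variance: P -> 0 sentinel
  dg <- students_t_test(a, a + 1, paired = TRUE)
  expect_equal(dg$p_value, 0)
})

test_that("Shapiro-Wilk accepts normal samples and flags skewed ones", {
  qs <- qnorm(ppoints(20))
  expect_gt(shapiro_wilk(qs)$W, 0.95)
  expect_lt(shapiro_wilk(exp(3 * qs))$p_value, 0.05)
  expect_error(shapiro_wilk(c(1, 2)), "between 3 and 50")
  expect_error(shapiro_wilk(rnorm(51)), "between 3 and 50")
})

test_that("gated diameter change is (max - min)/mean and scale-free", {
  expect_equal(diameter_change(rep(2.4, 6)), 0)
  s <- c(2.0, 2.2, 2.6, 2.4, 2.1, 2.3)
  expect_equal(diameter_change(s), (2.6 - 2.0) / mean(s))
  expect_equal(round(diameter_change(s), 3), 0.265)
  expect_equal(diameter_change(10 * s), diameter_change(s), tolerance = 1e-14)
  expect_error(diameter_change(c(1)), "2 positive samples")
})

test_that("morphometry CSV validation rejects inconsistent tables", {
  bad <- tempfile(fileext = ".csv")
  writeLines(c("subject,v_min,v_max", "1,2.0,1.0"), bad)
  expect_error(read_morphometry(bad), "min > max")
  writeLines(c("subject,v_min,v_max", "1,-2.0,1.0"), bad)
  expect_error(read_morphometry(bad), "non-positive")
  unlink(bad)
})
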