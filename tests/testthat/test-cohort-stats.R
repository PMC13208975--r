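test_that("percent change reproduces the printed clinical deltas", {
  # ACT 21 -> 24
  act <- percent_change(21, 24)
  expect_equal(act$rounded, 14.29)
  # NPS 4.14 -> 0.75: -81.88 raw, -82 at integer rounding
  nps <- percent_change(4.14, 0.75, digits = 0)
  expect_equal(round(nps$percent, 2), -81.88)
  expect_equal(nps$rounded, -82)
  # no change
  expect_equal(percent_change(7.3, 7.3)$percent, 0)
  expect_error(percent_change(0, 5), "zero baseline")
})

test_that("Wilcoxon signed-rank: exact path, zero handling, symmetry", {
  # identical columns -> p = 1 with warning
  x <- c(1, 2, 3, 4)
  expect_warning(res <- wilcoxon_signed_rank(x, x), "zero")
  expect_equal(res$p.value, 1)
  expect_equal(res$zeros_dropped, 4L)

  # n = 6 strictly positive differences: two-sided exact p = 2/64
  pre <- c(1, 2, 3, 4, 5, 6)
  post <- pre + c(0.5, 1.1, 0.7, 2.2, 1.4, 0.9)
  r <- wilcoxon_signed_rank(pre, post)
  expect_true(r$exact)
  expect_equal(r$p.value, 0.03125)
  expect_equal(r$statistic, 21)   # all ranks positive: 6*7/2

  # sign-flip symmetry
  r2 <- wilcoxon_signed_rank(post, pre)
  expect_equal(r2$p.value, r$p.value)

  expect_error(wilcoxon_signed_rank(1:3, 1:4), "same length")
})

test_that("Wilcoxon exact p matches sign-assignment enumeration", {
  set.seed(2024)
  for (rep in 1:100) {
    n <- sample(3:10, 1)
    d <- round(runif(n, 0.1, 10), 3) * sample(c(-1, 1), n, replace = TRUE)
    while (anyDuplicated(abs(d)) > 0)
      d <- round(runif(n, 0.1, 10), 3) * sample(c(-1, 1), n, replace = TRUE)
    got <- wilcoxon_signed_rank(rep(0, n), d)
    expect_true(got$exact)
    expect_equal(got$p.value, oracle_wilcoxon_exact(d), tolerance = 1e-12)
  }
})

test_that("Wilcoxon falls back to the corrected normal approximation", {
  set.seed(5)
  pre <- rnorm(30); post <- pre + rnorm(30, 0.5)
  r <- wilcoxon_signed_rank(pre, post)
  expect_false(r$exact)
  expect_match(r$method, "continuity correction")
  # ties force the approximation even at small n
  r2 <- wilcoxon_signed_rank(c(0, 0, 0, 0), c(1, 1, 2, 3))
  expect_false(r2$exact)
})

test_that("Friedman: closed form on strictly ordered columns, invariances", {
  m <- matrix(c(1:10, 11:20, 21:30), ncol = 3)  # strictly ordered per subject
  ft <- friedman_test(m)
  expect_equal(ft$statistic, 20)   # 12n/(k(k+1)) * sum (Rbar - (k+1)/2)^2
  expect_equal(ft$df, 2)
  expect_lt(ft$p.value, 0.001)

  # identical columns -> statistic 0, p = 1
  same <- matrix(rep(1:8, 3), ncol = 3)
  ft0 <- friedman_test(same)
  expect_equal(ft0$statistic, 0)
  expect_equal(ft0$p.value, 1)

  # permuting subjects leaves the statistic unchanged
  perm <- m[sample(nrow(m)), ]
  expect_equal(friedman_test(perm)$statistic, ft$statistic)

  # joint strictly monotone transform preserves within-subject ranks
  expect_equal(friedman_test(exp(m / 10))$statistic, ft$statistic)

  expect_error(friedman_test(matrix(c(1, NA, 2, 3), ncol = 2)), "missing")
  expect_error(friedman_test(matrix(1:3, ncol = 1)), "at least 2")
})

test_that("Bonferroni correction caps at 1 and never lowers a p-value", {
  expect_equal(bonferroni(0.01, m = 3), 0.03)
  expect_equal(bonferroni(0.5, m = 3), 1)
  set.seed(9)
  p <- runif(20)
  expect_true(all(bonferroni(p, m = 4) >= p))
  expect_error(bonferroni(1.2), "\\[0, 1\\]")
})

test_that("Bland-Altman bias and limits match the hand-computed oracle", {
  a <- c(1, 2, 3, 4); b <- c(0, 0, 0, 0)
  rep_ <- bland_altman(a, b)
  expect_equal(rep_$bias, 2.5)
  sd_oracle <- sqrt(sum((a - 2.5)^2) / 3)   # 1.29099...
  expect_equal(rep_$sd_diff, sd_oracle)
  expect_equal(rep_$loa_low, 2.5 - 1.96 * sd_oracle)
  expect_equal(rep_$loa_high, 2.5 + 1.96 * sd_oracle)
  expect_equal(round(rep_$sd_diff, 4), 1.291)
  expect_equal(round(rep_$loa_low, 3), -0.030)
  expect_equal(round(rep_$loa_high, 3), 5.030)

  # identical methods
  r0 <- bland_altman(a, a)
  expect_equal(r0$bias, 0)
  expect_equal(r0$loa_high - r0$loa_low, 0)
  # constant offset
  rc <- bland_altman(a, a - 0.17)
  expect_equal(rc$bias, 0.17)
  expect_equal(rc$sd_diff, 0)
  expect_error(bland_altman(1:3, 1:4), "same length")
})

test_that("agreement reports are internally consistent (limits = bias +/- 1.96 SD)", {
  # structural self-consistency on cohort-scale numbers like the reported
  # bias 0.17 with limits about (-0.007, 0.34)
  set.seed(3)
  a <- runif(20); b <- pmin(1, pmax(0, a - rnorm(20, 0.17, 0.09)))
  r <- bland_altman(a, b, names = c("pabcd", "lms_percent"))
  expect_lte(r$loa_low, r$bias)
  expect_gte(r$loa_high, r$bias)
  expect_equal(r$loa_high - r$bias, r$bias - r$loa_low)
  expect_equal(r$loa_high - r$loa_low, 2 * 1.96 * r$sd_diff)
  expect_equal(r$bias, mean(r$pairs$diff))
})

test_that("cohort tables summarize per column and timepoint", {
  co <- data.frame(
    subject_id = rep(1:3, each = 2),
    timepoint = rep(c("pre", "post"), 3),
    lms = c(9, 6, 8, 7, 9, 5),
    pabcd = c(0.7, 0.5, 0.65, 0.55, 0.75, 0.45))
  tab <- cohort_table(co)
  lms_row <- tab[tab$variable == "lms", ]
  expect_equal(lms_row$mean_pre, mean(c(9, 8, 9)))
  expect_equal(lms_row$delta_mean, mean(c(6, 7, 5)) - mean(c(9, 8, 9)))
  expect_equal(lms_row$min_pre, 8)
  expect_equal(lms_row$max_post, 7)

  # worked delta from printed means: 6.1 - 8.7 = -2.6
  printed <- data.frame(subject_id = 1, timepoint = c("pre", "post"),
                        lms_mean = c(8.7, 6.1))
  trow <- cohort_table(printed)
  expect_equal(trow$delta_mean, -2.6)
  expect_true(is.na(trow$sd_pre))   # single subject: SD absent

  const <- data.frame(subject_id = 1:4,
                      timepoint = rep(c("pre", "post"), 2),
                      v = rep(3.3, 4))
  crow <- cohort_table(const)
  expect_equal(crow$sd_pre, 0)
  expect_equal(crow$min_pre, crow$max_pre)
  expect_equal(crow$mean_pre, 3.3)
})

test_that("cohort CSV round trip preserves paired structure", {
  co <- default_cohort(5, seed = 77)
  f <- cohort_fills(co)
  long <- data.frame(
    subject_id = rep(f$id, 2),
    timepoint = rep(c("pre", "post"), each = nrow(f)),
    pabcd = c(f$pre, f$post))
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(long, path, row.names = FALSE)
  back <- read_cohort(path)
  expect_equal(nrow(back), 10L)
  tab <- cohort_table(back)
  expect_equal(tab$mean_pre, mean(f$pre))
  expect_equal(tab$delta_mean, mean(f$post) - mean(f$pre))
})
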