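test_that("stratify uses the strict-greater rule", {
  co <- survival_cohort(c(1, 2, 3), c(1, 1, 1), c(1, 2, 3))
  s <- stratify(co, 2)
  expect_equal(as.character(s$labels), c("low", "low", "high"))
  expect_equal(s$n_low, 2)
  # threshold below the minimum: everyone is high
  expect_equal(stratify(co, 0.5)$n_high, 3)
  # threshold at the maximum: high group empty (ties fall low)
  expect_equal(stratify(co, 3)$n_high, 0)
  expect_error(stratify(co, Inf), "finite")
})

test_that("the default scan grid has 81 quantile levels", {
  set.seed(51)
  sim <- simulate_cohort(n = 100, hr_high = 2, seed = 51)
  scan <- scan_cutpoints(sim$cohort)
  expect_equal(nrow(scan$table), 81)
  expect_equal(scan$table$level, seq(0.10, 0.90, by = 0.01))
  # thresholds are non-decreasing in the quantile level
  expect_true(all(diff(scan$table$threshold) >= 0))
})

test_that("scan skips degenerate splits and errors when all are degenerate", {
  co <- survival_cohort(1:10, rep(1, 10), rep(5, 10))
  expect_error(scan_cutpoints(co), "no admissible cutpoint")

  # min_group too large for the cohort fails the precondition
  sim <- simulate_cohort(n = 50, seed = 3)
  expect_error(scan_cutpoints(sim$cohort, min_group = 26), "min_group")
  # min_group at the cohort midpoint: only exactly balanced splits survive
  sc <- scan_cutpoints(sim$cohort, min_group = 25)
  ok_thr <- sc$table$threshold[!sc$table$skipped]
  expect_true(all(vapply(ok_thr, function(t) sum(sim$cohort$expr > t) == 25,
                         logical(1))))
  expect_gt(sum(sc$table$skipped), 0)
})

test_that("best statistic is maximal and ties break to the smallest level", {
  set.seed(61)
  sim <- simulate_cohort(n = 120, hr_high = 2.5, seed = 61)
  scan <- scan_cutpoints(sim$cohort)
  ok <- !scan$table$skipped
  expect_true(all(scan$best_statistic >= scan$table$statistic[ok]))
  maxima <- which(ok & scan$table$statistic == scan$best_statistic)
  expect_equal(scan$best_level, scan$table$level[min(maxima)])

  # expression with a wide gap: adjacent quantile levels give identical
  # splits, so the maximum is attained at several levels
  expr <- c(rep(1, 10), rep(10, 10))
  set.seed(62)
  co <- survival_cohort(rexp(20) + 0.01, rep(1, 20), expr)
  sc <- scan_cutpoints(co)
  dup <- sc$table$statistic == sc$best_statistic & !sc$table$skipped
  expect_gt(sum(dup), 1)
  expect_equal(sc$best_level, min(sc$table$level[dup]))
})

test_that("scan statistics match direct log-rank computation per level", {
  sim <- simulate_cohort(n = 80, hr_high = 2, seed = 71)
  co <- sim$cohort
  scan <- scan_cutpoints(co)
  for (i in sample(which(!scan$table$skipped), 10)) {
    grp <- as.integer(co$expr > scan$table$threshold[i])
    expect_equal(scan$table$statistic[i],
                 logrank_statistic(co, grp)$statistic, tolerance = 1e-12)
  }
})

test_that("permutation results are deterministic and internally consistent", {
  sim <- simulate_cohort(n = 60, hr_high = 3, seed = 81)
  p1 <- permutation_test(sim$cohort, n_perm = 300, seed = 99)
  p2 <- permutation_test(sim$cohort, n_perm = 300, seed = 99)
  expect_identical(p1$null_stats, p2$null_stats)
  expect_identical(p1$p_value, p2$p_value)

  # both exceedance rules recomputable from the returned null statistics
  expect_equal(p1$p_strict, mean(p1$null_stats > p1$observed))
  expect_equal(p1$p_add_one,
               (1 + sum(p1$null_stats >= p1$observed)) / (300 + 1))

  # observed above every null statistic: strict 0, add-one 1/(N+1)
  if (all(p1$null_stats < p1$observed)) {
    expect_identical(p1$p_strict, 0)
    expect_equal(p1$p_add_one, 1 / 301)
  }
})

test_that("permutation test validates its arguments", {
  sim <- simulate_cohort(n = 40, seed = 91)
  expect_warning(permutation_test(sim$cohort, n_perm = 50, seed = 1),
                 "fewer than 100")
  expect_error(permutation_test(sim$cohort, n_perm = 100, seed = "a"),
               "seed")
})
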