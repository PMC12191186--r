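test_that("cusum grid is exact deci-ug/g integer arithmetic", {
  co <- make_scan_cohort(c(7.1, 12.35, 29.9, 400), c(TRUE, TRUE, FALSE, TRUE))
  scan <- cusum_scan(co)
  g <- scan$grid
  expect_true(all(diff(g$threshold_deci) == 1L))
  expect_identical(g$threshold_deci[1], 70L)
  expect_identical(g$threshold_deci[nrow(g)], 4000L)
  expect_equal(g$cum_total[nrow(g)], 4)
})

test_that("jump points satisfy the min_jump increment by direct recount", {
  # six urgent patients stacked at 12.0 plus background elsewhere
  fit <- c(rep(12.0, 6), 7, 8.5, 20, 35, 50)
  urg <- c(rep(TRUE, 6), rep(FALSE, 5))
  scan <- cusum_scan(make_scan_cohort(fit, urg))
  expect_true(12 %in% scan$jump_points$threshold)
  expect_equal(nrow(scan$jump_points), 1)
  # no urgent cases: no jumps, conversion rate identically zero
  scan0 <- cusum_scan(make_scan_cohort(fit, rep(FALSE, 11)))
  expect_equal(nrow(scan0$jump_points), 0)
  expect_true(all(scan0$grid$conversion_rate == 0))
})

test_that("cusum_scan equals the brute-force recount oracle", {
  for (seed in 1:8) {
    co <- generate_cohort(synthetic_params(
      n = sample(100:1000, 1), seed = seed))
    scan <- cusum_scan(co)
    or <- oracle_cusum(co$fit_value, co$urgent)
    expect_equal(scan$grid$threshold, or$threshold)
    expect_identical(scan$grid$cum_total, or$cum_total)
    expect_identical(scan$grid$cum_urgent, or$cum_urgent)
    expect_equal(scan$grid$conversion_rate, or$rate)
    expect_equal(scan$jump_points$threshold, or$jumps)
  }
})

test_that("cumulative counts are monotone and close at the cohort", {
  co <- generate_cohort(synthetic_params(n = 700, seed = 19))
  g <- cusum_scan(co)$grid
  expect_true(all(diff(g$cum_total) >= 0))
  expect_true(all(diff(g$cum_urgent) >= 0))
  expect_true(all(g$cum_urgent <= g$cum_total))
  expect_equal(g$cum_total[nrow(g)], nrow(co))
  # rate at the grid max equals overall urgent prevalence
  expect_equal(g$conversion_rate[nrow(g)], mean(co$urgent))
})

test_that("conversion_rate_at reads the grid and refuses off-grid points", {
  fit <- c(rep(10, 199), 15)
  urg <- c(rep(FALSE, 199), TRUE)
  scan <- cusum_scan(make_scan_cohort(fit, urg))
  expect_equal(conversion_rate_at(scan, 15), 1 / 200)
  expect_error(conversion_rate_at(scan, 15.05), "nearest grid point")
  all_urgent <- cusum_scan(make_scan_cohort(c(8, 12, 30), rep(TRUE, 3)))
  rates <- all_urgent$grid$conversion_rate[all_urgent$grid$cum_total > 0]
  expect_true(all(rates == 1))
})

test_that("cohort denominator mode divides by the full cohort", {
  co <- make_scan_cohort(c(5, 10, 20, 40), c(TRUE, TRUE, FALSE, FALSE))
  scan <- cusum_scan(co, denominator = "cohort")
  expect_equal(conversion_rate_at(scan, 10), 2 / 4)
  expect_error(cusum_scan(co, step = 0), "positive")
  expect_error(cusum_scan(co, min_jump = 0), "count")
})

test_that("significance scan reproduces the closed-form 2x2 comparison", {
  # Group 1: 400 patients / 8 events; Group 2 at t = 15: 300 / 18
  fit <- c(rep(8, 400), rep(14, 300), rep(16.5, 60))
  urg <- c(rep(c(TRUE, FALSE), c(8, 392)),
           rep(c(TRUE, FALSE), c(18, 282)),
           rep(c(TRUE, FALSE), c(12, 48)))
  co <- make_scan_cohort(fit, urg)
  sc <- incremental_significance_scan(co)
  row15 <- sc$rows[sc$rows$t == 15, ]
  expect_equal(row15$n1, 400)
  expect_equal(row15$n2, 300)
  expect_equal(row15$odds_ratio, (18 / 282) / (8 / 392), tolerance = 1e-6)
  expect_lt(row15$p_value, 0.05)
  # the 16.5 block keeps every larger threshold significant too
  expect_true(all(sc$rows$p_value[sc$rows$t >= 15] < 0.05))
  expect_equal(sc$first_sustained, 14) # 14 already holds the same 2x2
})

test_that("identical event rates yield no sustained threshold", {
  fit <- c(rep(8, 200), rep(20, 200))
  urg <- rep(c(TRUE, FALSE), 200)   # 50% everywhere
  sc <- incremental_significance_scan(make_scan_cohort(fit, urg))
  expect_true(is.na(sc$first_sustained))
  ok <- !sc$rows$flagged
  expect_true(all(abs(sc$rows$odds_ratio[ok] - 1) < 1e-8))
})

test_that("empty or zero-cell thresholds are flagged, not dropped", {
  fit <- c(rep(8, 100), rep(25, 80))
  urg <- c(rep(c(TRUE, FALSE), c(10, 90)), rep(c(TRUE, FALSE), c(40, 40)))
  sc <- incremental_significance_scan(make_scan_cohort(fit, urg))
  early <- sc$rows$t < 25
  expect_true(all(sc$rows$flagged[early]))   # Group 2 empty below 25
  expect_false(any(sc$rows$flagged[!early]))
  expect_equal(nrow(sc$rows), 19)            # every t reported
  expect_error(incremental_significance_scan(
    make_scan_cohort(rep(50, 10), rep(TRUE, 10))), "Group 1")
})

test_that("tail reading of Group 2 is available and labelled", {
  fit <- c(rep(8, 300), rep(12, 50), rep(28, 50))
  urg <- c(rep(c(TRUE, FALSE), c(15, 285)),
           rep(c(TRUE, FALSE), c(5, 45)), rep(c(TRUE, FALSE), c(20, 30)))
  co <- make_scan_cohort(fit, urg)
  cum <- incremental_significance_scan(co)
  tail <- incremental_significance_scan(co, group2 = "tail")
  expect_equal(tail$group2, "tail")
  r_cum <- cum$rows[cum$rows$t == 20, ]
  r_tail <- tail$rows[tail$rows$t == 20, ]
  expect_equal(r_cum$n2, 50)    # (10, 20]: the 12s
  expect_equal(r_tail$n2, 50)   # [20, 29]: the 28s
  expect_gt(r_tail$odds_ratio, r_cum$odds_ratio)
})

test_that("first_sustained falls as the FIT effect strengthens", {
  firsts <- vapply(c(0.004, 0.02, 0.08), function(b1) {
    co <- generate_cohort(synthetic_params(n = 5000, beta1 = b1, beta0 = -2,
                                           seed = 400))
    fs <- incremental_significance_scan(co)$first_sustained
    if (is.na(fs)) 99 else fs
  }, numeric(1))
  expect_true(all(diff(firsts) <= 0))
})
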