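test_that("AUC equals Mann-Whitney concordance, with ties counted 1/2", {
  d <- tibble::tibble(s = c(1, 2, 3, 4), y = c(0, 0, 1, 1))
  expect_equal(glance(roc_with_ci(d, s, y))$auc, 1)
  d2 <- tibble::tibble(s = rep(2, 6), y = c(0, 1, 0, 1, 0, 1))
  expect_equal(glance(roc_with_ci(d2, s, y))$auc, 0.5)
  d3 <- tibble::tibble(s = c(10, 20, 15, 30, 5), y = c(0, 1, 0, 1, 0))
  expect_equal(glance(roc_with_ci(d3, s, y))$auc, oracle_auc(d3$s, d3$y))
})

test_that("AUC matches the exhaustive pair-counting oracle on random cohorts", {
  set.seed(88)
  for (i in 1:25) {
    n <- sample(10:200, 1)
    s <- round(rlnorm(n, 2, 1), 1)          # ties likely after rounding
    y <- runif(n) < plogis(-1 + 0.2 * s)
    if (all(y) || !any(y)) next
    d <- tibble::tibble(s = s, y = y)
    expect_equal(glance(roc_with_ci(d, s, y))$auc, oracle_auc(s, y))
  }
})

test_that("label flip maps AUC to 1 - AUC and swaps CI bounds", {
  co <- generate_cohort(synthetic_params(n = 800, seed = 12))
  a <- glance(roc_with_ci(co, fit_value, urgent))
  co$flipped <- !co$urgent
  b <- glance(roc_with_ci(co, fit_value, flipped))
  expect_equal(b$auc, 1 - a$auc)
  expect_equal(b$ci_low, 1 - a$ci_high)
  expect_equal(b$ci_high, 1 - a$ci_low)
})

test_that("ROC curve is a valid staircase from (0,0) to (1,1)", {
  co <- generate_cohort(synthetic_params(n = 500, seed = 3))
  cv <- tidy(roc_with_ci(co, fit_value, urgent))
  expect_equal(c(cv$fpr[1], cv$tpr[1]), c(0, 0))
  expect_equal(c(cv$fpr[nrow(cv)], cv$tpr[nrow(cv)]), c(1, 1))
  expect_true(all(diff(cv$fpr) >= 0))
  expect_true(all(diff(cv$tpr) >= 0))
})

test_that("single-class outcomes are rejected", {
  d <- tibble::tibble(s = 1:5, y = rep(TRUE, 5))
  expect_error(roc_with_ci(d, s, y), "single class")
})

test_that("DeLong CI width shrinks roughly as 1/sqrt(n)", {
  widths <- vapply(c(200, 800, 3200), function(n) {
    co <- generate_cohort(synthetic_params(n = n, seed = 101))
    g <- glance(roc_with_ci(co, fit_value, urgent))
    g$ci_high - g$ci_low
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("bootstrap CI agrees with DeLong to first order", {
  co <- generate_cohort(synthetic_params(n = 600, seed = 55))
  set.seed(1)
  bo <- glance(roc_with_ci(co, fit_value, urgent, method = "bootstrap",
                           boot_reps = 500))
  de <- glance(roc_with_ci(co, fit_value, urgent))
  expect_equal(bo$auc, de$auc)                 # point estimate identical
  expect_lt(abs(bo$ci_low - de$ci_low), 0.03)
  expect_lt(abs(bo$ci_high - de$ci_high), 0.03)
})

test_that("single binary predictor recovers the 2x2 cross-product OR", {
  d <- tibble::tibble(
    exposed = rep(c(1, 0), c(100, 100)),
    y = c(rep(c(1, 0), c(10, 90)), rep(c(1, 0), c(5, 95)))
  )
  fit <- fit_logistic(d, "y", "exposed")
  or <- tidy(fit)$odds_ratio[tidy(fit)$term == "exposed"]
  expect_equal(or, (10 * 95) / (90 * 5), tolerance = 1e-6)
  # property: random non-degenerate 2x2 tables, 6 significant figures
  set.seed(14)
  for (i in 1:10) {
    cells <- sample(3:60, 4, replace = TRUE)  # a,b exposed; c,d unexposed
    d2 <- tibble::tibble(
      x = rep(c(1, 0), c(cells[1] + cells[2], cells[3] + cells[4])),
      y = c(rep(c(1, 0), cells[1:2]), rep(c(1, 0), cells[3:4]))
    )
    or2 <- tidy(fit_logistic(d2, "y", "x"))
    or2 <- or2$odds_ratio[or2$term == "x"]
    expect_equal(or2, (cells[1] * cells[4]) / (cells[2] * cells[3]),
                 tolerance = 1e-6)
  }
})

test_that("degenerate logistic inputs fail loudly", {
  d <- tibble::tibble(x = rep(1, 20), y = rep(c(0, 1), 10))
  expect_error(fit_logistic(d, "y", "x"), "zero variance")
  d2 <- tibble::tibble(x = rnorm(20), y = rep(0, 20))
  expect_error(fit_logistic(d2, "y", "x"), "single class")
  # complete separation: explicit diagnostic, not silent divergence
  d3 <- tibble::tibble(x = c(1:10, 21:30), y = rep(c(0, 1), each = 10))
  expect_warning(fit <- fit_logistic(d3, "y", "x"), "separation")
  expect_true(fit$separation)
})

test_that("paired DeLong comparison behaves on the analytic cases", {
  co <- generate_cohort(synthetic_params(n = 400, seed = 21))
  co$same <- co$fit_value
  r <- compare_auc_paired(co, fit_value, same, urgent)
  expect_equal(r$delta_auc, 0)
  expect_equal(r$p_value, 1)
  # rank-preserving transform leaves AUC unchanged
  co$logfit <- log(co$fit_value)
  r2 <- compare_auc_paired(co, fit_value, logfit, urgent)
  expect_equal(r2$delta_auc, 0)
  # crafted small set: delta matches brute-force pair counting
  d <- tibble::tibble(a = c(1, 2, 3, 4, 5, 6),
                      b = c(6, 5, 1, 3, 2, 4),
                      y = c(0, 0, 0, 1, 1, 1))
  r3 <- compare_auc_paired(d, a, b, y)
  expect_equal(r3$delta_auc, oracle_auc(d$b, d$y) - oracle_auc(d$a, d$y))
})

test_that("adjusted ROC equals raw-FIT ROC for the FIT-only model", {
  co <- generate_cohort(synthetic_params(n = 800, seed = 33))
  adj <- adjusted_roc(co, covariates = "fit_value")
  raw <- roc_with_ci(co, fit_value, urgent)
  expect_equal(adj$auc, raw$auc)          # monotone transform invariance
  expect_true(isTRUE(attr(adj, "apparent")))
})

test_that("an informative covariate lifts the adjusted AUC when FIT is noise", {
  # urgent depends on haemoglobin only; FIT carries no signal
  set.seed(61)
  n <- 20000
  hb <- rnorm(n, 112, 19)
  co <- tibble::tibble(
    fit_value = rlnorm(n, log(16), 2.4),
    haemoglobin_g_l = hb,
    age = rnorm(n, 65, 14),
    sex = sample(c("M", "F"), n, TRUE),
    urgent = runif(n) < plogis(-0.5 - 0.08 * (hb - 112))
  )
  adj <- adjusted_roc(co)
  raw <- roc_with_ci(co, fit_value, urgent)
  expect_gt(adj$auc, raw$auc + 0.1)
})
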