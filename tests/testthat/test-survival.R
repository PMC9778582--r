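test_that("product-limit estimates match hand traces", {
  cu <- km_estimate(c(2, 3), c(1, 1))
  expect_equal(cu$survival, c(0.5, 0))

  cu <- km_estimate(c(1, 2, 3), c(0, 1, 1))
  expect_equal(cu$time, c(1, 2, 3))
  expect_equal(cu$survival, c(1, 0.5, 0))
  expect_equal(cu$n_risk, c(3, 2, 1))
})

test_that("without censoring the curve is one minus the empirical CDF", {
  set.seed(12)
  tm <- rexp(80, 1 / 50)
  cu <- km_estimate(tm, rep(1, 80))
  ec <- ecdf(tm)
  for (t in c(10, 30, 50, 100)) {
    expect_equal(survival_at(cu, t)$estimate, 1 - ec(t))
  }
})

test_that("ties put events before censorings at the same time", {
  cu <- km_estimate(c(5, 5, 5, 8), c(1, 0, 1, 1))
  # both events at t=5 see all 4 at risk: S(5) = (1 - 2/4) = 0.5
  expect_equal(cu$survival[cu$time == 5], 0.5)
})

test_that("step evaluation is right-continuous with paper-style percentages", {
  cu <- km_estimate(c(2, 3), c(1, 1))
  expect_equal(survival_at(cu, 0)$estimate, 1)
  expect_equal(survival_at(cu, 0)$pct, 100.0)
  expect_equal(survival_at(cu, 2.5)$pct, 50.0)
  expect_equal(survival_at(cu, 2)$estimate, 0.5)  # post-jump value at the event
  expect_true(survival_at(cu, 99)$beyond_last)
})

test_that("an all-censored sample gives S identically 1 and no median", {
  cu <- km_estimate(c(10, 20, 30), c(0, 0, 0))
  expect_true(all(cu$survival == 1))
  expect_true(is.na(km_median(cu)$median_days))
})

test_that("the median is the first time S reaches 0.5, or not reached", {
  # S drops 1 -> 0.4 at t = 100
  cu <- km_estimate(c(rep(100, 6), rep(200, 4)), c(rep(1, 6), rep(0, 4)))
  expect_equal(km_median(cu)$median_days, 100)
  # S plateaus at 0.6
  cu <- km_estimate(c(rep(50, 4), rep(300, 6)), c(rep(1, 4), rep(0, 6)))
  expect_true(is.na(km_median(cu)$median_days))
})

test_that("estimates, CIs, medians and log-rank match the survival package", {
  skip_if_not_installed("survival")
  set.seed(2024)
  for (i in 1:20) {
    n <- sample(10:60, 1)
    tm <- round(rexp(n, 1 / 120), 1)
    ev <- rbinom(n, 1, 0.75)
    if (sum(ev) == 0) ev[1] <- 1
    cu <- km_estimate(tm, ev)
    sf <- survival::survfit(survival::Surv(tm, ev) ~ 1, conf.type = "log-log")
    idx <- match(sf$time, cu$time)
    expect_equal(cu$survival[idx], sf$surv, tolerance = 1e-10)
    both <- is.finite(sf$lower) & !is.na(cu$ci_lower[idx])
    expect_equal(cu$ci_lower[idx][both], sf$lower[both], tolerance = 1e-10)
    expect_equal(cu$ci_upper[idx][both], sf$upper[both], tolerance = 1e-10)

    g <- sample(1:2, n, replace = TRUE)
    if (length(unique(g)) == 2) {
      lr <- logrank_test(tm, ev, g)
      sd <- survival::survdiff(survival::Surv(tm, ev) ~ g)
      expect_equal(lr$chi_square, sd$chisq, tolerance = 1e-10)
    }
  }
  # median and its Brookmeyer-Crowley-style CI against survfit's table
  set.seed(7)
  tm <- rexp(400, 1 / 120); ev <- rbinom(400, 1, 0.8)
  cu <- km_estimate(tm, ev)
  tab <- summary(survival::survfit(survival::Surv(tm, ev) ~ 1,
                                   conf.type = "log-log"))$table
  med <- km_median(cu)
  expect_equal(med$median_days, unname(tab["median"]))
  expect_equal(med$ci_lower, unname(tab["0.95LCL"]))
  expect_equal(med$ci_upper, unname(tab["0.95UCL"]))
})

test_that("exponential simulations recover the true median", {
  set.seed(99)
  tm <- pmin(rexp(2000, log(2) / 100), 365)
  ev <- as.integer(tm < 365)
  med <- km_median(km_estimate(tm, ev))
  expect_gt(med$median_days, 90)
  expect_lt(med$median_days, 110)
})

test_that("log-rank is exact on symmetric groups and errors on empty ones", {
  tm <- c(3, 5, 8, 3, 5, 8)
  ev <- c(1, 0, 1, 1, 0, 1)
  g <- rep(c("a", "b"), each = 3)
  lr <- logrank_test(tm, ev, g)
  expect_equal(lr$chi_square, 0)
  expect_equal(lr$p_value, 1)
  expect_equal(sum(lr$observed), sum(lr$expected))
  expect_error(logrank_test(tm, ev, factor(g, levels = c("a", "b", "c"))),
               "zero observations")
  expect_error(logrank_test(tm, ev, rep("a", 6)), "two groups")
})

test_that("log-rank is invariant to relabeling and monotone time transforms", {
  set.seed(3)
  tm <- rexp(120, 1 / 90); ev <- rbinom(120, 1, 0.8)
  g <- sample(c("x", "y", "z"), 120, replace = TRUE)
  a <- logrank_test(tm, ev, g)
  relab <- c(x = "3", y = "1", z = "2")[g]
  b <- logrank_test(tm, ev, relab)
  expect_equal(a$chi_square, b$chi_square)
  expect_equal(a$df, 2)
  d <- logrank_test(sqrt(tm), ev, g)
  expect_equal(a$chi_square, d$chi_square)
})

test_that("greenwood CIs cover the true survival close to nominal rate", {
  set.seed(500)
  true_s <- exp(-180 / 200)
  hits <- 0
  for (i in 1:500) {
    tm <- pmin(rexp(200, 1 / 200), 365)
    ev <- as.integer(tm < 365)
    sv <- survival_at(km_estimate(tm, ev), 180)
    if (!is.na(sv$ci_lower) && sv$ci_lower <= true_s && true_s <= sv$ci_upper)
      hits <- hits + 1
  }
  expect_gte(hits / 500, 0.92)
})

test_that("p-values print in the journal style", {
  expect_equal(format_p(0.0004), "<0.001")
  expect_equal(format_p(0.028), "0.028")
  expect_equal(format_p(0.95), "0.950")
})
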