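test_that("generation is deterministic given (config, seed)", {
  cfg <- sadd_like_config()
  a <- generate_trial(cfg, seed = 5)
  b <- generate_trial(cfg, seed = 5)
  expect_identical(a$observed$utilities, b$observed$utilities)
  expect_identical(a$observed$costs, b$observed$costs)
  c_ <- generate_trial(cfg, seed = 6)
  expect_false(identical(a$observed$utilities, c_$observed$utilities))
})

test_that("zero missingness probabilities leave the data complete", {
  cfg <- synthetic_config(n = c(30, 30),
    missingness = missingness_spec("MCAR", p_u = c(0, 0), p_c = c(0, 0)))
  s <- generate_trial(cfg, seed = 2)
  expect_identical(s$observed$utilities, s$complete$utilities)
  expect_identical(s$observed$costs, s$complete$costs)
  expect_false(anyNA(s$observed$utilities))
})

test_that("complete-data moments converge to the configuration", {
  cfg <- synthetic_config(n = c(50000, 50000))
  d <- generate_trial(cfg, seed = 3)$complete
  for (a in 0:1) {
    sel <- d$arm == a
    for (j in 1:3) {
      u <- d$utilities[sel, j]
      expect_lt(abs(mean(u) - cfg$utility_mean[a + 1, j]),
                3 * sd(u) / sqrt(length(u)))
      cst <- d$costs[sel, j]
      expect_lt(abs(mean(cst) - cfg$cost_mean[a + 1, j]),
                4 * sd(cst) / sqrt(length(cst)))
      # heavy lognormal tails: check dispersion on the log scale, where
      # the sample SD is well behaved
      m <- cfg$cost_mean[a + 1, j]
      s2 <- cfg$cost_sd[a + 1, j]
      sdlog_cfg <- sqrt(log(1 + (s2 / m)^2))
      expect_lt(abs(sd(log(cst)) / sdlog_cfg - 1), 0.02)
    }
  }
  # correlation structure of the utilities
  expect_lt(abs(cor(d$utilities[, 1], d$utilities[, 2]) - 0.5), 0.02)
})

test_that("missingness margins hit their calibrated targets", {
  cfg <- sadd_like_config(n = c(20000, 20000))
  d <- generate_trial(cfg, seed = 4)$observed
  mu <- colMeans(is.na(d$utilities))[2:3]
  mc <- colMeans(is.na(d$costs))[2:3]
  # intercepts are calibrated against a neutral N(0,1) score; with strong
  # outcome-dependent selection the last-observed score distribution shifts,
  # so realized late-time margins sit a few points below the nominal target
  expect_lt(max(abs(mu - c(0.32, 0.47))), 0.05)
  expect_lt(max(abs(mc - c(0.155, 0.26))), 0.05)
  expect_false(anyNA(d$utilities[, 1]))
  expect_false(anyNA(d$costs[, 1]))
})

test_that("the preset's completeness matches the targeted pattern mix", {
  comp <- vapply(1:10, function(s) {
    d <- generate_trial(sadd_like_config(), seed = s)$observed
    pt <- pattern_table(d)
    pt$n_total[pt$pattern == "------"] / n_participants(d)
  }, numeric(1))
  expect_lt(abs(mean(comp) - 0.46), 0.05)
  # utilities are more often missing than costs
  d <- generate_trial(sadd_like_config(), seed = 1)$observed
  expect_gt(sum(is.na(d$utilities)), sum(is.na(d$costs)))
})

test_that("MAR mechanism follows its logistic form in the previous outcome", {
  # tau = 0 so the conditional P(missing at time 2 | baseline utility) is
  # exactly logistic in the standardized baseline value
  cfg <- synthetic_config(n = c(40000, 40000),
    missingness = missingness_spec("MAR_prev_outcome",
                                   p_u = c(0.3, 0.3), p_c = c(0.1, 0.1),
                                   gamma_u = -1, gamma_c = 0, tau = 0))
  s <- generate_trial(cfg, seed = 7)
  u1 <- s$complete$utilities[, 1]
  miss2 <- is.na(s$observed$utilities[, 2])
  zbar <- (u1 - mean(cfg$utility_mean[, 1])) / mean(cfg$utility_sd[, 1])
  alpha <- cealmm:::logit_intercept_for_margin(0.3, 1)
  bins <- cut(zbar, breaks = quantile(zbar, seq(0, 1, 0.1)),
              include.lowest = TRUE)
  for (b in levels(bins)) {
    sel <- bins == b
    p_hat <- mean(miss2[sel])
    p_the <- mean(plogis(alpha - 1 * zbar[sel]))
    se <- sqrt(p_the * (1 - p_the) / sum(sel))
    expect_lt(abs(p_hat - p_the), 4 * se)
  }
})

test_that("non-monotone patterns occur (observed late, missing early)", {
  d <- generate_trial(sadd_like_config(n = c(500, 500)), seed = 8)$observed
  nonmono <- is.na(d$utilities[, 2]) & !is.na(d$utilities[, 3])
  expect_gt(sum(nonmono), 0L)
})

test_that("true estimands are the configured-mean functionals", {
  cfg <- synthetic_config(
    n = c(10, 10),
    utility_mean = rbind(c(0.68, 0.73, 0.73), c(0.68, 0.73, 0.73)),
    cost_mean = rbind(c(1200, 1300, 2700), c(1200, 1300, 2700)),
    cost_sd = matrix(1000, 2, 3))
  te <- true_estimands(cfg)
  expect_equal(te$qaly[["incremental"]], 0)
  expect_equal(te$total_cost[["incremental"]], 0)
  expect_equal(te$qaly[["control"]],
               0.125 * 0.68 + 0.375 * 0.73 + 0.25 * 0.73)
  expect_equal(te$qaly[["control"]], 0.54125)
  expect_equal(te$total_cost[["control"]], 4000)
})

test_that("invalid configurations are rejected", {
  expect_error(
    synthetic_config(cross_corr = 1.05, utility_corr = 0, cost_corr = 0),
    "positive definite")
  expect_error(
    synthetic_config(missingness = missingness_spec(
      "MCAR", p_u = c(0.9, 0.9), p_c = c(0.9, 0.9))),
    "below 5%")
})
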