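test_that("design has the documented column layout", {
  set.seed(2)
  d <- rand_missing_dataset(12, 3)
  dd5 <- build_design(mmrm_spec("utility"), d)
  expect_equal(dd5$coef_names,
               c("time1", "time2", "time3", "time2:trt", "time3:trt"))
  dd6 <- build_design(mmrm_spec("utility", constrain_baseline = FALSE), d)
  expect_equal(length(dd6$coef_names), 6L)
  expect_true("time1:trt" %in% dd6$coef_names)

  # J = 2 toy: three columns matching a hand-written indicator matrix
  d2 <- trial_dataset(1:4, c(0, 0, 1, 1),
                      matrix(c(0.7, 0.6, 0.5, 0.4, 0.8, 0.9, 0.6, 0.7), 4),
                      matrix(10, 4, 2), times = c(0, 0.5))
  dd2 <- build_design(mmrm_spec("utility"), d2)
  expect_equal(length(dd2$coef_names), 3L)
  beta <- c(0.1, 0.2, 0.3)
  M <- cealmm:::fitted_mean_matrix(beta, dd2)
  expect_equal(M, naive_mean_matrix(beta, d2$arm, 2), ignore_attr = TRUE)
})

test_that("single-observation likelihood contributions are exact", {
  # one participant, J = 2, fully observed, Sigma = I, zero residuals
  d <- trial_dataset(1:2, c(0, 1),
                     rbind(c(0.5, 0.5), c(0.5, 0.5)),
                     matrix(1, 2, 2), times = c(0, 0.5))
  spec <- mmrm_spec("utility", constrain_baseline = FALSE)
  beta <- c(0.5, 0.5, 0, 0)     # means match data exactly
  ll <- observed_loglik(d, spec, beta, diag(2))
  expect_equal(ll, 2 * -log(2 * pi), tolerance = 1e-12)

  # participant observed only at time 2: marginal univariate density equals
  # numerical marginalization of the bivariate density over the missing one
  Sigma <- matrix(c(0.09, 0.04, 0.04, 0.16), 2)
  d1 <- trial_dataset(1:3, c(1, 0, 1),
                      rbind(c(NA, 0.9), c(0.6, 0.7), c(0.55, 0.65)),
                      matrix(1, 3, 2), times = c(0, 0.5))
  beta <- c(0.55, 0.6, 0.05, 0.1)
  ll_all <- observed_loglik(d1, spec, beta, Sigma)
  # participants 2 and 3 fully observed: subtract their dense contributions
  dense <- function(y, mu) {
    r <- y - mu
    -0.5 * (log(det(2 * pi * Sigma)) +
              as.numeric(t(r) %*% solve(Sigma) %*% r))
  }
  ll1 <- ll_all - dense(c(0.6, 0.7), beta[1:2]) -
    dense(c(0.55, 0.65), beta[1:2] + beta[3:4])
  # participant 1 is in arm 1: their means fold in the interaction terms
  beta <- c(beta[1] + beta[3], beta[2] + beta[4], 0, 0)
  dens_biv <- function(u1) {
    r <- rbind(u1 - beta[1], 0.9 - beta[2])
    apply(r, 2, function(x) {
      exp(-0.5 * (log(det(2 * pi * Sigma)) +
                    as.numeric(t(x) %*% solve(Sigma) %*% x)))
    })
  }
  marg <- integrate(dens_biv, -10, 10, rel.tol = 1e-12)$value
  expect_equal(ll1, log(marg), tolerance = 1e-8)
  expect_equal(ll1, dnorm(0.9, beta[2], sqrt(Sigma[2, 2]), log = TRUE),
               tolerance = 1e-12)
})

test_that("observed-data likelihood matches the dense brute-force oracle", {
  set.seed(99)
  for (rep in 1:10) {
    d <- rand_missing_dataset(n = 10, J = 3)
    spec <- mmrm_spec("utility")
    beta <- rnorm(5, c(0.7, 0.7, 0.7, 0, 0), 0.2)
    Sigma <- rand_pd(3) * 0.05
    dd <- build_design(spec, d)
    M <- naive_mean_matrix(beta, dd$arm, 3)
    expect_equal(observed_loglik(d, spec, beta, Sigma),
                 naive_obs_loglik(dd$Y, M, Sigma), tolerance = 1e-10)
  }
})

test_that("saturated fit on complete data recovers cell means exactly", {
  cfg <- synthetic_config(n = c(40, 40))
  d <- generate_trial(cfg, seed = 5)$complete
  f <- fit_mmrm(d, mmrm_spec("utility", constrain_baseline = FALSE,
                             reml = FALSE))
  expect_true(f$converged)
  cm0 <- colMeans(d$utilities[d$arm == 0, ])
  cm1 <- colMeans(d$utilities[d$arm == 1, ])
  expect_equal(unname(f$beta[1:3]), unname(cm0), tolerance = 1e-6)
  expect_equal(unname(f$beta[1:3] + f$beta[4:6]), unname(cm1),
               tolerance = 1e-6)
})

test_that("fit agrees with nlme::gls on incomplete data (ML and REML)", {
  skip_if_not_installed("nlme")
  cfg <- synthetic_config(n = c(60, 60),
    missingness = missingness_spec("MCAR", p_u = c(0.2, 0.3),
                                   p_c = c(0.1, 0.2)))
  d <- generate_trial(cfg, seed = 9)$observed
  n <- n_participants(d)
  long <- data.frame(id = rep(seq_len(n), each = 3),
                     arm = rep(d$arm, each = 3),
                     time = factor(rep(1:3, n)),
                     u = as.vector(t(d$utilities)))
  long <- long[!is.na(long$u), ]
  long$trt2 <- as.integer(long$time == 2 & long$arm == 1)
  long$trt3 <- as.integer(long$time == 3 & long$arm == 1)
  for (reml in c(FALSE, TRUE)) {
    g <- nlme::gls(u ~ 0 + time + trt2 + trt3, data = long,
                   correlation = nlme::corSymm(form = ~ as.integer(time) | id),
                   weights = nlme::varIdent(form = ~ 1 | time),
                   method = if (reml) "REML" else "ML")
    f <- fit_mmrm(d, mmrm_spec("utility", reml = reml))
    expect_equal(unname(f$beta), unname(coef(g)), tolerance = 1e-5)
    if (reml) {
      # (nlme rescales the ML covariance by n/(n - p); REML is comparable)
      expect_equal(unname(sqrt(diag(f$vcov_beta))),
                   unname(sqrt(diag(vcov(g)))), tolerance = 1e-4)
    } else {
      expect_equal(f$loglik, as.numeric(logLik(g)), tolerance = 1e-6)
    }
  }
})

test_that("parameters are recovered from MAR data at moderate n", {
  cfg <- sadd_like_config(n = c(1000, 1000))
  d <- generate_trial(cfg, seed = 77)$observed
  f <- suppressMessages(fit_mmrm(d, mmrm_spec("utility")))
  expect_true(f$converged)
  # follow-up arm differences vs generating truth, within 3 Wald SEs
  truth <- cfg$utility_mean[2, 2:3] - cfg$utility_mean[1, 2:3]
  est <- f$beta[c("time2:trt", "time3:trt")]
  se <- sqrt(diag(f$vcov_beta))[c("time2:trt", "time3:trt")]
  expect_true(all(abs(est - truth) < 3 * se))
})

test_that("compound symmetry recovers a random-intercept covariance", {
  # data generated with between-person variance 0.04 and residual 0.01:
  # implied marginal covariance has 0.05 on the diagonal, 0.04 off it
  set.seed(11)
  n <- 1500
  omega <- rnorm(n, 0, sqrt(0.04))
  U <- 0.7 + outer(omega, rep(1, 3)) + matrix(rnorm(n * 3, 0, 0.1), n, 3)
  d <- trial_dataset(1:n, rep(0:1, length.out = n), U,
                     matrix(1, n, 3), times = c(0, 0.25, 0.75))
  f <- fit_mmrm(d, mmrm_spec("utility", covariance = "cs"))
  expect_true(f$converged)
  expect_lt(abs(mean(diag(f$Sigma)) - 0.05), 0.005)
  expect_lt(abs(f$Sigma[1, 2] - 0.04), 0.005)
  expect_equal(f$Sigma[1, 2], f$Sigma[2, 3], tolerance = 1e-8)

  # nested families: unstructured ML likelihood >= compound symmetry's
  set.seed(12)
  dm <- rand_missing_dataset(40, 3)
  f_un <- fit_mmrm(dm, mmrm_spec("utility", reml = FALSE))
  f_cs <- fit_mmrm(dm, mmrm_spec("utility", covariance = "cs", reml = FALSE))
  expect_gte(f_un$loglik, f_cs$loglik - 1e-6)
})

test_that("fit is invariant to participant order and id labels", {
  set.seed(21)
  d <- rand_missing_dataset(30, 3)
  f1 <- fit_mmrm(d, mmrm_spec("utility"))
  perm <- sample(n_participants(d))
  d2 <- trial_dataset(paste0("z", seq_along(perm)), d$arm[perm],
                      d$utilities[perm, ], d$costs[perm, ], d$times)
  f2 <- fit_mmrm(d2, mmrm_spec("utility"))
  expect_equal(f1$beta, f2$beta, tolerance = 1e-7)
  expect_equal(f1$Sigma, f2$Sigma, tolerance = 1e-6)
})

test_that("marginal means combine coefficients and covariance correctly", {
  V <- diag(c(4, 1, 1, 2, 3)) * 1e-4
  V[2, 4] <- V[4, 2] <- 5e-5
  f <- mock_fit(beta = c(0.7, 0.73, 0.72, 0.02, 0.05), vcov = V)
  mm <- marginal_means(f)
  i2 <- mm[mm$time == 0.25 & mm$arm == "intervention", ]
  expect_equal(i2$estimate, 0.73 + 0.02)
  # CI half-width equals 1.96 * sqrt(c' V c) for the explicit contrast
  cvec <- c(0, 1, 0, 1, 0)
  hw <- qnorm(0.975) * sqrt(as.numeric(cvec %*% V %*% cvec))
  expect_equal(i2$upper - i2$estimate, hw, tolerance = 1e-10)

  # zero interactions: arms coincide
  f0 <- mock_fit(beta = c(0.7, 0.73, 0.72, 0, 0))
  mm0 <- marginal_means(f0)
  expect_equal(mm0$estimate[mm0$arm == "difference"], c(0, 0))
})

test_that("participants with no observations are dropped with a message", {
  d <- trial_dataset(1:5, c(0, 0, 1, 1, 1),
                     rbind(c(0.7, 0.8, 0.6), c(NA, NA, NA),
                           c(0.5, 0.6, 0.7), c(0.6, 0.5, 0.4),
                           c(0.7, 0.7, 0.7)),
                     matrix(10, 5, 3), times = c(0, 0.25, 0.75))
  expect_message(dd <- build_design(mmrm_spec("utility"), d), "dropped")
  expect_equal(dd$n_used, 4L)
  expect_equal(dd$n_dropped, 1L)
})
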