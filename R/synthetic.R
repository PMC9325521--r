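#' Missingness mechanism specification for synthetic trials
#'
#' Post-baseline outcome entries go missing according to a logistic model on
#' a participant-level latent frailty and (optionally) a standardized
#' outcome value:
#' \deqn{logit P(M_{bj} = 1) = \alpha_{bj} + \gamma_b z + \tau u_i,}
#' where `b` indexes the block (utility or cost), `j >= 2` the time,
#' `u_i ~ N(0, 1)` is shared across all of a participant's indicators
#' (inducing the clustering of missingness within participants seen in real
#' pattern tables), and `z` is the normal score of an outcome value:
#' the most recent *observed* earlier outcome of the same block for
#' `MAR_prev_outcome`, the current (possibly unobserved) outcome for
#' `MNAR_current`, and absent for `MCAR`. Baseline (time 1) is always fully
#' observed.
#'
#' The intercepts `alpha_bj` are not supplied directly: you state the target
#' marginal missingness probabilities `p_u`, `p_c` per follow-up time, and
#' the intercepts are solved for by integrating the logistic over the
#' `N(0, gamma^2 + tau^2)` latent load, so the realized margins match the
#' targets regardless of `gamma` and `tau`.
#'
#' @param mechanism One of `"MCAR"`, `"MAR_prev_outcome"`, `"MNAR_current"`.
#' @param p_u,p_c Target marginal probabilities of a missing utility / cost
#'   at each follow-up time (length J - 1), each in \[0, 1).
#' @param gamma_u,gamma_c Logistic slopes on the standardized outcome
#'   (ignored for MCAR).
#' @param tau Standard deviation of the shared participant frailty.
#' @return A list of class `missingness_spec`.
#' @export
missingness_spec <- function(mechanism = c("MCAR", "MAR_prev_outcome",
                                           "MNAR_current"),
                             p_u, p_c, gamma_u = 0, gamma_c = 0, tau = 0) {
  mechanism <- match.arg(mechanism)
  stopifnot(length(p_u) == length(p_c),
            all(p_u >= 0 & p_u < 1), all(p_c >= 0 & p_c < 1),
            tau >= 0)
  if (mechanism == "MCAR") gamma_u <- gamma_c <- 0
  structure(list(mechanism = mechanism, p_u = p_u, p_c = p_c,
                 gamma_u = gamma_u, gamma_c = gamma_c, tau = tau),
            class = "missingness_spec")
}

# Solve alpha such that E[plogis(alpha + s*X)] = p for X ~ N(0,1).
logit_intercept_for_margin <- function(p, s) {
  if (p <= 0) return(-Inf)
  if (s < 1e-12) return(stats::qlogis(p))
  marg <- function(a) {
    stats::integrate(function(x) stats::plogis(a + s * x) * stats::dnorm(x),
                     -Inf, Inf, rel.tol = 1e-10)$value - p
  }
  stats::uniroot(marg, c(-40, 40), tol = 1e-10)$root
}

#' Configuration for a synthetic two-arm cost-utility trial
#'
#' Defines the generating model used by [generate_trial()]: multivariate
#' normal utilities, marginally skewed costs linked through a Gaussian
#' copula, and a missingness mechanism ([missingness_spec()]). Rows of the
#' mean/sd matrices are arms (control, intervention); columns are time
#' points.
#'
#' @param n Length-2 integer vector: participants per arm
#'   (control, intervention).
#' @param times Measurement times in years, starting at 0.
#' @param utility_mean,utility_sd 2 x J matrices (or length-J vectors,
#'   recycled to both arms) of utility means and SDs.
#' @param cost_mean,cost_sd 2 x J matrices (or vectors) of cost means/SDs.
#' @param cost_dist Marginal cost family: `"lognormal"` (default, matching
#'   the heavy right skew of trial cost data), `"gamma"`, or `"normal"`.
#' @param utility_corr Exchangeable correlation of utilities across times.
#' @param cost_corr Exchangeable correlation of (latent) costs across times.
#' @param cross_corr Same-time latent correlation between utility and cost.
#' @param utility_range Optional length-2 truncation range for utilities
#'   (default `NULL`, no truncation).
#' @param missingness A [missingness_spec()]; default MCAR with 20% missing
#'   per follow-up entry.
#' @param seed Default seed used by [generate_trial()] when none is given.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n = c(100L, 100L),
                             times = c(0, 0.25, 0.75),
                             utility_mean = rbind(c(0.68, 0.73, 0.73),
                                                  c(0.68, 0.76, 0.83)),
                             utility_sd = rbind(c(0.28, 0.28, 0.24),
                                                c(0.28, 0.28, 0.24)),
                             cost_mean = rbind(c(1355, 1437, 2146),
                                               c(1355, 1130, 2550)),
                             cost_sd = rbind(c(2748, 3338, 4401),
                                             c(2748, 1868, 4288)),
                             cost_dist = c("lognormal", "gamma", "normal"),
                             utility_corr = 0.5,
                             cost_corr = 0.4,
                             cross_corr = -0.2,
                             utility_range = NULL,
                             missingness = missingness_spec(
                               "MCAR", p_u = rep(0.2, length(times) - 1),
                               p_c = rep(0.2, length(times) - 1)),
                             seed = 1L) {
  cost_dist <- match.arg(cost_dist)
  J <- length(times)
  as_2J <- function(x, nm) {
    x <- if (is.matrix(x)) x else matrix(x, 2, J, byrow = TRUE)
    if (!all(dim(x) == c(2, J))) stop(nm, " must be 2 x J")
    x
  }
  utility_mean <- as_2J(utility_mean, "utility_mean")
  utility_sd <- as_2J(utility_sd, "utility_sd")
  cost_mean <- as_2J(cost_mean, "cost_mean")
  cost_sd <- as_2J(cost_sd, "cost_sd")
  stopifnot(length(n) == 2L, all(n >= 2), times[1] == 0,
            all(diff(times) > 0),
            all(utility_sd > 0), all(cost_sd > 0), all(cost_mean > 0),
            inherits(missingness, "missingness_spec"),
            length(missingness$p_u) == J - 1L)

  # latent copula correlation over (u_1..u_J, c_1..c_J)
  exch <- function(r) (1 - r) * diag(J) + r * matrix(1, J, J)
  R <- rbind(cbind(exch(utility_corr), cross_corr * diag(J)),
             cbind(cross_corr * diag(J), exch(cost_corr)))
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10) {
    stop("copula correlation matrix is not positive definite; reduce ",
         "utility_corr/cost_corr/cross_corr")
  }

  # expected share of fully observed participants must be workable
  exp_complete <- prod(1 - missingness$p_u) * prod(1 - missingness$p_c)
  if (exp_complete < 0.05) {
    stop("missingness targets imply expected completeness below 5%")
  }

  structure(
    list(n = as.integer(n), times = times, J = J,
         utility_mean = utility_mean, utility_sd = utility_sd,
         cost_mean = cost_mean, cost_sd = cost_sd, cost_dist = cost_dist,
         utility_corr = utility_corr, cost_corr = cost_corr,
         cross_corr = cross_corr, utility_range = utility_range,
         copula_corr = R, missingness = missingness, seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

# cost marginal quantile transform for latent normal scores z, and its
# inverse normal-score transform for observed cost values
cost_from_z <- function(z, m, s, dist) {
  switch(dist,
    lognormal = {
      sdlog <- sqrt(log(1 + (s / m)^2))
      meanlog <- log(m) - sdlog^2 / 2
      exp(meanlog + sdlog * z)
    },
    gamma = {
      shape <- (m / s)^2
      stats::qgamma(stats::pnorm(z), shape = shape, rate = shape / m)
    },
    normal = m + s * z
  )
}

cost_to_z <- function(x, m, s, dist) {
  switch(dist,
    lognormal = {
      sdlog <- sqrt(log(1 + (s / m)^2))
      meanlog <- log(m) - sdlog^2 / 2
      (log(pmax(x, 1e-300)) - meanlog) / sdlog
    },
    gamma = {
      shape <- (m / s)^2
      stats::qnorm(pmin(pmax(
        stats::pgamma(x, shape = shape, rate = shape / m), 1e-12), 1 - 1e-12))
    },
    normal = (x - m) / s
  )
}

#' Generate a synthetic two-arm cost-utility trial
#'
#' Draws a complete dataset from the configured copula model, then applies
#' the configured missingness mechanism to produce the observed (incomplete)
#' dataset. Each post-baseline indicator is drawn separately, so
#' non-monotone patterns (e.g. observed at the last time but missing at an
#' earlier one) arise naturally.
#'
#' @param config A [synthetic_config()].
#' @param seed Integer seed (default `config$seed`). Identical
#'   (config, seed) give bit-identical output.
#' @return A list with `complete` and `observed` [trial_dataset()]s sharing
#'   ids and arms, and `truth`: the configured generating parameters plus
#'   the true estimands from [true_estimands()].
#' @export
generate_trial <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(seed)
  J <- config$J
  n <- sum(config$n)
  arm <- rep(c(0L, 1L), config$n)

  # latent normal scores via Cholesky of the copula correlation
  L <- chol(config$copula_corr)
  Z <- matrix(stats::rnorm(n * 2 * J), n, 2 * J) %*% L
  Zu <- Z[, seq_len(J), drop = FALSE]
  Zc <- Z[, J + seq_len(J), drop = FALSE]

  U <- matrix(NA_real_, n, J)
  C <- matrix(NA_real_, n, J)
  for (a in 0:1) {
    sel <- arm == a
    for (j in seq_len(J)) {
      U[sel, j] <- config$utility_mean[a + 1, j] +
        config$utility_sd[a + 1, j] * Zu[sel, j]
      C[sel, j] <- cost_from_z(Zc[sel, j], config$cost_mean[a + 1, j],
                               config$cost_sd[a + 1, j], config$cost_dist)
    }
  }
  if (!is.null(config$utility_range)) {
    U <- pmin(pmax(U, config$utility_range[1]), config$utility_range[2])
  }
  if (config$cost_dist == "normal") C <- pmax(C, 0)

  ms <- config$missingness
  s_load <- sqrt(ms$tau^2 +
                   c(u = ms$gamma_u, c = ms$gamma_c)^2 *
                   (ms$mechanism != "MCAR"))
  alpha_u <- vapply(ms$p_u, logit_intercept_for_margin, numeric(1),
                    s = s_load[["u"]])
  alpha_c <- vapply(ms$p_c, logit_intercept_for_margin, numeric(1),
                    s = s_load[["c"]])

  # standardized outcome values driving the outcome-dependent mechanisms.
  # The reference moments pool the two arms: dropout responds to the
  # participant's absolute outcome level, not their arm-relative rank, so
  # arms whose outcome distributions differ are selected differently (the
  # way outcome-dependent missingness biases complete-case contrasts).
  zu <- matrix(0, n, J)
  zc <- matrix(0, n, J)
  for (j in seq_len(J)) {
    zu[, j] <- (U[, j] - mean(config$utility_mean[, j])) /
      mean(config$utility_sd[, j])
    zc[, j] <- cost_to_z(C[, j], mean(config$cost_mean[, j]),
                         mean(config$cost_sd[, j]), config$cost_dist)
  }

  frailty <- stats::rnorm(n)
  Mu <- matrix(FALSE, n, J)
  Mc <- matrix(FALSE, n, J)
  last_obs_idx <- function(Mblock, j) {
    # per participant, most recent time before j with an observed value
    apply(Mblock[, seq_len(j - 1), drop = FALSE], 1L, function(m) {
      max(which(!m))
    })
  }
  for (j in 2:J) {
    zprev_u <- switch(ms$mechanism,
      MCAR = 0,
      MAR_prev_outcome = zu[cbind(seq_len(n), last_obs_idx(Mu, j))],
      MNAR_current = zu[, j])
    zprev_c <- switch(ms$mechanism,
      MCAR = 0,
      MAR_prev_outcome = zc[cbind(seq_len(n), last_obs_idx(Mc, j))],
      MNAR_current = zc[, j])
    pu <- stats::plogis(alpha_u[j - 1] + ms$gamma_u * zprev_u +
                          ms$tau * frailty)
    pc <- stats::plogis(alpha_c[j - 1] + ms$gamma_c * zprev_c +
                          ms$tau * frailty)
    if (ms$p_u[j - 1] > 0) Mu[, j] <- stats::runif(n) < pu
    if (ms$p_c[j - 1] > 0) Mc[, j] <- stats::runif(n) < pc
  }

  Uobs <- U
  Cobs <- C
  Uobs[Mu] <- NA_real_
  Cobs[Mc] <- NA_real_

  ids <- sprintf("p%03d", seq_len(n))
  complete <- trial_dataset(ids, arm, U, C, config$times)
  observed <- trial_dataset(ids, arm, Uobs, Cobs, config$times)
  list(complete = complete, observed = observed,
       truth = c(true_estimands(config), list(config = config, seed = seed)))
}

#' True estimands implied by a synthetic configuration
#'
#' The generating-model QALY per arm (trapezoidal AUC of the configured
#' utility means) and total cost per arm (sum of configured follow-up cost
#' means; baseline-period cost excluded), plus their incremental values.
#' Used as ground truth in parameter-recovery simulations.
#'
#' @param config A [synthetic_config()].
#' @return A list with `qaly` (named length-3: control, intervention,
#'   incremental) and `total_cost` (same layout).
#' @export
true_estimands <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  w <- auc_weights(config$times)
  q <- as.numeric(config$utility_mean %*% w)
  tc <- rowSums(config$cost_mean[, -1, drop = FALSE])
  list(
    qaly = c(control = q[1], intervention = q[2],
             incremental = q[2] - q[1]),
    total_cost = c(control = tc[1], intervention = tc[2],
                   incremental = tc[2] - tc[1])
  )
}

#' SADD-like synthetic trial preset
#'
#' A [synthetic_config()] emulating the structure of the motivating
#' antidepressants-in-dementia trial: two arms of 111 and 108 participants,
#' outcomes at 0, 3 and 9 months (0, 0.25, 0.75 years), utility means around
#' 0.67-0.83 with SDs 0.2-0.3, heavily right-skewed costs (SD larger than
#' the mean) around 1100-2600 currency units, a fully observed baseline, and
#' non-monotone missingness with marginal missingness of 32%/47% for
#' follow-up utilities and 15.5%/26% for follow-up costs — utilities more
#' often missing than costs, and roughly 46% of participants complete.
#' Missingness follows `MAR_prev_outcome`: lower previous utility and higher
#' previous cost (sicker participants) increase dropout, with a shared
#' frailty clustering missingness within participants.
#'
#' @param n Per-arm sample sizes (default `c(111, 108)`); scale up for
#'   simulation studies.
#' @param seed Default seed stored in the config.
#' @return A [synthetic_config()].
#' @export
sadd_like_config <- function(n = c(111L, 108L), seed = 1L) {
  synthetic_config(
    n = n,
    times = c(0, 0.25, 0.75),
    utility_mean = rbind(c(0.679, 0.733, 0.734),
                         c(0.679, 0.763, 0.827)),
    utility_sd = rbind(c(0.280, 0.277, 0.237),
                       c(0.280, 0.277, 0.237)),
    cost_mean = rbind(c(1355, 1437, 2146),
                      c(1355, 1130, 2550)),
    cost_sd = rbind(c(2748, 3338, 4401),
                    c(2748, 1868, 4288)),
    cost_dist = "lognormal",
    utility_corr = 0.5, cost_corr = 0.4, cross_corr = -0.2,
    missingness = missingness_spec(
      "MAR_prev_outcome",
      p_u = c(0.32, 0.47), p_c = c(0.155, 0.26),
      gamma_u = -4.0, gamma_c = 1.5, tau = 5.0),
    seed = seed
  )
}
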