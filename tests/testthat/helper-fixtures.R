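# Shared fixtures and independent oracles, all built in code.

# The nine observed/missing patterns of the motivating trial's missingness
# table (mask over U1 U2 U3 C1 C2 C3; "-" observed, "X" missing) with the
# published per-arm counts: 111 control, 108 intervention, 101 completers.
table1_patterns <- function() {
  data.frame(
    pattern = c("------", "-XX-XX", "-XX---", "--X---", "--X--X",
                "-X----", "-XX--X", "----XX", "-----X"),
    n_control = c(54L, 12L, 15L, 11L, 9L, 4L, 2L, 2L, 2L),
    n_intervention = c(47L, 17L, 14L, 13L, 8L, 4L, 2L, 3L, 0L),
    stringsAsFactors = FALSE
  )
}

# 219-row dataset realizing those patterns exactly (outcome values are
# arbitrary constants; only the missingness structure matters)
make_table1_dataset <- function() {
  pats <- table1_patterns()
  rows <- list()
  for (i in seq_len(nrow(pats))) {
    mask <- strsplit(pats$pattern[i], "")[[1]] == "X"
    for (a in 0:1) {
      cnt <- if (a == 0) pats$n_control[i] else pats$n_intervention[i]
      if (cnt == 0) next
      u <- rep(0.7, 3); u[mask[1:3]] <- NA
      co <- rep(1000, 3); co[mask[4:6]] <- NA
      rows[[length(rows) + 1L]] <- data.frame(
        arm = rep(a, cnt),
        u1 = u[1], u2 = u[2], u3 = u[3],
        c1 = co[1], c2 = co[2], c3 = co[3])
    }
  }
  df <- do.call(rbind, rows)
  trial_dataset(id = seq_len(nrow(df)), arm = df$arm,
                utilities = as.matrix(df[c("u1", "u2", "u3")]),
                costs = as.matrix(df[c("c1", "c2", "c3")]),
                times = c(0, 0.25, 0.75))
}

# independent dense-density log-likelihood oracle: per-participant loop with
# solve() and det() on the observed submatrix
naive_obs_loglik <- function(Y, mean_mat, Sigma) {
  ll <- 0
  for (i in seq_len(nrow(Y))) {
    o <- which(!is.na(Y[i, ]))
    r <- Y[i, o] - mean_mat[i, o]
    S <- Sigma[o, o, drop = FALSE]
    ll <- ll - 0.5 * (log(det(2 * pi * S)) +
                        as.numeric(t(r) %*% solve(S) %*% r))
  }
  ll
}

# mean matrix implied by the documented coefficient layout, built from
# hand-written indicators (independent of package internals)
naive_mean_matrix <- function(beta, arm, J, constrain_baseline = TRUE) {
  n_int <- if (constrain_baseline) J - 1L else J
  M <- matrix(NA_real_, length(arm), J)
  for (i in seq_along(arm)) {
    for (j in seq_len(J)) {
      mu <- beta[j]
      if (arm[i] == 1L) {
        if (!constrain_baseline) mu <- mu + beta[J + j]
        else if (j >= 2L) mu <- mu + beta[J + j - 1L]
      }
      M[i, j] <- mu
    }
  }
  M
}

# random positive-definite covariance
rand_pd <- function(J) {
  A <- matrix(stats::rnorm(J * J), J)
  crossprod(A) + diag(J) * 0.5
}

# small random dataset with non-monotone missingness; baseline kept
# observed and every arm-time cell left estimable
rand_missing_dataset <- function(n = 12, J = 3) {
  repeat {
    arm <- rep(0:1, length.out = n)
    U <- matrix(stats::rnorm(n * J, 0.7, 0.3), n, J)
    C <- matrix(stats::rlnorm(n * J, 7, 1), n, J)
    for (j in 2:J) {
      U[stats::runif(n) < 0.3, j] <- NA
      C[stats::runif(n) < 0.3, j] <- NA
    }
    ok <- TRUE
    for (j in 2:J) for (a in 0:1) {
      if (!any(!is.na(U[arm == a, j])) || !any(!is.na(C[arm == a, j]))) {
        ok <- FALSE
      }
    }
    if (ok) {
      return(trial_dataset(seq_len(n), arm, U, C,
                           times = seq(0, by = 0.25, length.out = J)))
    }
  }
}

# minimal mmrm_fit stand-in with known coefficients (for contrast tests)
mock_fit <- function(beta, vcov = NULL, times = c(0, 0.25, 0.75),
                     outcome = "utility", constrain_baseline = TRUE) {
  spec <- mmrm_spec(outcome, constrain_baseline = constrain_baseline)
  nm <- cealmm:::mmrm_coef_names(length(times), constrain_baseline,
                                 character())
  names(beta) <- nm
  V <- vcov %||% diag(0, length(beta))
  dimnames(V) <- list(nm, nm)
  structure(list(beta = beta, Sigma = diag(length(times)),
                 vcov_beta = V, loglik = 0, converged = TRUE,
                 n_used = 0L, n_dropped = 0L, spec = spec, times = times,
                 covariate_means = numeric(0)),
            class = "mmrm_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
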