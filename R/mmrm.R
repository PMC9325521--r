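#' Specify a mixed model for repeated measures (MMRM)
#'
#' Defines the model fitted by [fit_mmrm()]: a multivariate-normal model for
#' one outcome series (utility or cost) with a separate mean per time point,
#' time-by-arm interaction terms at follow-up, optional time-constant
#' baseline-covariate effects, and a residual covariance that is either
#' unstructured or compound symmetry (the structure implied by a random
#' intercept: equal variances, one common covariance).
#'
#' With `constrain_baseline = TRUE` (the default) no treatment term is
#' included at baseline, so the two arms share the baseline mean. Because
#' randomization guarantees no treatment effect at time 0, this both reflects
#' the design and adjusts the follow-up treatment contrasts for baseline
#' outcome imbalance (the constrained longitudinal data analysis, cLDA,
#' formulation).
#'
#' @param outcome `"utility"` or `"cost"`: which series of the dataset the
#'   model is for.
#' @param covariance `"un"` (unstructured) or `"cs"` (compound symmetry).
#' @param reml Logical; fit by REML (default) or maximum likelihood.
#' @param covariates Character vector of baseline covariate names (must be
#'   columns of the dataset's `covariates` data frame); their coefficients
#'   are constant over time.
#' @param constrain_baseline Logical; omit the treatment term at baseline.
#' @return An object of class `mmrm_spec`.
#' @export
mmrm_spec <- function(outcome = c("utility", "cost"),
                      covariance = c("un", "cs"),
                      reml = TRUE,
                      covariates = character(),
                      constrain_baseline = TRUE) {
  outcome <- match.arg(outcome)
  covariance <- match.arg(covariance)
  structure(
    list(outcome = outcome, covariance = covariance, reml = isTRUE(reml),
         covariates = as.character(covariates),
         constrain_baseline = isTRUE(constrain_baseline)),
    class = "mmrm_spec"
  )
}

#' @export
print.mmrm_spec <- function(x, ...) {
  cat("mmrm_spec: outcome =", x$outcome,
      "| covariance =", x$covariance,
      "| estimation =", if (x$reml) "REML" else "ML",
      "| constrained baseline =", x$constrain_baseline, "\n")
  if (length(x$covariates)) {
    cat("  covariates:", paste(x$covariates, collapse = ", "), "\n")
  }
  invisible(x)
}

# Coefficient names for the fixed-effect vector, in the fixed column order:
# time means ascending, then time-by-arm interactions ascending, then
# baseline covariates.
mmrm_coef_names <- function(J, constrain_baseline, covariates) {
  jj <- if (constrain_baseline) 2:J else 1:J
  c(paste0("time", 1:J), paste0("time", jj, ":trt"), covariates)
}

#' Build the MMRM design from a trial dataset
#'
#' Assembles the response matrix and design information used by the
#' observed-data likelihood. Participants whose outcome series is entirely
#' missing cannot contribute and are dropped (with a message).
#'
#' @param spec An [mmrm_spec()].
#' @param data A [trial_dataset()]. Covariates named in the spec must be
#'   fully observed (apply [mean_impute_baseline()] first).
#' @return A list with elements `Y` (n_used x J response matrix), `arm`,
#'   `Xc` (n_used x q covariate matrix), `coef_names`, `J`, `n_used`,
#'   `n_dropped`, and `patterns` (participants grouped by observed/missing
#'   mask).
#' @keywords internal
#' @export
build_design <- function(spec, data) {
  stopifnot(inherits(spec, "mmrm_spec"), inherits(data, "trial_dataset"))
  Y <- if (spec$outcome == "utility") data$utilities else data$costs
  J <- length(data$times)

  q <- length(spec$covariates)
  Xc <- matrix(0, nrow(Y), 0L)
  if (q) {
    if (is.null(data$covariates) ||
        !all(spec$covariates %in% names(data$covariates))) {
      stop("covariate(s) not present in dataset: ",
           paste(setdiff(spec$covariates, names(data$covariates)),
                 collapse = ", "))
    }
    Xc <- as.matrix(data$covariates[spec$covariates])
    storage.mode(Xc) <- "double"
    if (anyNA(Xc)) {
      stop("missing covariate values; run mean_impute_baseline() before ",
           "fitting")
    }
  }

  keep <- rowSums(!is.na(Y)) > 0L
  n_dropped <- sum(!keep)
  if (n_dropped) {
    message(n_dropped, " participant(s) with no observed ", spec$outcome,
            " values dropped from the ", spec$outcome, " model")
  }
  Y <- Y[keep, , drop = FALSE]
  arm <- data$arm[keep]
  Xc <- Xc[keep, , drop = FALSE]

  # every arm-time mean in the design must be estimable
  for (j in seq_len(J)) {
    obs_j <- !is.na(Y[, j])
    if (spec$constrain_baseline && j == 1L) {
      if (!any(obs_j)) stop("no observations at baseline")
    } else {
      for (a in 0:1) {
        if (!any(obs_j & arm == a)) {
          stop("no observed ", spec$outcome, " values at time index ", j,
               " in arm ", a, "; the arm-time mean is not estimable")
        }
      }
    }
  }

  key <- apply(!is.na(Y), 1L, function(m) paste(as.integer(m), collapse = ""))
  patterns <- lapply(split(seq_len(nrow(Y)), key), function(idx) {
    list(obs = which(!is.na(Y[idx[1], ])), idx = idx)
  })

  list(Y = Y, arm = arm, Xc = Xc,
       coef_names = mmrm_coef_names(J, spec$constrain_baseline,
                                    spec$covariates),
       J = J, n_used = nrow(Y), n_dropped = n_dropped,
       constrain_baseline = spec$constrain_baseline,
       patterns = patterns)
}

# Pattern basis matrices: X_i = B + arm_i * C + sum_k x_ik * D_k, where the
# rows correspond to the participant's observed time points and the columns
# to the full coefficient vector.
pattern_basis <- function(obs, J, constrain_baseline, q) {
  n_int <- if (constrain_baseline) J - 1L else J
  p <- J + n_int + q
  k <- length(obs)
  B <- matrix(0, k, p)
  B[cbind(seq_len(k), obs)] <- 1
  C <- matrix(0, k, p)
  for (r in seq_len(k)) {
    j <- obs[r]
    if (!constrain_baseline) {
      C[r, J + j] <- 1
    } else if (j >= 2L) {
      C[r, J + j - 1L] <- 1
    }
  }
  D <- if (q) lapply(seq_len(q), function(kk) {
    M <- matrix(0, k, p)
    M[, J + n_int + kk] <- 1
    M
  }) else list()
  list(B = B, C = C, D = D, p = p)
}

# Profiled generalized-least-squares pass for a fixed Sigma: accumulates
# X'WX, X'Wy and the transformed response sum-of-squares across missingness
# patterns (W = inverse of Sigma restricted to the observed coordinates).
mmrm_gls_pass <- function(Sigma, dd) {
  q <- ncol(dd$Xc)
  p <- dd$J + (if (dd$constrain_baseline) dd$J - 1L else dd$J) + q
  XtWX <- matrix(0, p, p)
  XtWy <- numeric(p)
  yty <- 0
  logdet <- 0
  n_obs <- 0L
  for (pt in dd$patterns) {
    obs <- pt$obs
    idx <- pt$idx
    nm <- length(idx)
    So <- Sigma[obs, obs, drop = FALSE]
    U <- tryCatch(chol(So), error = function(e) NULL)
    if (is.null(U)) return(NULL)
    logdet <- logdet + nm * 2 * sum(log(diag(U)))
    n_obs <- n_obs + nm * length(obs)

    bas <- pattern_basis(obs, dd$J, dd$constrain_baseline, q)
    Bt <- backsolve(U, bas$B, transpose = TRUE)
    Ct <- backsolve(U, bas$C, transpose = TRUE)
    Dt <- lapply(bas$D, function(M) backsolve(U, M, transpose = TRUE))

    a <- dd$arm[idx]
    Z <- backsolve(U, t(dd$Y[idx, obs, drop = FALSE]), transpose = TRUE)
    # Z is k x nm: column i holds the whitened response of participant i
    yty <- yty + sum(Z * Z)

    s_a <- sum(a)
    XtWX <- XtWX + nm * crossprod(Bt) +
      s_a * (crossprod(Bt, Ct) + crossprod(Ct, Bt)) +
      s_a * crossprod(Ct)          # a is 0/1 so sum(a^2) = sum(a)
    zsum <- rowSums(Z)
    za <- as.numeric(Z %*% a)
    XtWy <- XtWy + crossprod(Bt, zsum)[, 1] + crossprod(Ct, za)[, 1]
    if (q) {
      x <- dd$Xc[idx, , drop = FALSE]
      for (kk in seq_len(q)) {
        s_x <- sum(x[, kk])
        s_ax <- sum(a * x[, kk])
        XtWX <- XtWX +
          s_x * (crossprod(Bt, Dt[[kk]]) + crossprod(Dt[[kk]], Bt)) +
          s_ax * (crossprod(Ct, Dt[[kk]]) + crossprod(Dt[[kk]], Ct))
        for (ll in seq_len(q)) {
          XtWX <- XtWX + sum(x[, kk] * x[, ll]) *
            crossprod(Dt[[kk]], Dt[[ll]])
        }
        XtWy <- XtWy +
          crossprod(Dt[[kk]], as.numeric(Z %*% x[, kk]))[, 1]
      }
    }
  }
  list(XtWX = XtWX, XtWy = XtWy, yty = yty, logdet = logdet, n_obs = n_obs)
}

# Covariance parameterizations ------------------------------------------

# Unstructured: log-Cholesky. theta = (log diag of lower factor L,
# off-diagonal entries of L column-major); Sigma = L L'.
theta_to_sigma_un <- function(theta, J) {
  L <- diag(exp(theta[seq_len(J)]), J)
  L[lower.tri(L)] <- theta[-seq_len(J)]
  tcrossprod(L)
}

sigma_to_theta_un <- function(Sigma) {
  L <- t(chol(Sigma))
  c(log(diag(L)), L[lower.tri(L)])
}

# Compound symmetry: theta = (log total variance, logit of the intraclass
# correlation mapped onto its valid range (-1/(J-1), 1)).
cs_rho_bounds <- function(J) c(-1 / (J - 1) + 1e-6, 1 - 1e-6)
theta_to_sigma_cs <- function(theta, J) {
  b <- cs_rho_bounds(J)
  s2 <- exp(theta[1])
  rho <- b[1] + (b[2] - b[1]) * stats::plogis(theta[2])
  s2 * ((1 - rho) * diag(J) + rho * matrix(1, J, J))
}

sigma_to_theta_cs <- function(Sigma) {
  J <- nrow(Sigma)
  b <- cs_rho_bounds(J)
  s2 <- mean(diag(Sigma))
  rho <- mean(Sigma[lower.tri(Sigma)]) / s2
  rho <- min(max(rho, b[1] + 1e-4), b[2] - 1e-4)
  c(log(s2), stats::qlogis((rho - b[1]) / (b[2] - b[1])))
}

n_cov_par <- function(covariance, J) {
  if (covariance == "un") J * (J + 1L) / 2L else 2L
}

theta_to_sigma <- function(theta, covariance, J) {
  if (covariance == "un") theta_to_sigma_un(theta, J)
  else theta_to_sigma_cs(theta, J)
}

# Starting covariance: pairwise-complete sample covariance pooled within
# arm, floored to positive definiteness at 1e-6 of the trace.
start_sigma <- function(dd) {
  Yc <- dd$Y
  for (a in 0:1) {
    sel <- dd$arm == a
    Yc[sel, ] <- sweep(Yc[sel, , drop = FALSE], 2L,
                       colMeans(Yc[sel, , drop = FALSE], na.rm = TRUE))
  }
  S <- suppressWarnings(stats::cov(Yc, use = "pairwise.complete.obs"))
  S[is.na(S)] <- 0
  diag(S)[diag(S) <= 0] <- stats::var(as.numeric(Yc), na.rm = TRUE)
  e <- eigen(S, symmetric = TRUE)
  floor_val <- 1e-6 * sum(abs(e$values))
  e$values[e$values < floor_val] <- floor_val
  e$vectors %*% (e$values * t(e$vectors))
}

# -2 * profiled (restricted) log-likelihood at covariance parameters theta
mmrm_neg2ll <- function(theta, dd, covariance, reml) {
  Sigma <- theta_to_sigma(theta, covariance, dd$J)
  gp <- mmrm_gls_pass(Sigma, dd)
  if (is.null(gp)) return(1e10)
  ch <- tryCatch(chol(gp$XtWX), error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  beta <- backsolve(ch, backsolve(ch, gp$XtWy, transpose = TRUE))
  rss <- gp$yty - sum(beta * gp$XtWy)
  val <- gp$logdet + rss + gp$n_obs * log(2 * pi)
  if (reml) {
    p <- length(beta)
    val <- val + 2 * sum(log(diag(ch))) - p * log(2 * pi)
  }
  if (!is.finite(val)) return(1e10)
  val
}

#' Fit a mixed model for repeated measures by observed-data likelihood
#'
#' Maximizes the observed-data multivariate-normal (restricted) likelihood:
#' each participant contributes the marginal normal density of their observed
#' outcome subvector, with the corresponding rows of the design matrix and
#' submatrix of the residual covariance. No imputation of outcomes is
#' performed, and the resulting inference is valid when outcome missingness
#' is at random given the observed outcomes and the model covariates.
#'
#' The covariance is parameterized unconstrained (log-Cholesky for the
#' unstructured model) and optimized by quasi-Newton with the fixed effects
#' profiled out by generalized least squares; up to `restarts` jittered
#' restarts are attempted if the optimizer does not report convergence.
#'
#' @param data A [trial_dataset()].
#' @param spec An [mmrm_spec()].
#' @param start Optional starting covariance matrix (J x J).
#' @param restarts Maximum number of jittered restarts after a
#'   non-converged attempt.
#' @return An object of class `mmrm_fit` with elements `beta` (named
#'   fixed-effect estimates), `Sigma` (estimated residual covariance),
#'   `vcov_beta`, `loglik` (maximized objective; REML criterion when
#'   `spec$reml`), `converged`, `n_used`, `n_dropped`, `spec`, `times`, and
#'   `covariate_means` (observed means of the model covariates, the default
#'   profile for [marginal_means()]).
#' @examples
#' set.seed(1)
#' cfg <- synthetic_config(n = c(40, 40))
#' d <- generate_trial(cfg)$observed
#' fit <- fit_mmrm(d, mmrm_spec("utility"))
#' coef(fit)
#' @export
fit_mmrm <- function(data, spec, start = NULL, restarts = 3L) {
  dd <- build_design(spec, data)
  J <- dd$J

  # standardize the response internally so the covariance parameters are
  # well scaled for the optimizer (currency outcomes span ~1e3-1e4);
  # estimates are transformed back afterwards
  y_scale <- stats::sd(dd$Y, na.rm = TRUE)
  if (!is.finite(y_scale) || y_scale <= 0) y_scale <- 1
  dd$Y <- dd$Y / y_scale

  S0 <- if (is.null(start)) start_sigma(dd) else
    as.matrix(start) / y_scale^2
  theta0 <- if (spec$covariance == "un") sigma_to_theta_un(S0)
            else sigma_to_theta_cs(S0)

  best <- NULL
  attempt <- 0L
  theta_try <- theta0
  repeat {
    opt <- stats::optim(theta_try, mmrm_neg2ll, dd = dd,
                        covariance = spec$covariance, reml = spec$reml,
                        method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-12,
                                       ndeps = rep(1e-5, length(theta_try))))
    if (is.null(best) || opt$value < best$value) best <- opt
    if (best$convergence == 0 || attempt >= restarts) break
    attempt <- attempt + 1L
    theta_try <- theta0 + stats::rnorm(length(theta0), sd = 0.1)
  }
  converged <- best$convergence == 0 && is.finite(best$value) &&
    best$value < 1e10

  Sigma <- theta_to_sigma(best$par, spec$covariance, J)
  gp <- mmrm_gls_pass(Sigma, dd)
  ch <- chol(gp$XtWX)
  beta <- backsolve(ch, backsolve(ch, gp$XtWy, transpose = TRUE))
  vcov_beta <- chol2inv(ch)

  # undo the internal response standardization
  beta <- beta * y_scale
  vcov_beta <- vcov_beta * y_scale^2
  Sigma <- Sigma * y_scale^2
  loglik <- -best$value / 2 - gp$n_obs * log(y_scale)
  if (spec$reml) loglik <- loglik + length(beta) * log(y_scale)

  names(beta) <- dd$coef_names
  dimnames(vcov_beta) <- list(dd$coef_names, dd$coef_names)
  dimnames(Sigma) <- list(paste0("t", 1:J), paste0("t", 1:J))

  cov_means <- if (ncol(dd$Xc)) colMeans(dd$Xc) else numeric(0)
  names(cov_means) <- spec$covariates

  structure(
    list(beta = beta, Sigma = Sigma, vcov_beta = vcov_beta,
         loglik = loglik, converged = converged,
         n_used = dd$n_used, n_dropped = dd$n_dropped,
         spec = spec, times = data$times, covariate_means = cov_means,
         optim = list(value = best$value, counts = best$counts,
                      convergence = best$convergence,
                      restarts_used = attempt)),
    class = "mmrm_fit"
  )
}

#' @export
print.mmrm_fit <- function(x, ...) {
  cat("MMRM fit (", x$spec$outcome, ", ",
      if (x$spec$covariance == "un") "unstructured" else "compound symmetry",
      " covariance, ", if (x$spec$reml) "REML" else "ML", ")\n", sep = "")
  cat("  n used:", x$n_used,
      if (x$n_dropped) paste0("(", x$n_dropped, " dropped, all missing)"),
      "\n")
  cat("  log-likelihood:", format(x$loglik, digits = 7),
      if (!x$converged) " [NOT CONVERGED]", "\n")
  cat("  coefficients:\n")
  print(round(x$beta, 4))
  invisible(x)
}

#' @export
coef.mmrm_fit <- function(object, ...) object$beta

#' @export
vcov.mmrm_fit <- function(object, ...) object$vcov_beta

#' @export
logLik.mmrm_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$beta) +
              n_cov_par(object$spec$covariance, length(object$times)),
            class = "logLik")
}

#' Observed-data log-likelihood at given parameters
#'
#' Evaluates the sum over participants of the marginal multivariate-normal
#' log-density of each participant's observed outcome subvector, with mean
#' given by the fixed effects and covariance the matching submatrix of
#' `Sigma`. This is the objective (up to the REML adjustment) that
#' [fit_mmrm()] maximizes.
#'
#' @param data A [trial_dataset()].
#' @param spec An [mmrm_spec()].
#' @param beta Fixed-effect vector in the design's column order (time means,
#'   then time-by-arm interactions, then covariates).
#' @param Sigma J x J residual covariance matrix (positive definite).
#' @return The scalar log-likelihood.
#' @export
observed_loglik <- function(data, spec, beta, Sigma) {
  dd <- build_design(spec, data)
  M <- fitted_mean_matrix(beta, dd)
  ll <- 0
  for (pt in dd$patterns) {
    obs <- pt$obs
    idx <- pt$idx
    So <- Sigma[obs, obs, drop = FALSE]
    U <- chol(So)
    R <- dd$Y[idx, obs, drop = FALSE] - M[idx, obs, drop = FALSE]
    Z <- backsolve(U, t(R), transpose = TRUE)
    ll <- ll - 0.5 * (length(idx) *
                        (2 * sum(log(diag(U))) + length(obs) * log(2 * pi)) +
                        sum(Z * Z))
  }
  if (!is.finite(ll)) stop("non-finite log-likelihood: ill-conditioned Sigma")
  ll
}

# n x J matrix of fitted means implied by beta for each participant
fitted_mean_matrix <- function(beta, dd) {
  J <- dd$J
  n_int <- if (dd$constrain_baseline) J - 1L else J
  mu <- beta[seq_len(J)]
  delta <- numeric(J)
  if (dd$constrain_baseline) delta[2:J] <- beta[J + seq_len(n_int)]
  else delta <- beta[J + seq_len(n_int)]
  M <- matrix(mu, dd$n_used, J, byrow = TRUE) +
    outer(as.numeric(dd$arm), delta)
  q <- ncol(dd$Xc)
  if (q) {
    gamma <- beta[J + n_int + seq_len(q)]
    M <- M + as.numeric(dd$Xc %*% gamma)
  }
  M
}

# contrast vector picking the arm mean at time index j (arm in 0/1),
# evaluated at a covariate profile
arm_time_contrast <- function(fit, j, arm, covariate_profile = NULL) {
  J <- length(fit$times)
  cb <- fit$spec$constrain_baseline
  p <- length(fit$beta)
  cvec <- numeric(p)
  names(cvec) <- names(fit$beta)
  cvec[paste0("time", j)] <- 1
  if (arm == 1L && !(cb && j == 1L)) {
    cvec[paste0("time", j, ":trt")] <- 1
  }
  q <- length(fit$spec$covariates)
  if (q) {
    prof <- if (is.null(covariate_profile)) fit$covariate_means
            else covariate_profile[fit$spec$covariates]
    cvec[fit$spec$covariates] <- as.numeric(prof)
  }
  cvec
}

estimate_contrast <- function(fit, cvec, level = 0.95) {
  est <- sum(cvec * fit$beta)
  se <- sqrt(max(0, as.numeric(cvec %*% fit$vcov_beta %*% cvec)))
  z <- stats::qnorm(1 - (1 - level) / 2)
  c(estimate = est, se = se, lower = est - z * se, upper = est + z * se)
}

#' Model-based marginal means and arm differences by time
#'
#' Estimated per-arm outcome means at each follow-up time (and at baseline
#' when the baseline treatment term is present), with Wald 95% confidence
#' intervals from the fitted coefficient covariance, plus the
#' intervention-minus-control difference at each follow-up. Covariate terms
#' are evaluated at `covariate_profile` (default: observed covariate means).
#'
#' @param fit An [mmrm_fit][fit_mmrm()] object.
#' @param covariate_profile Optional named vector of covariate values.
#' @param level Confidence level (default 0.95).
#' @return A data frame with columns `time`, `arm` (`"control"`,
#'   `"intervention"`, `"difference"`), `estimate`, `se`, `lower`, `upper`.
#' @export
marginal_means <- function(fit, covariate_profile = NULL, level = 0.95) {
  stopifnot(inherits(fit, "mmrm_fit"))
  J <- length(fit$times)
  jj <- if (fit$spec$constrain_baseline) 2:J else 1:J
  rows <- list()
  for (j in jj) {
    c0 <- arm_time_contrast(fit, j, 0L, covariate_profile)
    c1 <- arm_time_contrast(fit, j, 1L, covariate_profile)
    for (piece in list(list("control", c0), list("intervention", c1),
                       list("difference", c1 - c0))) {
      est <- estimate_contrast(fit, piece[[2]], level)
      rows[[length(rows) + 1L]] <- data.frame(
        time = fit$times[j], arm = piece[[1]],
        estimate = est["estimate"], se = est["se"],
        lower = est["lower"], upper = est["upper"], row.names = NULL)
    }
  }
  do.call(rbind, rows)
}
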