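#' Single mean-imputation of baseline covariates
#'
#' Replaces missing baseline covariate values with the observed mean (for a
#' continuous covariate) or observed mode (for a binary 0/1 covariate),
#' pooled across arms by default — under randomization the arms'
#' baseline distributions are exchangeable, and pooled single imputation of
#' baseline covariates is valid and efficient. Outcome values are never
#' touched.
#'
#' @param data A [trial_dataset()].
#' @param covariates Covariate names to impute; default all.
#' @param pool Pool arms when computing the imputation value (default TRUE);
#'   otherwise impute within arm.
#' @return The dataset with imputed covariates; an attribute
#'   `imputation_log` records the number of values imputed per covariate.
#' @examples
#' d <- trial_dataset(id = 1:3, arm = c(0, 1, 1),
#'                    utilities = matrix(0.7, 3, 2),
#'                    costs = matrix(10, 3, 2), times = c(0, 0.5),
#'                    covariates = data.frame(age = c(1, 2, NA)))
#' mean_impute_baseline(d)$covariates$age
#' @export
mean_impute_baseline <- function(data, covariates = NULL, pool = TRUE) {
  stopifnot(inherits(data, "trial_dataset"))
  if (is.null(data$covariates)) return(data)
  covariates <- covariates %||% names(data$covariates)
  log <- stats::setNames(integer(length(covariates)), covariates)
  for (cn in covariates) {
    v <- data$covariates[[cn]]
    miss <- is.na(v)
    if (!any(miss)) next
    if (all(miss)) stop("covariate ", dQuote(cn), " has no observed values")
    impute_one <- function(obs) {
      if (all(obs %in% c(0, 1))) {
        # binary: observed mode, ties broken toward 0
        if (mean(obs) > 0.5) 1 else 0
      } else {
        mean(obs)
      }
    }
    if (pool) {
      v[miss] <- impute_one(v[!miss])
    } else {
      for (a in 0:1) {
        sel <- miss & data$arm == a
        if (any(sel)) {
          obs <- v[!is.na(data$covariates[[cn]]) & data$arm == a]
          if (!length(obs)) stop("covariate ", dQuote(cn),
                                 " has no observed values in arm ", a)
          v[sel] <- impute_one(obs)
        }
      }
    }
    data$covariates[[cn]] <- v
    log[cn] <- sum(miss)
  }
  attr(data, "imputation_log") <- log
  data
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Complete-case estimates of incremental QALYs and total costs
#'
#' The conventional complete-case analysis (CCA): restrict to participants
#' with fully observed utility and cost series, compute each completer's
#' QALY (trapezoidal AUC of their utilities) and total cost (sum of
#' follow-up costs), and estimate the arm difference of each by ordinary
#' linear regression on arm, the baseline value of the same outcome, and any
#' further baseline covariates. Baseline adjustment mirrors the MMRM's
#' constrained-baseline adjustment, so differences between CCA and MMRM
#' results isolate the handling of missing data.
#'
#' CCA is unbiased only when being a completer is independent of the
#' outcomes given the adjustment covariates; when missingness depends on
#' post-baseline outcomes it is generally biased, and it always discards the
#' partially observed participants (loss of efficiency).
#'
#' @param data A [trial_dataset()].
#' @param times Measurement times (default the dataset's).
#' @param covariates Additional baseline covariate names to adjust for.
#' @param level Confidence level.
#' @return A list with `qaly` and `total_cost`, each a list holding the
#'   per-arm completer means (`control`, `intervention`) and model-based
#'   `incremental` (estimate, se, lower, upper), plus `n_complete` per arm.
#' @export
cca_estimates <- function(data, times = data$times, covariates = character(),
                          level = 0.95) {
  cc <- complete_cases(data)
  if (length(covariates)) cc <- mean_impute_baseline(cc, covariates)
  w <- auc_weights(times)
  J <- length(times)
  qaly <- as.numeric(cc$utilities %*% w)
  total_cost <- rowSums(cc$costs[, -1, drop = FALSE])
  n0 <- sum(cc$arm == 0L)
  n1 <- sum(cc$arm == 1L)
  if (n0 < 2L || n1 < 2L) stop("fewer than two completers in an arm")

  fit_one <- function(y, baseline) {
    df <- data.frame(y = y, arm = cc$arm, base = baseline)
    if (length(covariates)) df <- cbind(df, cc$covariates[covariates])
    fm <- stats::lm(y ~ ., data = df)
    s <- summary(fm)$coefficients["arm", , drop = TRUE]
    z <- stats::qt(1 - (1 - level) / 2, df = fm$df.residual)
    list(
      control = c(mean = mean(y[cc$arm == 0L]), n = n0),
      intervention = c(mean = mean(y[cc$arm == 1L]), n = n1),
      incremental = c(estimate = unname(s["Estimate"]),
                      se = unname(s["Std. Error"]),
                      lower = unname(s["Estimate"] - z * s["Std. Error"]),
                      upper = unname(s["Estimate"] + z * s["Std. Error"])),
      model = fm
    )
  }

  list(
    qaly = fit_one(qaly, cc$utilities[, 1]),
    total_cost = fit_one(total_cost, cc$costs[, 1]),
    n_complete = c(control = n0, intervention = n1)
  )
}
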