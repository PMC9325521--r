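#' Trapezoidal area-under-the-curve weights
#'
#' Per-time weights such that the weighted sum of outcome values equals the
#' trapezoidal-rule integral of the piecewise-linear outcome curve over the
#' measurement grid. For times t_1 < ... < t_J (in years) the weights are
#' (t_2 - t_1)/2 for the first point, (t_{j+1} - t_{j-1})/2 for interior
#' points and (t_J - t_{J-1})/2 for the last; they sum to the horizon
#' t_J - t_1. Applied to utilities this yields QALYs.
#'
#' @param times Strictly increasing numeric vector of length >= 2 (years).
#' @return Numeric vector of weights, same length as `times`.
#' @examples
#' auc_weights(c(0, 0.25, 0.75)) # 0.125 0.375 0.250
#' @export
auc_weights <- function(times) {
  times <- as.numeric(times)
  J <- length(times)
  if (J < 2) stop("at least two times are required")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  gaps <- diff(times)
  w <- numeric(J)
  w[1] <- gaps[1] / 2
  w[J] <- gaps[J - 1] / 2
  if (J > 2) w[2:(J - 1)] <- (times[3:J] - times[1:(J - 2)]) / 2
  w
}

# assemble an estimand result from contrast vectors on a fitted model
estimand_from_contrasts <- function(fit, c_control, c_interv, label, scale,
                                    level = 0.95) {
  ctrl <- estimate_contrast(fit, c_control, level)
  intv <- estimate_contrast(fit, c_interv, level)
  incr <- estimate_contrast(fit, c_interv - c_control, level)
  structure(
    list(label = label, scale = scale,
         control = ctrl, intervention = intv, incremental = incr,
         weights = list(control = c_control, intervention = c_interv)),
    class = "estimand_result"
  )
}

#' @export
print.estimand_result <- function(x, ...) {
  cat(x$label, " (", x$scale, ")\n", sep = "")
  m <- rbind(control = x$control, intervention = x$intervention,
             incremental = x$incremental)
  print(round(m, 4))
  invisible(x)
}

#' QALY estimand from a fitted utility MMRM
#'
#' Per-arm quality-adjusted life years over the study horizon, obtained as
#' the trapezoidal-AUC-weighted linear combination of the model's arm-time
#' utility means, with standard errors from the coefficient covariance
#' (c'Vc). With a constrained baseline the common baseline mean enters both
#' arms and cancels from the incremental QALY, which then depends only on
#' the follow-up time-by-arm interaction coefficients — the incremental QALY
#' is baseline-adjusted by construction. With an unconstrained baseline the
#' baseline arm difference contributes to the increment (a warning notes
#' this).
#'
#' @param fit_u An [mmrm_fit][fit_mmrm()] for the utility outcome.
#' @param times Measurement times in years; defaults to the fit's times.
#' @param covariate_profile Optional named covariate values at which per-arm
#'   means are evaluated (covariate terms cancel from the increment).
#' @return An `estimand_result` with `control`, `intervention` and
#'   `incremental` components (each estimate, se, lower, upper).
#' @export
qaly_estimand <- function(fit_u, times = fit_u$times,
                          covariate_profile = NULL) {
  stopifnot(inherits(fit_u, "mmrm_fit"))
  if (fit_u$spec$outcome != "utility") {
    warning("QALY estimand computed from a fit whose outcome is not utility")
  }
  if (!fit_u$spec$constrain_baseline) {
    warning("unconstrained baseline: the baseline arm difference ",
            "contributes to the incremental QALY")
  }
  w <- auc_weights(times)
  J <- length(times)
  c0 <- numeric(length(fit_u$beta))
  c1 <- numeric(length(fit_u$beta))
  for (j in seq_len(J)) {
    c0 <- c0 + w[j] * arm_time_contrast(fit_u, j, 0L, covariate_profile)
    c1 <- c1 + w[j] * arm_time_contrast(fit_u, j, 1L, covariate_profile)
  }
  estimand_from_contrasts(fit_u, c0, c1, "QALYs", "QALYs (years)")
}

#' Total-cost estimand from a fitted cost MMRM
#'
#' Per-arm total cost over the study, obtained by summing the model's
#' follow-up arm-time cost means. The baseline-period cost (the time-1
#' response, covering pre-randomization resource use) is excluded from the
#' total but remains in the model as a response, so follow-up contrasts are
#' adjusted for baseline cost. The incremental total is the sum of the
#' follow-up time-by-arm interaction coefficients.
#'
#' @param fit_c An [mmrm_fit][fit_mmrm()] for the cost outcome.
#' @param covariate_profile Optional named covariate values.
#' @return An `estimand_result` (currency units).
#' @export
total_cost_estimand <- function(fit_c, covariate_profile = NULL) {
  stopifnot(inherits(fit_c, "mmrm_fit"))
  if (fit_c$spec$outcome != "cost") {
    warning("total-cost estimand computed from a fit whose outcome is not ",
            "cost")
  }
  J <- length(fit_c$times)
  c0 <- numeric(length(fit_c$beta))
  c1 <- numeric(length(fit_c$beta))
  for (j in 2:J) {
    c0 <- c0 + arm_time_contrast(fit_c, j, 0L, covariate_profile)
    c1 <- c1 + arm_time_contrast(fit_c, j, 1L, covariate_profile)
  }
  estimand_from_contrasts(fit_c, c0, c1, "Total costs", "currency")
}

#' Table of estimands in the conventional reporting layout
#'
#' Combines per-time marginal means and the aggregate QALY and total-cost
#' estimands into a single data frame with per-arm estimates, confidence
#' intervals and the incremental column, mirroring the usual trial CEA
#' results table.
#'
#' @param fit_u,fit_c Fitted utility and cost models.
#' @param covariate_profile Optional named covariate values.
#' @return A data frame with one row per quantity (`U_j`, `QALYs`, `C_j`,
#'   `Total costs`) and columns for each arm and the increment.
#' @export
estimand_table <- function(fit_u, fit_c, covariate_profile = NULL) {
  fmt <- function(est) {
    data.frame(estimate = est[["estimate"]], lower = est[["lower"]],
               upper = est[["upper"]])
  }
  rows <- list()
  add_row <- function(label, ctrl, intv, incr) {
    rows[[length(rows) + 1L]] <<- cbind(
      data.frame(quantity = label),
      stats::setNames(fmt(ctrl), c("control", "control_low", "control_high")),
      stats::setNames(fmt(intv),
                      c("intervention", "intervention_low",
                        "intervention_high")),
      stats::setNames(fmt(incr),
                      c("incremental", "incremental_low", "incremental_high")))
  }
  J <- length(fit_u$times)
  for (j in 2:J) {
    c0 <- arm_time_contrast(fit_u, j, 0L, covariate_profile)
    c1 <- arm_time_contrast(fit_u, j, 1L, covariate_profile)
    add_row(paste0("U_", j), estimate_contrast(fit_u, c0),
            estimate_contrast(fit_u, c1), estimate_contrast(fit_u, c1 - c0))
  }
  q <- qaly_estimand(fit_u, covariate_profile = covariate_profile)
  add_row("QALYs", q$control, q$intervention, q$incremental)
  for (j in 2:J) {
    c0 <- arm_time_contrast(fit_c, j, 0L, covariate_profile)
    c1 <- arm_time_contrast(fit_c, j, 1L, covariate_profile)
    add_row(paste0("C_", j), estimate_contrast(fit_c, c0),
            estimate_contrast(fit_c, c1), estimate_contrast(fit_c, c1 - c0))
  }
  tc <- total_cost_estimand(fit_c, covariate_profile = covariate_profile)
  add_row("Total costs", tc$control, tc$intervention, tc$incremental)
  do.call(rbind, rows)
}
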