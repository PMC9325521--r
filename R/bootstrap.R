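#' Nonparametric bootstrap of the full cost-effectiveness pipeline
#'
#' Resamples participants with replacement — by default stratified by arm so
#' each replicate keeps the original arm sizes — and re-runs the whole
#' estimation pipeline on each replicate: baseline covariate mean-imputation,
#' both MMRM fits, and the QALY and total-cost estimands. The participant is
#' the resampling unit, so both outcome series travel together and the
#' within-person cost-utility correlation is preserved in the joint draws
#' (required for a valid acceptability curve).
#'
#' Replicates whose optimizer fails to converge are recorded as failed and
#' excluded from the draws (never retried, to avoid distorting the resampling
#' distribution); a warning is raised if more than 5% of replicates fail.
#'
#' @param data A [trial_dataset()].
#' @param spec_u,spec_c [mmrm_spec()] objects for the utility and cost
#'   models.
#' @param B Number of bootstrap replicates (the conventional production
#'   choice is 10,000; use fewer for exploration).
#' @param seed Integer seed; draws are fully reproducible given
#'   (data, specs, B, seed).
#' @param stratify Stratify resampling by arm (default TRUE).
#' @param covariate_profile Passed to the estimand functions.
#' @param resampler Optional function `(n) -> indices` used to draw each
#'   arm's resample (testing hook; default sampling with replacement).
#' @return An object of class `bootstrap_draws`: a list with `draws` (data
#'   frame with columns `delta_qaly`, `delta_cost` for converged replicates),
#'   `B_requested`, `n_failed`, `seed`.
#' @export
bootstrap_cea <- function(data, spec_u = mmrm_spec("utility"),
                          spec_c = mmrm_spec("cost"),
                          B = 10000L, seed = 1L, stratify = TRUE,
                          covariate_profile = NULL, resampler = NULL) {
  stopifnot(inherits(data, "trial_dataset"), B >= 1L)
  set.seed(seed)
  draw_idx <- resampler %||% function(n) sample.int(n, n, replace = TRUE)
  idx0 <- which(data$arm == 0L)
  idx1 <- which(data$arm == 1L)
  n <- n_participants(data)

  dq <- numeric(B)
  dc <- numeric(B)
  ok <- logical(B)
  for (b in seq_len(B)) {
    take <- if (stratify) {
      c(idx0[draw_idx(length(idx0))], idx1[draw_idx(length(idx1))])
    } else {
      draw_idx(n)
    }
    rep_data <- trial_dataset(
      id = seq_along(take), arm = data$arm[take],
      utilities = data$utilities[take, , drop = FALSE],
      costs = data$costs[take, , drop = FALSE],
      times = data$times,
      covariates = if (is.null(data$covariates)) NULL else
        data$covariates[take, , drop = FALSE]
    )
    res <- tryCatch({
      if (!is.null(rep_data$covariates)) {
        rep_data <- mean_impute_baseline(
          rep_data, unique(c(spec_u$covariates, spec_c$covariates)))
      }
      fu <- suppressMessages(fit_mmrm(rep_data, spec_u))
      fc <- suppressMessages(fit_mmrm(rep_data, spec_c))
      if (!fu$converged || !fc$converged) stop("replicate did not converge")
      q <- qaly_estimand(fu, covariate_profile = covariate_profile)
      tc <- total_cost_estimand(fc, covariate_profile = covariate_profile)
      c(q$incremental[["estimate"]], tc$incremental[["estimate"]])
    }, error = function(e) NULL)
    if (!is.null(res)) {
      dq[b] <- res[1]
      dc[b] <- res[2]
      ok[b] <- TRUE
    }
  }

  n_failed <- sum(!ok)
  if (n_failed > 0.05 * B) {
    warning(n_failed, " of ", B, " bootstrap replicates failed to converge ",
            "(more than 5%); interpret bootstrap summaries with caution")
  }
  structure(
    list(draws = data.frame(delta_qaly = dq[ok], delta_cost = dc[ok]),
         B_requested = as.integer(B), n_failed = n_failed,
         seed = as.integer(seed), stratified = isTRUE(stratify)),
    class = "bootstrap_draws"
  )
}

#' @export
print.bootstrap_draws <- function(x, ...) {
  cat("bootstrap_draws:", nrow(x$draws), "converged replicates of",
      x$B_requested, "requested (seed", paste0(x$seed, ")"),
      if (x$n_failed) paste0("; ", x$n_failed, " failed"), "\n")
  cat("  delta QALY: mean", format(mean(x$draws$delta_qaly), digits = 4),
      " 95% percentile CI (",
      paste(format(stats::quantile(x$draws$delta_qaly, c(0.025, 0.975)),
                   digits = 4), collapse = ", "), ")\n")
  cat("  delta cost: mean", format(mean(x$draws$delta_cost), digits = 4),
      " 95% percentile CI (",
      paste(format(stats::quantile(x$draws$delta_cost, c(0.025, 0.975)),
                   digits = 4), collapse = ", "), ")\n")
  invisible(x)
}

#' Percentile confidence intervals from bootstrap draws
#' @param draws A [bootstrap_cea()] result.
#' @param level Confidence level (default 0.95).
#' @return Matrix with rows `delta_qaly`, `delta_cost` and columns
#'   `lower`, `upper`.
#' @export
percentile_ci <- function(draws, level = 0.95) {
  stopifnot(inherits(draws, "bootstrap_draws"))
  a <- (1 - level) / 2
  out <- t(vapply(draws$draws, function(v) {
    stats::quantile(v, c(a, 1 - a), names = FALSE)
  }, numeric(2)))
  colnames(out) <- c("lower", "upper")
  out
}
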