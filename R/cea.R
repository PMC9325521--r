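#' Incremental cost-effectiveness ratio
#'
#' Computes ICER = delta cost / delta QALY with the cost-effectiveness-plane
#' quadrant implied by the signs (NE: more effective and more costly, SE:
#' more effective and cost-saving — dominant, NW: less effective and more
#' costly — dominated, SW: less effective and cost-saving). A zero
#' incremental effect gives an undefined ratio, flagged rather than an
#' error.
#'
#' @param delta_cost Incremental cost (currency).
#' @param delta_qaly Incremental effect (QALYs).
#' @return A list with `icer` (NA when undefined), `quadrant`, `defined`,
#'   and the inputs.
#' @examples
#' icer(550, 0.021375)
#' @export
icer <- function(delta_cost, delta_qaly) {
  defined <- is.finite(delta_qaly) && delta_qaly != 0
  quadrant <- if (delta_qaly > 0 && delta_cost >= 0) "NE"
    else if (delta_qaly > 0) "SE"
    else if (delta_qaly < 0 && delta_cost >= 0) "NW"
    else if (delta_qaly < 0) "SW"
    else NA_character_
  structure(
    list(icer = if (defined) delta_cost / delta_qaly else NA_real_,
         quadrant = quadrant, defined = defined,
         delta_cost = delta_cost, delta_qaly = delta_qaly),
    class = "icer"
  )
}

#' @export
print.icer <- function(x, ...) {
  if (x$defined) {
    cat("ICER:", format(x$icer, big.mark = ",", digits = 6),
        "per QALY (quadrant ", x$quadrant, ")\n")
  } else {
    cat("ICER undefined (incremental effect is zero)\n")
  }
  invisible(x)
}

#' Default willingness-to-pay grid
#'
#' 0 to 50,000 in steps of 500 (currency per QALY), always containing the
#' conventional 25,000 headline threshold.
#' @return Numeric vector of thresholds.
#' @export
default_k_grid <- function() seq(0, 50000, by = 500)

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay threshold k, the probability that the
#' intervention is cost-effective: the proportion of bootstrap draws with
#' positive incremental net benefit, INB = k * delta QALY - delta cost.
#' Draws with INB exactly zero count as not cost-effective (strict
#' inequality, the common convention; ties have probability zero for
#' continuous draws).
#'
#' @param draws A [bootstrap_cea()] result (or a data frame with columns
#'   `delta_qaly`, `delta_cost`).
#' @param k_grid Thresholds in currency per QALY (default
#'   [default_k_grid()]).
#' @return Data frame of class `ceac` with columns `k` and `prob_ce`.
#' @export
ceac <- function(draws, k_grid = default_k_grid()) {
  df <- if (inherits(draws, "bootstrap_draws")) draws$draws
        else as.data.frame(draws)
  stopifnot(all(c("delta_qaly", "delta_cost") %in% names(df)))
  if (!nrow(df)) stop("no bootstrap draws available")
  prob <- vapply(k_grid, function(k) {
    mean(k * df$delta_qaly - df$delta_cost > 0)
  }, numeric(1))
  structure(data.frame(k = k_grid, prob_ce = prob),
            class = c("ceac", "data.frame"))
}

#' Cost-effectiveness plane data
#'
#' Packages the joint bootstrap draws, the point-estimate marker and the
#' willingness-to-pay threshold line for plotting in the (delta QALY,
#' delta cost) plane.
#'
#' @param draws A [bootstrap_cea()] result (or draw data frame).
#' @param point Length-2 numeric: the point-estimate pair
#'   (delta_qaly, delta_cost).
#' @param k Willingness-to-pay threshold whose acceptance line (through the
#'   origin with slope k) is drawn.
#' @return A list of class `cep` with `draws`, `point`, `k`.
#' @export
cep <- function(draws, point, k = 25000) {
  df <- if (inherits(draws, "bootstrap_draws")) draws$draws
        else as.data.frame(draws)
  stopifnot(length(point) == 2L)
  structure(list(draws = df,
                 point = stats::setNames(as.numeric(point),
                                         c("delta_qaly", "delta_cost")),
                 k = k),
            class = "cep")
}

#' Plot a cost-effectiveness plane
#'
#' @param x A [cep()] object.
#' @param ... Unused.
#' @return A ggplot object: the draw cloud, the acceptance line of slope `k`
#'   through the origin, and a darker marker at the point estimate.
#' @export
plot_cep <- function(x, ...) {
  stopifnot(inherits(x, "cep"))
  ggplot2::ggplot(x$draws,
                  ggplot2::aes(x = delta_qaly, y = delta_cost)) +
    ggplot2::geom_point(alpha = 0.3, colour = "steelblue", size = 0.8) +
    ggplot2::geom_abline(intercept = 0, slope = x$k, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = 0, colour = "grey50") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey50") +
    ggplot2::annotate("point", x = x$point["delta_qaly"],
                      y = x$point["delta_cost"], colour = "black", size = 2.5) +
    ggplot2::labs(x = "Incremental QALYs", y = "Incremental cost",
                  title = "Cost-effectiveness plane",
                  subtitle = paste0("threshold k = ",
                                    format(x$k, big.mark = ","),
                                    " per QALY"))
}

#' Plot a cost-effectiveness acceptability curve
#'
#' @param x A [ceac()] data frame.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_ceac <- function(x, ...) {
  stopifnot(inherits(x, "ceac"))
  ggplot2::ggplot(as.data.frame(x),
                  ggplot2::aes(x = k, y = prob_ce)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Willingness to pay (per QALY)",
                  y = "Probability cost-effective",
                  title = "Cost-effectiveness acceptability curve")
}

#' Full cost-effectiveness summary
#'
#' Bundles the point estimates, ICER, CEAC and plane data computed from a
#' pair of fitted models and their bootstrap draws.
#'
#' @param fit_u,fit_c Fitted utility and cost MMRMs.
#' @param draws A [bootstrap_cea()] result.
#' @param k Headline willingness-to-pay threshold.
#' @param k_grid CEAC threshold grid.
#' @param covariate_profile Optional named covariate values.
#' @return A list of class `cea_summary` with `qaly`, `total_cost`
#'   (estimand results), `icer`, `ceac`, `cep`, `prob_ce_at_k`, and
#'   `percentile_ci`.
#' @export
cea_summary <- function(fit_u, fit_c, draws, k = 25000,
                        k_grid = default_k_grid(),
                        covariate_profile = NULL) {
  k_grid <- sort(unique(c(k_grid, k)))
  q <- qaly_estimand(fit_u, covariate_profile = covariate_profile)
  tc <- total_cost_estimand(fit_c, covariate_profile = covariate_profile)
  dq <- q$incremental[["estimate"]]
  dc <- tc$incremental[["estimate"]]
  curve <- ceac(draws, k_grid)
  structure(
    list(qaly = q, total_cost = tc, icer = icer(dc, dq),
         ceac = curve,
         cep = cep(draws, c(dq, dc), k),
         prob_ce_at_k = curve$prob_ce[match(k, curve$k)],
         k = k,
         percentile_ci = percentile_ci(draws)),
    class = "cea_summary"
  )
}

#' @export
print.cea_summary <- function(x, ...) {
  print(x$qaly)
  print(x$total_cost)
  print(x$icer)
  cat("Probability cost-effective at k =", format(x$k, big.mark = ","),
      ":", format(x$prob_ce_at_k, digits = 3), "\n")
  invisible(x)
}
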