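#' @keywords internal
"_PACKAGE"

utils::globalVariables(c("delta_qaly", "delta_cost", "k", "prob_ce"))

# read a YAML (or JSON) analysis/simulation configuration
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
}

config_to_synthetic <- function(cfg) {
  ms <- cfg$missingness %||% list()
  miss <- missingness_spec(
    mechanism = ms$mechanism %||% "MCAR",
    p_u = as.numeric(ms$p_u %||% rep(0.2, length(cfg$times) - 1)),
    p_c = as.numeric(ms$p_c %||% rep(0.2, length(cfg$times) - 1)),
    gamma_u = ms$gamma_u %||% 0, gamma_c = ms$gamma_c %||% 0,
    tau = ms$tau %||% 0)
  mat2 <- function(x) do.call(rbind, lapply(x, as.numeric))
  synthetic_config(
    n = as.integer(cfg$n), times = as.numeric(cfg$times),
    utility_mean = mat2(cfg$utility_mean), utility_sd = mat2(cfg$utility_sd),
    cost_mean = mat2(cfg$cost_mean), cost_sd = mat2(cfg$cost_sd),
    cost_dist = cfg$cost_dist %||% "lognormal",
    utility_corr = cfg$utility_corr %||% 0.5,
    cost_corr = cfg$cost_corr %||% 0.4,
    cross_corr = cfg$cross_corr %||% -0.2,
    missingness = miss,
    seed = as.integer(cfg$seed %||% 1L))
}

#' Simulate a synthetic trial from a configuration file
#'
#' Reads a YAML/JSON simulation configuration (see
#' `system.file("extdata", "sadd_like.yaml", package = "cealmm")`),
#' generates the trial, and writes `complete.csv`, `observed.csv` and
#' `truth.json` into `out_dir`. Re-running with the same config and seed
#' reproduces the files byte-identically.
#'
#' @param config_path Path to the configuration file, or `"sadd_like"` for
#'   the shipped preset.
#' @param out_dir Output directory (created if needed).
#' @param seed Optional seed overriding the config's.
#' @return Invisibly, the paths of the written files.
#' @export
run_simulate <- function(config_path, out_dir, seed = NULL) {
  if (identical(config_path, "sadd_like")) {
    config_path <- system.file("extdata", "sadd_like.yaml",
                               package = "cealmm")
  }
  cfg <- config_to_synthetic(read_config(config_path))
  sim <- generate_trial(cfg, seed = seed %||% cfg$seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  write_one <- function(d, path) {
    J <- length(d$times)
    df <- data.frame(id = d$id, arm = d$arm,
                     as.data.frame(d$utilities), as.data.frame(d$costs),
                     check.names = FALSE)
    utils::write.csv(df, path, row.names = FALSE, na = "")
    path
  }
  p1 <- write_one(sim$complete, file.path(out_dir, "complete.csv"))
  p2 <- write_one(sim$observed, file.path(out_dir, "observed.csv"))
  p3 <- file.path(out_dir, "truth.json")
  truth <- lapply(sim$truth[c("qaly", "total_cost")], as.list)
  truth$seed <- sim$truth$seed
  jsonlite::write_json(truth, p3, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(complete = p1, observed = p2, truth = p3))
}

#' Run the full cost-effectiveness analysis pipeline
#'
#' Reads a wide-format trial CSV and an analysis configuration, fits the
#' utility and cost MMRMs, bootstraps the incremental estimands, and writes
#' the standard report artifacts into `out_dir`: the missingness pattern
#' table, observed summaries, the estimand table, the bootstrap draws, the
#' CEAC, the plane and curve figures, and a JSON run log (seed, replicate
#' counts, convergence, versions).
#'
#' @param data_path CSV file with one row per participant.
#' @param config Analysis configuration: a list or a YAML/JSON path with
#'   entries `schema` (column mapping with `id`, `arm`, `utilities`,
#'   `costs`, optional `covariates`), `times`, and optional `model`
#'   (`covariance`, `reml`, `constrain_baseline`, `covariates`), `bootstrap`
#'   (`B`, `seed`, `stratify`), `cea` (`k`, `k_min`, `k_max`, `k_step`),
#'   `cca` (logical: add the complete-case comparator).
#' @param out_dir Output directory.
#' @param figures Write PNG figures (default TRUE).
#' @return Invisibly, a list with the fitted models, bootstrap draws and
#'   [cea_summary()].
#' @export
run_analysis <- function(data_path, config, out_dir, figures = TRUE) {
  cfg <- if (is.character(config)) read_config(config) else config
  stopifnot(!is.null(cfg$schema), !is.null(cfg$times))
  times <- as.numeric(cfg$times)
  data <- read_trial_data(data_path, schema = cfg$schema, times = times)

  mod <- cfg$model %||% list()
  covs <- as.character(mod$covariates %||% character())
  if (length(covs)) data <- mean_impute_baseline(data, covs)
  make_spec <- function(outcome) {
    mmrm_spec(outcome,
              covariance = mod$covariance %||% "un",
              reml = mod$reml %||% TRUE,
              covariates = covs,
              constrain_baseline = mod$constrain_baseline %||% TRUE)
  }
  spec_u <- make_spec("utility")
  spec_c <- make_spec("cost")

  fit_u <- fit_mmrm(data, spec_u)
  fit_c <- fit_mmrm(data, spec_c)
  if (!fit_u$converged || !fit_c$converged) {
    stop("base MMRM fit did not converge (utility: ", fit_u$converged,
         ", cost: ", fit_c$converged, "); bootstrap not run. ",
         "Consider covariance = 'cs'.")
  }

  bs <- cfg$bootstrap %||% list()
  B <- as.integer(bs$B %||% 10000L)
  seed <- as.integer(bs$seed %||% 1L)
  draws <- bootstrap_cea(data, spec_u, spec_c, B = B, seed = seed,
                         stratify = bs$stratify %||% TRUE)

  ce <- cfg$cea %||% list()
  k <- as.numeric(ce$k %||% 25000)
  k_grid <- seq(as.numeric(ce$k_min %||% 0), as.numeric(ce$k_max %||% 50000),
                by = as.numeric(ce$k_step %||% 500))
  summ <- cea_summary(fit_u, fit_c, draws, k = k, k_grid = k_grid)

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(pattern_table(data)),
                   file.path(out_dir, "pattern_table.csv"),
                   row.names = FALSE)
  utils::write.csv(observed_summary(data),
                   file.path(out_dir, "observed_summary.csv"),
                   row.names = FALSE)
  est <- estimand_table(fit_u, fit_c)
  if (isTRUE(cfg$cca)) {
    cca <- cca_estimates(data, times, covariates = covs)
    est$cca_incremental <- NA_real_
    est$cca_incremental[est$quantity == "QALYs"] <-
      cca$qaly$incremental[["estimate"]]
    est$cca_incremental[est$quantity == "Total costs"] <-
      cca$total_cost$incremental[["estimate"]]
  }
  utils::write.csv(est, file.path(out_dir, "estimands.csv"),
                   row.names = FALSE)
  utils::write.csv(draws$draws, file.path(out_dir, "bootstrap_draws.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(summ$ceac), file.path(out_dir, "ceac.csv"),
                   row.names = FALSE)
  if (figures) {
    ggplot2::ggsave(file.path(out_dir, "cep.png"), plot_cep(summ$cep),
                    width = 6, height = 5, dpi = 150)
    ggplot2::ggsave(file.path(out_dir, "ceac.png"), plot_ceac(summ$ceac),
                    width = 6, height = 4, dpi = 150)
  }
  log <- list(
    data_path = normalizePath(data_path),
    n = n_participants(data),
    seed = seed, B_requested = B, B_failed = draws$n_failed,
    utility_converged = fit_u$converged, cost_converged = fit_c$converged,
    icer = summ$icer$icer, prob_ce_at_k = summ$prob_ce_at_k, k = k,
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("cealmm")),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(data = data, fit_u = fit_u, fit_c = fit_c, draws = draws,
                 summary = summ))
}
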