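#' Two-arm longitudinal cost-utility trial dataset
#'
#' Container for a wide-format trial dataset: one row per participant with a
#' binary treatment arm, health utilities and costs measured at a common grid
#' of `J >= 2` time points (the first being baseline, time 0), and optional
#' baseline covariates. Missing outcome entries are `NA`; no sentinel codes
#' are used.
#'
#' @param id Vector of unique participant identifiers (coerced to character).
#' @param arm Integer vector of treatment indicators, 0 = control,
#'   1 = intervention.
#' @param utilities Numeric matrix, one column per time point. Entries may be
#'   `NA`. Utilities are dimensionless quality-of-life weights (for the
#'   EQ-5D-3L UK tariff, typically in \[-0.594, 1\]).
#' @param costs Numeric matrix with the same dimensions as `utilities`, in
#'   currency units; entries may be `NA` and observed entries must be >= 0.
#' @param times Numeric vector of measurement times in years since
#'   randomization, strictly increasing, starting at 0.
#' @param covariates Optional data frame of baseline covariates (one row per
#'   participant); entries may be `NA` (see [mean_impute_baseline()]).
#'
#' @return An object of class `trial_dataset`: a list with elements `id`,
#'   `arm`, `utilities`, `costs`, `times`, `covariates`.
#' @examples
#' d <- trial_dataset(
#'   id = c("a", "b"), arm = c(0L, 1L),
#'   utilities = rbind(c(0.7, 0.8, NA), c(0.6, 0.6, 0.7)),
#'   costs = rbind(c(100, 120, 90), c(80, NA, 200)),
#'   times = c(0, 0.25, 0.75)
#' )
#' n_participants(d)
#' @export
trial_dataset <- function(id, arm, utilities, costs, times, covariates = NULL) {
  id <- as.character(id)
  arm <- as.integer(arm)
  utilities <- as.matrix(utilities)
  costs <- as.matrix(costs)
  storage.mode(utilities) <- "double"
  storage.mode(costs) <- "double"
  times <- as.numeric(times)
  J <- length(times)
  colnames(utilities) <- paste0("u", seq_len(J))
  colnames(costs) <- paste0("c", seq_len(J))

  if (anyDuplicated(id)) {
    stop("duplicate participant ids: ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  if (any(is.na(arm)) || !all(arm %in% c(0L, 1L))) {
    bad <- which(is.na(arm) | !(arm %in% c(0L, 1L)))
    stop("arm must be 0 or 1; offending row(s): ",
         paste(bad, collapse = ", "))
  }
  if (J < 2) stop("at least two measurement times are required")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (times[1] != 0) stop("first measurement time must be 0 (baseline)")
  if (nrow(utilities) != length(id) || nrow(costs) != length(id)) {
    stop("utilities and costs must have one row per participant")
  }
  if (ncol(utilities) != J || ncol(costs) != J) {
    stop("utilities and costs must have one column per time point (J = ",
         J, ")")
  }
  if (!any(arm == 0L) || !any(arm == 1L)) {
    stop("both arms must be non-empty")
  }
  if (any(costs < 0, na.rm = TRUE)) stop("observed costs must be >= 0")
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != length(id)) {
      stop("covariates must have one row per participant")
    }
  }

  structure(
    list(id = id, arm = arm, utilities = utilities, costs = costs,
         times = times, covariates = covariates),
    class = "trial_dataset"
  )
}

#' @export
print.trial_dataset <- function(x, ...) {
  cat("trial_dataset: ", n_participants(x), " participants (control ",
      sum(x$arm == 0L), ", intervention ", sum(x$arm == 1L), ")\n", sep = "")
  cat("  times (years):", paste(x$times, collapse = ", "), "\n")
  miss_u <- sum(is.na(x$utilities))
  miss_c <- sum(is.na(x$costs))
  cat("  missing entries: utilities ", miss_u, ", costs ", miss_c, "\n",
      sep = "")
  if (!is.null(x$covariates)) {
    cat("  covariates:", paste(names(x$covariates), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of participants in a trial dataset
#' @param data A [trial_dataset()].
#' @return Integer count of rows.
#' @export
n_participants <- function(data) {
  stopifnot(inherits(data, "trial_dataset"))
  length(data$id)
}

#' Read a wide-format trial dataset from delimited text
#'
#' Parses a delimited file with one row per participant and validates it into
#' a [trial_dataset()]. Cell values listed in `na_strings` (and empty cells)
#' are treated as missing.
#'
#' @param path Path to a delimited text file with a header row.
#' @param schema Named list mapping roles to column names: `id`, `arm`,
#'   `utilities` (character vector, one per time), `costs` (same length), and
#'   optionally `covariates`.
#' @param times Numeric vector of measurement times in years; length must
#'   match the utility/cost column lists.
#' @param sep Field separator (default comma).
#' @param na_strings Cell values mapped to missing.
#' @return A validated [trial_dataset()]; input row order is preserved.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("id,arm,u1,u2,c1,c2",
#'              "p1,0,0.7,0.8,100,150",
#'              "p2,1,0.6,,90,70"), f)
#' d <- read_trial_data(f,
#'   schema = list(id = "id", arm = "arm",
#'                 utilities = c("u1", "u2"), costs = c("c1", "c2")),
#'   times = c(0, 0.5))
#' sum(is.na(d$utilities))
#' @export
read_trial_data <- function(path, schema, times, sep = ",",
                            na_strings = c("", "NA", "NaN", ".")) {
  if (!file.exists(path)) stop("file not found: ", path)
  stopifnot(is.list(schema), !is.null(schema$id), !is.null(schema$arm),
            !is.null(schema$utilities), !is.null(schema$costs))
  if (length(schema$utilities) != length(times) ||
      length(schema$costs) != length(times)) {
    stop("times length (", length(times),
         ") must match the number of utility and cost columns")
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           na.strings = na_strings, colClasses = "character",
                           check.names = FALSE, stringsAsFactors = FALSE)
  needed <- c(schema$id, schema$arm, schema$utilities, schema$costs,
              schema$covariates)
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols)) {
    stop("column(s) not found in ", path, ": ",
         paste(missing_cols, collapse = ", "))
  }

  parse_num <- function(cols, what) {
    m <- sapply(cols, function(cn) {
      v <- raw[[cn]]
      num <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & is.na(num))
      if (length(bad)) {
        stop("non-numeric ", what, " value ", dQuote(v[bad[1]]),
             " in column ", dQuote(cn), ", row ", bad[1])
      }
      num
    })
    matrix(m, nrow = nrow(raw), dimnames = NULL)
  }

  arm_num <- suppressWarnings(as.numeric(raw[[schema$arm]]))
  bad_arm <- which(is.na(arm_num) | !(arm_num %in% c(0, 1)))
  if (length(bad_arm)) {
    stop("invalid arm value ", dQuote(raw[[schema$arm]][bad_arm[1]]),
         " in column ", dQuote(schema$arm), ", row ", bad_arm[1],
         " (must be 0 or 1)")
  }

  covs <- NULL
  if (!is.null(schema$covariates)) {
    covs <- as.data.frame(
      parse_num(schema$covariates, "covariate"))
    names(covs) <- schema$covariates
  }

  trial_dataset(
    id = raw[[schema$id]],
    arm = as.integer(arm_num),
    utilities = parse_num(schema$utilities, "utility"),
    costs = parse_num(schema$costs, "cost"),
    times = times,
    covariates = covs
  )
}

#' Tabulate missingness patterns of the utility and cost series
#'
#' Summarizes the distinct observed/missing masks over the `2J` outcome
#' entries (utilities then costs), with per-arm and overall counts and
#' percentages, sorted by descending overall count. This is the standard
#' missing-data-pattern table reported for trial-based cost-effectiveness
#' analyses.
#'
#' @param data A [trial_dataset()].
#' @return A data frame of class `pattern_table` with columns `pattern`
#'   (string of `-` observed / `X` missing, utilities then costs),
#'   `n_control`, `n_intervention`, `n_total`, and integer-rounded
#'   percentages `pct_control`, `pct_intervention`, `pct_total`.
#' @examples
#' d <- trial_dataset(
#'   id = 1:4, arm = c(0, 0, 1, 1),
#'   utilities = rbind(c(0.7, 0.8), c(0.6, NA), c(0.5, 0.9), c(0.8, 0.7)),
#'   costs = matrix(100, 4, 2), times = c(0, 0.5)
#' )
#' pattern_table(d)
#' @export
pattern_table <- function(data) {
  stopifnot(inherits(data, "trial_dataset"))
  mask <- cbind(is.na(data$utilities), is.na(data$costs))
  key <- apply(mask, 1L, function(m) paste(ifelse(m, "X", "-"), collapse = ""))
  n0 <- sum(data$arm == 0L)
  n1 <- sum(data$arm == 1L)
  tab0 <- table(factor(key[data$arm == 0L], levels = unique(key)))
  tab1 <- table(factor(key[data$arm == 1L], levels = unique(key)))
  out <- data.frame(
    pattern = unique(key),
    n_control = as.integer(tab0),
    n_intervention = as.integer(tab1),
    stringsAsFactors = FALSE
  )
  out$n_total <- out$n_control + out$n_intervention
  out <- out[order(-out$n_total, out$pattern), , drop = FALSE]
  rownames(out) <- NULL
  out$pct_control <- as.integer(round(100 * out$n_control / n0))
  out$pct_intervention <- as.integer(round(100 * out$n_intervention / n1))
  out$pct_total <- as.integer(round(100 * out$n_total / (n0 + n1)))
  class(out) <- c("pattern_table", "data.frame")
  out
}

#' Restrict a trial dataset to complete cases
#'
#' Keeps only participants with fully observed utility and cost series (the
#' "completers"). Missing baseline covariates do not exclude a participant;
#' covariates are handled separately by [mean_impute_baseline()].
#'
#' @param data A [trial_dataset()].
#' @return A [trial_dataset()] containing the completers.
#' @export
complete_cases <- function(data) {
  stopifnot(inherits(data, "trial_dataset"))
  keep <- stats::complete.cases(data$utilities) &
    stats::complete.cases(data$costs)
  if (!any(keep & data$arm == 0L) || !any(keep & data$arm == 1L)) {
    stop("no complete cases left in at least one arm")
  }
  trial_dataset(
    id = data$id[keep], arm = data$arm[keep],
    utilities = data$utilities[keep, , drop = FALSE],
    costs = data$costs[keep, , drop = FALSE],
    times = data$times,
    covariates = if (is.null(data$covariates)) NULL else
      data$covariates[keep, , drop = FALSE]
  )
}

#' Observed per-arm, per-time outcome summaries
#'
#' Means, standard deviations and available sample sizes for each outcome at
#' each time point, by arm, computed over the non-missing observations only
#' (the usual "observed data" descriptive table).
#'
#' @param data A [trial_dataset()].
#' @return A data frame with columns `outcome` (`"utility"`/`"cost"`),
#'   `arm`, `time`, `mean`, `sd`, `n`. For an all-missing cell, `mean` and
#'   `sd` are `NA` and `n` is 0.
#' @export
observed_summary <- function(data) {
  stopifnot(inherits(data, "trial_dataset"))
  one <- function(mat, outcome) {
    do.call(rbind, lapply(c(0L, 1L), function(a) {
      sub <- mat[data$arm == a, , drop = FALSE]
      data.frame(
        outcome = outcome,
        arm = a,
        time = data$times,
        mean = apply(sub, 2L, function(v) {
          v <- v[!is.na(v)]
          if (length(v)) mean(v) else NA_real_
        }),
        sd = apply(sub, 2L, function(v) {
          v <- v[!is.na(v)]
          if (length(v) > 1L) stats::sd(v) else NA_real_
        }),
        n = apply(sub, 2L, function(v) sum(!is.na(v))),
        row.names = NULL
      )
    }))
  }
  rbind(one(data$utilities, "utility"), one(data$costs, "cost"))
}

#' Convert a long-format table to a wide trial dataset
#'
#' Accepts one row per participant-time with outcome columns and pivots to
#' the canonical wide representation immediately.
#'
#' @param df Data frame with columns named by `schema`: `id`, `arm`, `time`,
#'   `utility`, `cost`.
#' @param times Numeric vector of measurement times in years; every `time`
#'   value in `df` must match one of these.
#' @param schema Named list of column names (defaults shown above).
#' @return A [trial_dataset()].
#' @export
long_to_trial_data <- function(df, times,
                               schema = list(id = "id", arm = "arm",
                                             time = "time",
                                             utility = "utility",
                                             cost = "cost")) {
  df <- as.data.frame(df)
  ids <- unique(as.character(df[[schema$id]]))
  J <- length(times)
  ti <- match(df[[schema$time]], times)
  if (anyNA(ti)) stop("time value not on the declared grid: ",
                      df[[schema$time]][which(is.na(ti))[1]])
  ri <- match(as.character(df[[schema$id]]), ids)
  U <- matrix(NA_real_, length(ids), J)
  C <- matrix(NA_real_, length(ids), J)
  U[cbind(ri, ti)] <- as.numeric(df[[schema$utility]])
  C[cbind(ri, ti)] <- as.numeric(df[[schema$cost]])
  arm <- tapply(as.integer(df[[schema$arm]]), ri, function(a) {
    if (length(unique(a)) > 1L) stop("arm varies within a participant")
    a[1]
  })
  trial_dataset(id = ids, arm = as.integer(arm[as.character(seq_along(ids))]),
                utilities = U, costs = C, times = times)
}
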