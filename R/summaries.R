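#' Validate a trial dataset and apply the exclusion rules
#'
#' Recomputes per-subject hit/error/miss percentages, relabels any
#' responded trial with an RT above the deadline as missed, and flags for
#' exclusion every subject with a zero-error run (such subjects carry no
#' information about learning from negative feedback and are excluded from
#' modelling, as in the study's preprocessing).
#'
#' @param trials Trial table (`subject_id`, `run`, `trial`, `pair_id`,
#'   `response`, `rt_s`, `feedback`).
#' @param deadline Response deadline in seconds.
#' @return List of class `rlddm_validation` with `trials` (relabeled),
#'   `subject_rates` (per-subject percentages), `excluded` (subject,
#'   reason) and `retained` (subject ids).
#' @export
validate_dataset <- function(trials, deadline = 2.5) {
  req <- c("subject_id", "run", "trial", "pair_id", "response", "rt_s",
           "feedback")
  miss <- setdiff(req, names(trials))
  if (length(miss)) stop("trial table lacks columns: ",
                         paste(miss, collapse = ", "))
  bad <- which(!(trials$response %in% c("correct", "incorrect", "missed")) |
                 (trials$response != "missed" & !is.finite(trials$rt_s)))
  if (length(bad)) {
    stop("malformed trial rows (bad response/rt): lines ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  over <- trials$response != "missed" & trials$rt_s > deadline
  if (any(over)) {
    trials$response[over] <- "missed"
    trials$rt_s[over] <- NA_real_
    trials$feedback[over] <- NA_integer_
  }
  subjects <- unique(as.character(trials$subject_id))
  rates <- do.call(rbind, lapply(subjects, function(s) {
    tr <- trials[trials$subject_id == s, ]
    n <- nrow(tr)
    data.frame(subject_id = s,
               pct_hits = 100 * mean(tr$response == "correct"),
               pct_errors = 100 * mean(tr$response == "incorrect"),
               pct_missed = 100 * mean(tr$response == "missed"),
               stringsAsFactors = FALSE)
  }))
  excl <- list()
  for (s in subjects) {
    tr <- trials[trials$subject_id == s, ]
    errs_per_run <- tapply(tr$response == "incorrect", tr$run, sum)
    if (any(errs_per_run == 0)) {
      excl[[s]] <- data.frame(subject_id = s, reason = "zero errors in run",
                              stringsAsFactors = FALSE)
    }
  }
  excluded <- if (length(excl)) do.call(rbind, excl) else
    data.frame(subject_id = character(), reason = character(),
               stringsAsFactors = FALSE)
  rownames(excluded) <- NULL
  structure(list(trials = trials, subject_rates = rates, excluded = excluded,
                 retained = setdiff(subjects, excluded$subject_id)),
            class = "rlddm_validation")
}

#' Assign a reading-skill group from a reading percentile
#'
#' Children at or above the 16th percentile are labelled typical readers
#' (`TR`), below it poor readers (`PR`). In strict mode, percentiles in the
#' 16--25 range are additionally labelled `intermediate` (for exclusion in
#' sensitivity analyses).
#'
#' @param reading_percentile Percentile(s) in \[0, 100\].
#' @param strict Mark the 16--25 band as `"intermediate"`.
#' @return Character vector of labels `"TR"`, `"PR"` (and
#'   `"intermediate"` in strict mode).
#' @export
#' @examples
#' assign_reading_group(c(5, 16, 50))
assign_reading_group <- function(reading_percentile, strict = FALSE) {
  if (any(reading_percentile < 0 | reading_percentile > 100)) {
    stop("reading percentiles must lie in [0, 100]")
  }
  out <- ifelse(reading_percentile < 16, "PR", "TR")
  if (strict) {
    out[reading_percentile >= 16 & reading_percentile <= 25] <- "intermediate"
  }
  out
}

#' Bin-wise learning summaries
#'
#' Splits each run into `n_bins` consecutive equal-length blocks (10 trials
#' for the default 40-trial runs), shares bin indices across runs, and
#' averages within bin and group: accuracy (proportion correct among
#' responded trials; misses excluded from the denominator), mean and median
#' RT of correct trials, and -- when a trial-wise series is supplied -- the
#' mean drift and boundary.
#'
#' @param dataset Trial table (or `rlddm_cohort`).
#' @param series Optional output of [extract_trialwise_series()].
#' @param n_bins Number of bins per run; run length must be divisible by it.
#' @return Data frame with one row per group x bin.
#' @export
bin_summaries <- function(dataset, series = NULL, n_bins = 4) {
  if (inherits(dataset, "rlddm_cohort")) dataset <- dataset$trials
  if (!"group" %in% names(dataset)) dataset$group <- "all"
  run_len <- tapply(dataset$trial, interaction(dataset$subject_id, dataset$run,
                                               drop = TRUE), max)
  if (any(run_len %% n_bins != 0)) {
    stop("run length must be divisible by the number of bins (", n_bins, ")")
  }
  bin_of <- function(trial, len) ceiling(trial / (len / n_bins))
  len1 <- max(dataset$trial)
  dataset$bin <- bin_of(dataset$trial, len1)
  if (!is.null(series)) {
    key_d <- paste(dataset$subject_id, dataset$run, dataset$trial)
    key_s <- paste(series$subject_id, series$run, series$trial)
    m <- match(key_d, key_s)
    dataset$drift <- series$drift_mean[m]
    dataset$boundary <- series$boundary_mean[m]
  }
  out <- list(); i <- 0L
  for (g in unique(dataset$group)) {
    for (b in seq_len(n_bins)) {
      dd <- dataset[dataset$group == g & dataset$bin == b, ]
      responded <- dd$response != "missed"
      corr <- dd$response == "correct"
      i <- i + 1L
      out[[i]] <- data.frame(
        group = g, bin = b,
        accuracy = mean(corr[responded]),
        rt_mean = mean(dd$rt_s[corr], na.rm = TRUE),
        rt_median = median(dd$rt_s[corr], na.rm = TRUE),
        drift_mean = if (!is.null(series)) mean(dd$drift) else NA_real_,
        boundary_mean = if (!is.null(series)) mean(dd$boundary) else NA_real_,
        n_subjects = length(unique(dd$subject_id)),
        n_trials = nrow(dd),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Two-group contrast of subject-level values
#'
#' Welch two-sample t-test (unequal variances, two-tailed), the package's
#' default for comparing subject-specific parameter summaries between
#' reading-skill groups.
#'
#' @param values_a,values_b Numeric vectors (>= 2 values each).
#' @return List with `t`, `df`, `p`, and the group means.
#' @export
#' @examples
#' group_contrast(rnorm(10), rnorm(10, 1))
group_contrast <- function(values_a, values_b) {
  if (length(values_a) < 2 || length(values_b) < 2) {
    stop("need at least 2 values per group")
  }
  if (stats::var(values_a) == 0 && stats::var(values_b) == 0 &&
      mean(values_a) == mean(values_b)) {
    return(list(t = 0, df = length(values_a) + length(values_b) - 2, p = 1,
                mean_a = mean(values_a), mean_b = mean(values_b)))
  }
  tt <- stats::t.test(values_a, values_b, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_a = mean(values_a), mean_b = mean(values_b))
}
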