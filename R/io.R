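#' Write a trial table to CSV
#'
#' UTF-8, comma-separated, header row; RTs in seconds with 4 decimal
#' places; missed trials carry an empty `rt_s` field and response
#' `"missed"`. Columns: `subject_id`, `group`, `run`, `trial`, `pair_id`,
#' `correct_side`, `response`, `rt_s`, `feedback`.
#'
#' @param trials Trial table (or `rlddm_cohort`, whose trials are written).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  if (inherits(trials, "rlddm_cohort")) trials <- trials$trials
  cols <- c("subject_id", "group", "run", "trial", "pair_id", "foil_pair_id",
            "correct_side", "response", "rt_s", "feedback")
  for (c_ in setdiff(cols, names(trials))) trials[[c_]] <- NA
  out <- trials[cols]
  out$rt_s <- ifelse(is.na(out$rt_s), "", sprintf("%.4f", out$rt_s))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8", na = "")
  invisible(path)
}

#' Read a trial table from CSV
#'
#' Inverse of [write_trials()]: empty `rt_s`/`feedback` fields become `NA`
#' (missed trials).
#'
#' @param path CSV file written by [write_trials()] (or matching its schema).
#' @return Trial data frame.
#' @export
read_trials <- function(path) {
  tr <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(rt_s = "character"),
                        fileEncoding = "UTF-8")
  tr$rt_s <- suppressWarnings(as.numeric(tr$rt_s))
  tr$feedback <- suppressWarnings(as.integer(tr$feedback))
  tr
}

#' Read a configuration file
#'
#' YAML configuration with blocks `task` (n_runs, trials_per_run,
#' n_pairs_per_run, deadline, ...), `cohort` (per-group hyperparameter
#' means/SDs or a `preset` name, plus `n_subjects` per group and a `seed`),
#' `sampler` (preset, chains, iter, warmup, thin, seed) and `variant_id`.
#'
#' @param path YAML file.
#' @return List with elements `task` ([task_config()]), `cohort_spec`
#'   ([cohort_spec()], when a cohort block is present), `sampler`
#'   ([mcmc_config()]) and `variant_id`.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  task_args <- cfg$task
  task <- if (is.null(task_args)) task_config() else {
    nm <- intersect(names(task_args),
                    names(formals(task_config)))
    do.call(task_config, task_args[nm])
  }
  variant_id <- if (is.null(cfg$variant_id)) 4L else as.integer(cfg$variant_id)
  sampler <- if (is.null(cfg$sampler)) mcmc_config("desk") else {
    do.call(mcmc_config, c(list(preset = cfg$sampler$preset %||% "desk"),
                           cfg$sampler[intersect(names(cfg$sampler),
                                                 c("chains", "iter",
                                                   "warmup", "thin"))]))
  }
  spec <- NULL
  if (!is.null(cfg$cohort)) {
    groups <- names(cfg$cohort$groups)
    hyper <- lapply(cfg$cohort$groups, function(g) {
      if (!is.null(g$preset)) return(default_group_hyperparameters(g$preset))
      group_hyperparameters(unlist(g$mean), unlist(g$sd))
    })
    n_subjects <- vapply(cfg$cohort$groups,
                         function(g) as.integer(g$n_subjects), integer(1))
    names(hyper) <- names(n_subjects) <- groups
    spec <- cohort_spec(hyper, n_subjects, variant_id = variant_id,
                        seed = as.integer(cfg$cohort$seed %||% 1L),
                        task = task,
                        balanced = isTRUE(cfg$cohort$balanced))
  }
  list(task = task, cohort_spec = spec, sampler = sampler,
       variant_id = variant_id,
       seed = as.integer(cfg$sampler$seed %||% 1L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
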