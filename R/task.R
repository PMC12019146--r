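# deterministic seed mixing for independent substreams (task layout vs
# behavioral noise vs parameter draws); keeps derived seeds below 2^31
.mix_seed <- function(...) {
  x <- 104729
  for (v in c(...)) x <- (x * 1000003 + as.numeric(v)) %% 2147483629
  as.integer(x) + 1L
}

#' Task configuration
#'
#' Describes the structure of the audiovisual associative learning task:
#' `n_runs` runs of `trials_per_run` trials each, `n_pairs_per_run`
#' character--sound pairings learned deterministically over
#' `repetitions_per_pair` repetitions, and a response `deadline` after which
#' a trial counts as missed. Defaults reproduce the study design (2 runs of
#' 40 trials, 4 pairings x 10 repetitions, 2.5 s deadline). The stimulus and
#' feedback timing fields are carried for provenance only.
#'
#' @param n_runs,trials_per_run,n_pairs_per_run,repetitions_per_pair Counts.
#' @param deadline Response deadline in seconds.
#' @param stimulus_duration_s,feedback_duration_s Presentation timings
#'   (seconds), not used by the simulator.
#' @return An object of class `rlddm_task_config`.
#' @export
task_config <- function(n_runs = 2, trials_per_run = 40, n_pairs_per_run = 4,
                        repetitions_per_pair = 10, deadline = 2.5,
                        stimulus_duration_s = 2, feedback_duration_s = 2) {
  cfg <- list(n_runs = as.integer(n_runs),
              trials_per_run = as.integer(trials_per_run),
              n_pairs_per_run = as.integer(n_pairs_per_run),
              repetitions_per_pair = as.integer(repetitions_per_pair),
              deadline = deadline,
              stimulus_duration_s = stimulus_duration_s,
              feedback_duration_s = feedback_duration_s)
  if (any(unlist(cfg[1:4]) < 1)) stop("task counts must be >= 1")
  if (cfg$n_pairs_per_run * cfg$repetitions_per_pair != cfg$trials_per_run) {
    stop("inconsistent task config: n_pairs_per_run * repetitions_per_pair ",
         "must equal trials_per_run (", cfg$n_pairs_per_run, " * ",
         cfg$repetitions_per_pair, " != ", cfg$trials_per_run, ")")
  }
  if (cfg$deadline <= 0) stop("`deadline` must be positive")
  structure(cfg, class = "rlddm_task_config")
}

#' Generate a randomized task layout
#'
#' Builds the ordered trial skeleton for one subject: within each run every
#' pairing appears exactly `repetitions_per_pair` times in randomized order,
#' the side of the correct character is balanced 50/50 per pairing (up to
#' rounding), and each trial carries a foil -- the character of one of the
#' run's other pairings shown alongside the target. The layout is
#' deterministic given the seed.
#'
#' @param config An [task_config()] object.
#' @param seed Integer seed for the layout.
#' @return Data frame with columns `run`, `trial` (1-based within run),
#'   `pair_id`, `foil_pair_id` and `correct_side`.
#' @export
#' @examples
#' head(generate_task(task_config(), seed = 1))
generate_task <- function(config = task_config(), seed = 1L) {
  stopifnot(inherits(config, "rlddm_task_config"))
  out <- vector("list", config$n_runs)
  for (r in seq_len(config$n_runs)) {
    pairs <- sprintf("r%dp%d", r, seq_len(config$n_pairs_per_run))
    set.seed(.mix_seed(seed, r, 11L))
    pair_seq <- sample(rep(pairs, each = config$repetitions_per_pair))
    set.seed(.mix_seed(seed, r, 13L))
    side <- character(config$trials_per_run)
    for (p in pairs) {
      idx <- which(pair_seq == p)
      k <- length(idx)
      sides <- rep(c("left", "right"), length.out = k)
      side[idx] <- sample(sides)
    }
    foil <- pair_seq
    if (config$n_pairs_per_run > 1L) {
      set.seed(.mix_seed(seed, r, 17L))
      foil <- vapply(pair_seq, function(p)
        sample(setdiff(pairs, p), 1L), character(1), USE.NAMES = FALSE)
    }
    out[[r]] <- data.frame(run = r, trial = seq_len(config$trials_per_run),
                           pair_id = pair_seq, foil_pair_id = foil,
                           correct_side = side,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  attr(res, "deadline") <- config$deadline
  res
}
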