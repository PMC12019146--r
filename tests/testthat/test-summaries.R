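make_subject <- function(id, responses, run_len = 4, rts = NULL) {
  n <- length(responses)
  stopifnot(n %% run_len == 0)
  if (is.null(rts)) rts <- rep(1.2, n)
  rts[responses == "missed"] <- NA
  data.frame(subject_id = id, group = "all",
             run = rep(seq_len(n / run_len), each = run_len),
             trial = rep(seq_len(run_len), n / run_len),
             pair_id = "p1",
             response = responses, rt_s = rts,
             feedback = ifelse(responses == "correct", 1L,
                               ifelse(responses == "incorrect", 0L, NA)),
             stringsAsFactors = FALSE)
}

test_that("subjects with a zero-error run are flagged for exclusion", {
  all_correct <- make_subject("S1", rep("correct", 8))
  mixed <- make_subject("S2", rep(c("correct", "incorrect"), 4))
  rep_ <- validate_dataset(rbind(all_correct, mixed))
  expect_equal(rep_$excluded$subject_id, "S1")
  expect_equal(rep_$excluded$reason, "zero errors in run")
  expect_equal(rep_$retained, "S2")
})

test_that("responded trials beyond the deadline are relabeled as missed", {
  tr <- make_subject("S1", c(rep(c("correct", "incorrect"), 3),
                             "correct", "correct"),
                     rts = c(rep(1.2, 7), 2.6))
  rep_ <- validate_dataset(tr, deadline = 2.5)
  expect_equal(rep_$trials$response[8], "missed")
  expect_true(is.na(rep_$trials$rt_s[8]))
  expect_equal(rep_$subject_rates$pct_missed, 100 * 1 / 8)
  expect_equal(rep_$subject_rates$pct_hits + rep_$subject_rates$pct_errors +
                 rep_$subject_rates$pct_missed, 100)
})

test_that("malformed rows are reported with their positions", {
  tr <- make_subject("S1", rep(c("correct", "incorrect"), 2))
  tr$response[2] <- "hmm"
  expect_error(validate_dataset(tr), "lines 2")
})

test_that("reading groups split at the 16th percentile, strict mode marks 16-25", {
  expect_equal(assign_reading_group(c(15.9, 16, 50)), c("PR", "TR", "TR"))
  expect_equal(assign_reading_group(20, strict = TRUE), "intermediate")
  expect_equal(assign_reading_group(c(10, 20, 26), strict = TRUE),
               c("PR", "intermediate", "TR"))
  expect_error(assign_reading_group(101), "\\[0, 100\\]")
})

test_that("bin summaries aggregate 10-trial blocks and exclude misses from accuracy", {
  task <- generate_task(task_config(), seed = 1)
  tr <- cbind(subject_id = "S1", group = "all", task,
              response = "correct", rt_s = 1.1, feedback = 1L,
              stringsAsFactors = FALSE)
  b <- bin_summaries(tr)
  expect_equal(nrow(b), 4L)
  expect_true(all(b$accuracy == 1))
  expect_true(all(b$n_trials == 20L))  # 10 trials x 2 runs
})

test_that("toy bins match a brute-force aggregation oracle", {
  resp <- c("correct", "incorrect", "correct", "correct",
            "missed", "correct", "incorrect", "correct")
  rts <- c(1.0, 1.5, 1.1, 1.3, NA, 0.9, 1.6, 1.2)
  tr <- make_subject("S1", resp, run_len = 8, rts = rts)
  b <- bin_summaries(tr, n_bins = 4)  # 2-trial bins
  # brute force, bin 1 = trials 1-2, ..., accuracy among responded
  expect_equal(b$accuracy, c(1/2, 1, 1/1, 1/2))
  expect_equal(b$rt_mean[1], 1.0)
  expect_equal(b$rt_mean[2], mean(c(1.1, 1.3)))
  expect_equal(b$rt_mean[3], 0.9)
  expect_equal(b$rt_mean[4], 1.2)
  expect_error(bin_summaries(make_subject("S1", rep("correct", 6), run_len = 6)),
               "divisible")
})

test_that("group contrast reproduces the Welch formula", {
  a <- c(1.1, 1.4, 0.9, 1.3)
  b <- c(1.8, 2.0, 1.7, 2.4, 1.9)
  ct <- group_contrast(a, b)
  # hand-computed Welch statistic
  se <- sqrt(var(a) / length(a) + var(b) / length(b))
  t_hand <- (mean(a) - mean(b)) / se
  df_hand <- se^4 / ((var(a) / length(a))^2 / (length(a) - 1) +
                     (var(b) / length(b))^2 / (length(b) - 1))
  expect_equal(ct$t, t_hand, tolerance = 1e-12)
  expect_equal(ct$df, df_hand, tolerance = 1e-12)
  expect_equal(ct$p, 2 * pt(-abs(t_hand), df_hand), tolerance = 1e-12)

  expect_equal(group_contrast(c(1, 1, 1), c(1, 1, 1))[c("t", "p")],
               list(t = 0, p = 1))
  sep <- group_contrast(c(0, 0, 0, 0) + rnorm(4, 0, 1e-6),
                        c(1, 1, 1, 1) + rnorm(4, 0, 1e-6))
  expect_gt(abs(sep$t), 50)
  expect_lt(sep$p, 0.001)
  expect_error(group_contrast(1, c(1, 2)), "at least 2")
})

test_that("trial CSV round-trips exactly, including missed trials", {
  co <- small_cohort(n = 2, seed = 9)
  tr <- co$trials
  tr$rt_s <- round(tr$rt_s, 4)  # the CSV dialect stores 4 decimals
  path <- tempfile(fileext = ".csv")
  write_trials(tr, path)
  back <- read_trials(path)
  expect_equal(back$rt_s, tr$rt_s)
  expect_identical(back$response, tr$response)
  expect_identical(back$subject_id, tr$subject_id)
  expect_identical(as.integer(back$feedback), as.integer(tr$feedback))
  expect_identical(back$pair_id, tr$pair_id)
  expect_identical(back$foil_pair_id, tr$foil_pair_id)
})

test_that("CLI simulate and summarize run end to end", {
  out_dir <- tempfile("cli")
  cfg_path <- tempfile(fileext = ".yaml")
  writeLines(c(
    "task:",
    "  n_runs: 2",
    "  trials_per_run: 40",
    "variant_id: 4",
    "cohort:",
    "  seed: 3",
    "  groups:",
    "    TR: {preset: TR, n_subjects: 3}",
    "    PR: {preset: PR, n_subjects: 2}"
  ), cfg_path)
  suppressMessages(rlddm_cli(c("simulate", "--config", cfg_path,
                               "--out-dir", out_dir, "--seed", "3")))
  expect_true(file.exists(file.path(out_dir, "trials.csv")))
  tr <- read_trials(file.path(out_dir, "trials.csv"))
  expect_equal(nrow(tr), 5L * 80L)
  expect_setequal(unique(tr$group), c("TR", "PR"))

  suppressMessages(rlddm_cli(c("summarize", "--trials",
                               file.path(out_dir, "trials.csv"),
                               "--out-dir", out_dir)))
  expect_true(file.exists(file.path(out_dir, "bin_summaries.csv")))
  expect_true(file.exists(file.path(out_dir, "group_contrasts.json")))
  b <- utils::read.csv(file.path(out_dir, "bin_summaries.csv"))
  expect_equal(nrow(b), 8L)  # 2 groups x 4 bins
})
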