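# shared fixtures, all generated in code

# tiny deterministic trial table for one subject (no simulation involved)
toy_trials <- function(outcomes = c(1, 0, 1),
                       rts = rep_len(c(1.2, 1.4, 1.1), length(outcomes)),
                       pair = "r1p1") {
  n <- length(outcomes)
  data.frame(
    subject_id = "S001", group = "all", run = 1L, trial = seq_len(n),
    pair_id = pair,
    response = ifelse(outcomes == 1, "correct", "incorrect"),
    rt_s = rts, feedback = outcomes, stringsAsFactors = FALSE
  )
}

# hand-rolled delta-rule trace, independent of the package internals
delta_rule_trace <- function(outcomes, eta, as0 = 0.5) {
  as_before <- numeric(length(outcomes))
  pe <- numeric(length(outcomes))
  a <- as0
  for (i in seq_along(outcomes)) {
    as_before[i] <- a
    pe[i] <- outcomes[i] - a
    a <- a + eta * pe[i]
  }
  list(as_before = as_before, pe = pe, as_after = a)
}

# small simulated cohort used by several inference tests
small_cohort <- function(n = 6, seed = 42, variant_id = 4) {
  spec <- cohort_spec(list(all = default_group_hyperparameters("all")),
                      c(all = n), variant_id = variant_id, seed = seed)
  simulate_cohort(spec)
}

# quick sampler settings for smoke-level fits (not used for acceptance)
tiny_mcmc <- function() mcmc_config("desk", chains = 2, iter = 700,
                                    warmup = 400, thin = 1)
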