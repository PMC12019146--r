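test_that("density integrates to the closed-form absorption probability", {
  grid <- expand.grid(v = c(-2, 0, 2), a = c(1, 3), z = c(0.25, 0.5, 0.75))
  for (i in seq_len(nrow(grid))) {
    v <- grid$v[i]; a <- grid$a[i]; z <- grid$z[i]
    p_up <- stats::integrate(function(t)
      exp(wfpt_log_density(t, TRUE, v, a, z, tau = 0)), 0, Inf,
      rel.tol = 1e-9)$value
    p_lo <- stats::integrate(function(t)
      exp(wfpt_log_density(t, FALSE, v, a, z, tau = 0)), 0, Inf,
      rel.tol = 1e-9)$value
    expect_equal(p_up, upper_probability(v, a, z), tolerance = 1e-3)
    expect_equal(p_up + p_lo, 1, tolerance = 1e-4)
  }
})

test_that("closed-form absorption probability matches its limits and printed value", {
  expect_equal(upper_probability(0, 2, 0.3), 0.3)
  expect_equal(upper_probability(50, 2, 0.5), 1, tolerance = 1e-8)
  expect_equal(upper_probability(1, 2, 0.5), (1 - exp(-2)) / (1 - exp(-4)),
               tolerance = 1e-12)
})

test_that("reflection symmetry holds to machine precision", {
  for (v in c(-1.3, 0.4, 2)) for (z in c(0.2, 0.5, 0.8)) for (rt in c(0.3, 1, 2.2)) {
    expect_equal(wfpt_log_density(rt, FALSE, v, 2.4, z, 0),
                 wfpt_log_density(rt, TRUE, -v, 2.4, 1 - z, 0),
                 tolerance = 1e-13)
  }
})

test_that("driftless symmetric diffusion gives identical densities for both responses", {
  rts <- c(0.2, 0.7, 1.5, 3)
  expect_equal(wfpt_log_density(rts, TRUE, 0, 2, 0.5, 0),
               wfpt_log_density(rts, FALSE, 0, 2, 0.5, 0))
})

test_that("RTs at or below the nondecision time are impossible", {
  expect_identical(wfpt_log_density(0.49, TRUE, 1, 2, 0.5, tau = 0.5), -Inf)
  expect_identical(wfpt_log_density(0.5, TRUE, 1, 2, 0.5, tau = 0.5), -Inf)
  expect_equal(wfpt_log_density(0.49, TRUE, 1, 2, 0.5, tau = 0.5, floor = TRUE),
               -700)
  # stable down to very short decision times
  expect_true(is.finite(wfpt_log_density(0.5 + 1e-4, TRUE, 1, 2, 0.5, 0.5)))
})

test_that("invalid diffusion geometry is rejected", {
  expect_error(wfpt_log_density(1, TRUE, 1, -2, 0.5, 0), "boundary")
  expect_error(wfpt_log_density(1, TRUE, 1, 2, 1.2, 0), "z")
})

test_that("sequence likelihood reduces to the single-trial density", {
  tr <- toy_trials(outcomes = 1, rts = 1.2)
  p <- list(eta = 0.2, a_base = 2.5, a_mod = 0.1, tau = 0.4, z = 0.6,
            v_mod = 1.1)
  res <- trial_sequence_loglik(tr, p, 4)
  drift1 <- 1.1 * (0.5 + 0.5) / 2  # both associations at the 0.5 start
  expect_equal(res$total,
               wfpt_log_density(1.2, TRUE, drift1, 2.5, 0.6, 0.4))
  expect_length(res$pointwise, 1)
})

test_that("sequence likelihood replays the hand-rolled delta-rule trace", {
  outcomes <- c(1, 0, 1)
  tr <- toy_trials(outcomes = outcomes)
  p <- list(eta = 0.2, a_base = 3, a_mod = 0.05, tau = 0.4, z = 0.6, v_mod = 1)
  res <- trial_sequence_loglik(tr, p, 4)
  oracle <- delta_rule_trace(outcomes, eta = 0.2)
  expect_equal(res$as, c(0.5, 0.6, 0.48))
  expect_equal(res$as, oracle$as_before)
  expect_equal(res$pe, oracle$pe)
  expect_equal(0.48 + 0.2 * (1 - 0.48), 0.584)  # state after the last trial
  # per-trial drift follows the trace (single pairing; foil rests at 0.5)
  expect_equal(res$drift, 1 * (oracle$as_before + 0.5) / 2)
  expect_equal(res$boundary, 3 * (1:3)^0.05)
  expect_equal(res$total, sum(res$pointwise))
})

test_that("missed trials are skipped (exclude) or censored on request", {
  tr <- toy_trials(outcomes = c(1, 1), rts = c(1.2, 1.4))
  tr$response[2] <- "missed"; tr$rt_s[2] <- NA; tr$feedback[2] <- NA
  p <- list(eta = 0.2, a_base = 2.5, a_mod = 0.1, tau = 0.4, z = 0.6, v_mod = 1)

  res <- trial_sequence_loglik(tr, p, 4)
  expect_length(res$pointwise, 1)
  expect_true(is.na(res$pe[2]))
  expect_equal(res$censor_loglik, 0)

  # all trials missed: empty pointwise, zero total
  tr2 <- tr; tr2$response <- "missed"; tr2$rt_s <- NA; tr2$feedback <- NA
  res2 <- trial_sequence_loglik(tr2, p, 4)
  expect_length(res2$pointwise, 0)
  expect_equal(res2$total, 0)

  # censoring adds the survival mass; oracle by numerical integration
  resc <- trial_sequence_loglik(tr, p, 4, missed = "censor", deadline = 2.5)
  drift2 <- 1 * (0.6 + 0.5) / 2  # AS after the first correct trial
  bound2 <- 2.5 * 2^0.1
  tmax <- 2.5 - 0.4
  absorbed <- stats::integrate(function(t)
    exp(wfpt_log_density(t, TRUE, drift2, bound2, 0.6, 0)) +
      exp(wfpt_log_density(t, FALSE, drift2, bound2, 0.6, 0)),
    0, tmax, rel.tol = 1e-10)$value
  expect_equal(resc$censor_loglik, log(1 - absorbed), tolerance = 1e-6)
  expect_equal(resc$total, sum(resc$pointwise) + resc$censor_loglik)
})

test_that("inadmissible nondecision time floors or kills the likelihood", {
  tr <- toy_trials(outcomes = 1, rts = 0.3)
  p <- list(eta = 0.2, a_base = 2.5, a_mod = 0.1, tau = 0.4, z = 0.6, v_mod = 1)
  expect_identical(trial_sequence_loglik(tr, p, 4)$total, -Inf)
  expect_equal(trial_sequence_loglik(tr, p, 4, floor = TRUE)$total, -700)
})

test_that("unordered or malformed trial tables are rejected", {
  tr <- toy_trials()
  expect_error(trial_sequence_loglik(tr[c(2, 1, 3), ],
                                     list(eta = 0.2, a_base = 2, a_mod = 0.1,
                                          tau = 0.3, z = 0.5, v_mod = 1), 4),
               "ordered")
  tr2 <- tr; tr2$response[1] <- "typo"
  expect_error(trial_sequence_loglik(tr2,
                                     list(eta = 0.2, a_base = 2, a_mod = 0.1,
                                          tau = 0.3, z = 0.5, v_mod = 1), 4),
               "response")
})

test_that("density-implied CDF matches simulated first passages", {
  # moderate n here; the acceptance suite runs the full-size comparison
  set.seed(7)
  s <- sample_first_passage(1, 2, 0.5, tau = 0.3, deadline = 30, n = 20000)
  rtc <- sort(s$rt[s$response == "correct"] - 0.3)
  gridt <- seq(0, 30, length.out = 6000)
  dens <- exp(wfpt_log_density(pmax(gridt, 1e-9), TRUE, 1, 2, 0.5, 0))
  cdf_grid <- cumsum((dens[-1] + dens[-length(dens)]) / 2 * diff(gridt))
  cdf_grid <- cdf_grid / upper_probability(1, 2, 0.5)
  cdf_at <- stats::approx(gridt[-1], cdf_grid, xout = rtc, rule = 2)$y
  n <- length(rtc)
  ks <- max(pmax(abs(seq_len(n) / n - cdf_at), abs((seq_len(n) - 1) / n - cdf_at)))
  expect_lt(ks, 0.015)
})
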