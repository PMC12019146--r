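test_that("split R-hat flags separated chains and passes matched ones", {
  set.seed(21)
  ok <- matrix(rnorm(4000), 2000, 2)
  expect_lt(abs(compute_rhat(ok) - 1), 0.01)

  bad <- cbind(rnorm(500, 0), rnorm(500, 10))
  expect_gt(compute_rhat(bad), 1.5)

  const <- matrix(1, 100, 2)
  r <- compute_rhat(const)
  expect_equal(as.numeric(r), 1)
  expect_true(isTRUE(attr(r, "zero_variance")))

  expect_error(compute_rhat(matrix(1:10, ncol = 1)), "2 chains")
  arr <- array(rnorm(4000), c(1000, 2, 2), dimnames = list(NULL, NULL, c("a", "b")))
  rr <- compute_rhat(arr)
  expect_named(rr, c("a", "b"))
})

test_that("a short hierarchical fit produces well-formed output", {
  co <- small_cohort(n = 5, seed = 12)
  fit <- suppressWarnings(fit_hierarchical(co$trials, 4, tiny_mcmc(), seed = 12))
  expect_s3_class(fit, "rlddm_fit")
  expect_equal(length(fit$subjects), 5L)
  expect_equal(ncol(fit$pointwise),
               sum(co$trials$response != "missed"))
  expect_equal(nrow(fit$pointwise), 2 * 300L)
  expect_true(all(is.finite(fit$pointwise)))
  expect_named(fit$rhat)
  expect_true(all(is.finite(fit$rhat)))

  g <- summarize_group_parameters(fit)
  expect_setequal(g$parameter, c("eta", "a_base", "a_mod", "tau", "z", "v_mod"))
  expect_true(all(g$q2.5 <= g$mean & g$mean <= g$q97.5))

  s <- summarize_subject_parameters(fit)
  expect_equal(nrow(s), 5L * 6L)
  # natural-scale bounds respected
  expect_true(all(s$mean[s$parameter %in% c("eta", "z", "a_mod")] > 0))
  expect_true(all(s$mean[s$parameter %in% c("eta", "z", "a_mod")] < 1))
  expect_true(all(s$mean[s$parameter %in% c("a_base", "tau", "v_mod")] > 0))
})

test_that("two-rate and static-boundary variants fit with matching parameter sets", {
  co <- small_cohort(n = 3, seed = 13)
  fit1 <- suppressWarnings(fit_hierarchical(co$trials, 1,
                                            mcmc_config("desk", chains = 2,
                                                        iter = 220, warmup = 150,
                                                        thin = 1),
                                            seed = 13))
  expect_setequal(fit1$param_names,
                  c("eta_pos", "eta_neg", "a_base", "a_mod", "tau", "z", "v_mod"))
  fit6 <- suppressWarnings(fit_hierarchical(co$trials, 6,
                                            mcmc_config("desk", chains = 2,
                                                        iter = 220, warmup = 150,
                                                        thin = 1),
                                            seed = 13))
  expect_setequal(fit6$param_names, c("eta", "a_base", "tau", "z", "v_mod"))
  series6 <- extract_trialwise_series(fit6, co$trials, max_draws = 50)
  bnd <- tapply(series6$boundary_mean, series6$subject_id,
                function(x) diff(range(x)))
  expect_true(all(bnd < 1e-12))  # static boundary is constant per subject
})

test_that("single-subject datasets fall back to fixed weak priors with a warning", {
  co <- small_cohort(n = 1, seed = 14)
  w <- capture_warnings(
    fit <- fit_hierarchical(co$trials, 4, tiny_mcmc(), seed = 14)
  )
  expect_true(any(grepl("single-subject", w)))
  expect_false(fit$hierarchical)
  expect_error(summarize_group_parameters(fit), "group level")
})

test_that("subjects with zero responded trials are rejected", {
  co <- small_cohort(n = 2, seed = 15)
  tr <- co$trials
  s1 <- tr$subject_id == "S001"
  tr$response[s1] <- "missed"; tr$rt_s[s1] <- NA; tr$feedback[s1] <- NA
  expect_error(fit_hierarchical(tr, 4, tiny_mcmc()), "zero responded")
})

test_that("trial-wise series replay the generative recursion", {
  co <- small_cohort(n = 3, seed = 16)
  fit <- suppressWarnings(fit_hierarchical(co$trials, 4, tiny_mcmc(), seed = 16))
  series <- extract_trialwise_series(fit, co$trials, max_draws = 60)
  expect_equal(nrow(series), nrow(co$trials))
  expect_true(all(series$as_mean >= 0 & series$as_mean <= 1))
  expect_true(all(series$boundary_mean > 0))
  missed <- co$trials$response == "missed"
  expect_true(all(is.na(series$pe_mean[missed])))
  expect_true(all(!is.na(series$pe_mean[!missed])))
  # alignment with the trial table
  expect_equal(series$run, co$trials$run)
  expect_equal(series$trial, co$trials$trial)
  expect_error(extract_trialwise_series(fit, co$trials[1:80, ]), "match")
})

test_that("with the learning rate pinned near zero the PE series is outcome minus 0.5", {
  tr <- toy_trials(outcomes = c(1, 0, 1, 1))
  p <- list(eta = 1e-9, a_base = 2.5, a_mod = 0.1, tau = 0.4, z = 0.6, v_mod = 1)
  res <- trial_sequence_loglik(tr, p, 4)
  expect_equal(res$pe, c(1, 0, 1, 1) - 0.5, tolerance = 1e-6)
})

test_that("the likelihood is maximized near the generating parameters", {
  # simulator-likelihood consistency: coarse profile around the truth on a
  # large single-subject dataset (many runs of fresh pairings)
  cfg <- task_config(n_runs = 12)
  task <- generate_task(cfg, seed = 18)
  p0 <- list(eta = 0.19, a_base = 2.746, a_mod = 0.052, tau = 0.73,
             z = 0.75, v_mod = 0.97)
  beh <- simulate_subject(p0, task, 4, seed = 18)
  ll <- function(p) trial_sequence_loglik(beh, p, 4, missed = "censor")$total
  base <- ll(p0)
  for (par in c("tau", "z", "v_mod", "a_base")) {
    for (f in c(0.7, 1.3)) {
      p1 <- p0
      p1[[par]] <- p0[[par]] * f
      if (par == "z") p1$z <- min(p1$z, 0.97)
      if (par == "tau") p1$tau <- min(p1$tau, 1.0)
      expect_lt(ll(p1), base)
    }
  }
})

test_that("prior-predictive draws keep RTs in a plausible range", {
  set.seed(19)
  n_bad <- 0; n_tot <- 0
  for (i in 1:30) {
    mu <- rnorm(6, 0, 1.5); sig <- abs(rnorm(6, 0, 0.5))
    x <- rnorm(6, mu, sig)
    p <- list(eta = plogis(x[1]), a_base = exp(x[2]), a_mod = plogis(x[3]),
              tau = exp(x[4]), z = plogis(x[5]), v_mod = exp(x[6]))
    if (p$tau > 9) next  # cannot respond at all within the window
    s <- sample_first_passage(p$v_mod * 0.5, p$a_base, p$z, p$tau,
                              deadline = 10, n = 20)
    resp <- s$response != "missed"
    n_tot <- n_tot + sum(resp)
    n_bad <- n_bad + sum(s$rt[resp] <= 0 | s$rt[resp] > 10)
  }
  expect_lt(n_bad / n_tot, 0.01)
})
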