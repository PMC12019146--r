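# parameter scales: each RLDDM parameter lives on an unconstrained scale
# for hierarchical modelling (log for positive parameters, logit for
# unit-interval parameters)
.param_transforms <- c(eta = "logit", eta_pos = "logit", eta_neg = "logit",
                       a_base = "log", a_mod = "logit", tau = "log",
                       z = "logit", v_mod = "log")

.to_unconstrained <- function(x, transform) {
  switch(transform, log = log(x), logit = qlogis(x), stop("bad transform"))
}
.from_unconstrained <- function(x, transform) {
  switch(transform, log = exp(x), logit = plogis(x), stop("bad transform"))
}

# parameter names used by a given variant, in canonical order
.variant_param_names <- function(variant) {
  c(if (variant$n_learning_rates == 2L) c("eta_pos", "eta_neg") else "eta",
    "a_base",
    if (variant$boundary_mapping != "static") "a_mod",
    "tau", "z", "v_mod")
}

#' Group-level hyperparameters
#'
#' Means and spreads of the subject-parameter distribution of one group,
#' given on the natural scale and stored on the unconstrained scale (log for
#' `a_base`, `tau`, `v_mod`; logit for `eta`, `z`, `a_mod`). Natural-scale
#' means are mapped through the transform; natural-scale SDs are mapped by
#' the delta method (`sd / |d transform^{-1}|` at the mean).
#'
#' @param mean Named numeric vector of natural-scale group means (names from
#'   `eta`/`eta_pos`/`eta_neg`, `a_base`, `a_mod`, `tau`, `z`, `v_mod`).
#' @param sd Named numeric vector of natural-scale group SDs (same names);
#'   zeros are allowed and produce a degenerate (shared-parameter) group.
#' @return Object of class `rlddm_hyperparameters` with unconstrained-scale
#'   `mu` and `sigma` plus the natural-scale inputs.
#' @export
group_hyperparameters <- function(mean, sd) {
  if (is.null(names(mean)) || is.null(names(sd))) {
    stop("`mean` and `sd` must be named")
  }
  bad <- setdiff(names(mean), names(.param_transforms))
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  if (!setequal(names(mean), names(sd))) stop("`mean`/`sd` names must match")
  sd <- sd[names(mean)]
  if (any(sd < 0)) stop("group spreads must be non-negative")
  tr <- .param_transforms[names(mean)]
  mu <- mapply(.to_unconstrained, mean, tr)
  deriv <- ifelse(tr == "log", mean, mean * (1 - mean))  # d inv-transform
  sigma <- ifelse(sd == 0, 0, sd / deriv)
  structure(list(mu = mu, sigma = sigma, natural_mean = mean,
                 natural_sd = sd),
            class = "rlddm_hyperparameters")
}

#' Reference generating hyperparameters for the study groups
#'
#' Returns the group-level subject-parameter distributions used as the
#' package's reference study conditions for the single-learning-rate,
#' exponential-boundary model: the full sample, the typical-reader (TR)
#' group and the poor-reader (PR) group. Means and SDs of `tau`, `eta`,
#' `v_mod` and `z` are the reported sample summaries of the fitted model;
#' `a_mod` and `a_base` are derived from the reported bin-wise boundary
#' trajectory and the trial-averaged boundary summary (see the methods
#' vignette for the derivation).
#'
#' @param group `"all"`, `"TR"` or `"PR"`.
#' @return An [group_hyperparameters()] object.
#' @export
#' @examples
#' default_group_hyperparameters("all")$natural_mean
default_group_hyperparameters <- function(group = c("all", "TR", "PR")) {
  group <- match.arg(group)
  tab <- list(
    all = list(mean = c(eta = 0.19, a_base = 2.746, a_mod = 0.052,
                        tau = 0.73, z = 0.75, v_mod = 0.97),
               sd = c(eta = 0.002, a_base = 0.113, a_mod = 0.010,
                      tau = 0.13, z = 0.01, v_mod = 0.32)),
    TR = list(mean = c(eta = 0.19, a_base = 2.746, a_mod = 0.053,
                       tau = 0.70, z = 0.75, v_mod = 0.98),
              sd = c(eta = 0.002, a_base = 0.112, a_mod = 0.010,
                     tau = 0.13, z = 0.01, v_mod = 0.32)),
    PR = list(mean = c(eta = 0.19, a_base = 2.742, a_mod = 0.049,
                       tau = 0.77, z = 0.75, v_mod = 0.94),
              sd = c(eta = 0.002, a_base = 0.096, a_mod = 0.010,
                     tau = 0.10, z = 0.01, v_mod = 0.28))
  )[[group]]
  group_hyperparameters(tab$mean, tab$sd)
}

#' Sample a first passage of the decision diffusion
#'
#' Forward-simulates the diffusion between the error boundary (0) and the
#' correct boundary (`boundary`), starting at `z * boundary`, with drift
#' `drift` toward the correct boundary. The default backend is
#' Euler--Maruyama with step `dt`; crossings missed between steps bias
#' plain Euler passages long, so the barriers are pulled in by the standard
#' continuity correction `0.5826 * sqrt(dt)`, leaving a residual bias well
#' below Monte-Carlo noise at the default step.
#' `method = "exact"` draws the boundary from the closed-form
#' absorption probability and the passage time by numerical inversion of the
#' first-passage CDF. Passages not absorbed by `deadline` are missed.
#'
#' @inheritParams wfpt_log_density
#' @param deadline Response deadline in seconds (> `tau`).
#' @param n Number of draws.
#' @param seed Optional integer seed.
#' @param method `"euler"` or `"exact"`.
#' @param dt Euler step in seconds.
#' @return Data frame with `response` (`"correct"`, `"incorrect"`,
#'   `"missed"`) and `rt` (seconds; `NA` when missed).
#' @export
#' @examples
#' sample_first_passage(1, 2, 0.5, 0.3, 2.5, n = 5, seed = 1)
sample_first_passage <- function(drift, boundary, z, tau, deadline, n = 1,
                                 seed = NULL, method = c("euler", "exact"),
                                 dt = 0.001) {
  method <- match.arg(method)
  if (deadline <= tau) stop("`deadline` must exceed `tau`")
  if (boundary <= 0 || z <= 0 || z >= 1 || tau < 0) {
    stop("inadmissible diffusion parameters")
  }
  if (!is.null(seed)) set.seed(seed)
  if (method == "euler") {
    res <- .euler_fp_cpp(as.integer(n), drift, boundary, z, tau, deadline, dt)
    resp <- c("missed", "incorrect", "correct")[res$response + 2L]
    return(data.frame(response = resp, rt = res$rt, stringsAsFactors = FALSE))
  }
  # exact backend: boundary by closed form, passage time by CDF inversion
  p_up <- upper_probability(drift, boundary, z)
  resp <- character(n); rt <- rep(NA_real_, n)
  tmax <- deadline - tau
  for (i in seq_len(n)) {
    up <- runif(1) < p_up
    dens <- function(t) {
      exp(wfpt_log_density(t, up, drift, boundary, z, tau = 0))
    }
    p_resp <- if (up) p_up else 1 - p_up
    mass_by <- stats::integrate(Vectorize(dens), 0, tmax,
                                rel.tol = 1e-8, stop.on.error = FALSE)$value
    u <- runif(1) * p_resp
    if (u >= mass_by) { resp[i] <- "missed"; next }
    f <- function(t) {
      stats::integrate(Vectorize(dens), 0, t, rel.tol = 1e-8,
                       stop.on.error = FALSE)$value - u
    }
    t_hit <- stats::uniroot(f, c(1e-6, tmax), tol = 1e-6)$root
    resp[i] <- if (up) "correct" else "incorrect"
    rt[i] <- tau + t_hit
  }
  data.frame(response = resp, rt = rt, stringsAsFactors = FALSE)
}

#' Simulate one subject on a task layout
#'
#' Runs the full generative loop: per trial the drift and boundary are
#' derived from the current associative state, a response and RT are drawn
#' from the diffusion, feedback is 1 iff the response is correct
#' (deterministic pairings), and the trial's pairing is updated by the delta
#' rule. Associative strengths reset to 0.5 at each run start. Missed trials
#' receive no feedback and trigger no update.
#'
#' @param params Named list of subject parameters (see
#'   [trial_sequence_loglik()]).
#' @param task Trial skeleton from [generate_task()].
#' @param variant An `rlddm_variant` or id.
#' @param seed Integer seed for the behavioral noise.
#' @param deadline Response deadline in seconds.
#' @param dt Euler step in seconds.
#' @return The task data frame extended with `response`, `rt_s`, `feedback`.
#' @export
simulate_subject <- function(params, task, variant, seed = 1L,
                             deadline = NULL, dt = 0.001) {
  if (!inherits(variant, "rlddm_variant")) variant <- get_variant(variant)
  if (is.null(deadline)) deadline <- attr(task, "deadline")
  if (is.null(deadline)) deadline <- 2.5
  pv <- .params_vector(params, variant)
  if (deadline <= params$tau) stop("`deadline` must exceed `tau`")
  pairs <- sort(unique(as.character(task$pair_id)))
  foil_idx <- if ("foil_pair_id" %in% names(task)) {
    f <- match(as.character(task$foil_pair_id), pairs)
    as.integer(ifelse(is.na(f), 0L, f))
  } else rep(0L, nrow(task))
  set.seed(seed)
  res <- .sim_subject_cpp(as.integer(task$run), as.integer(task$trial),
                          match(as.character(task$pair_id), pairs),
                          foil_idx,
                          length(pairs), pv,
                          .mapping_cpp(variant$boundary_mapping),
                          deadline, dt, AS_INIT)
  out <- task
  out$response <- c("missed", "incorrect", "correct")[res$response + 2L]
  out$rt_s <- res$rt
  out$feedback <- res$feedback
  out
}

#' Cohort specification
#'
#' @param hyper Named list of [group_hyperparameters()] objects, one per
#'   group (names are the group labels, e.g. `TR`, `PR`).
#' @param n_subjects Named integer vector, subjects per group (same names).
#' @param variant_id Model variant generating the behavior.
#' @param seed Master seed; task layout, parameter draws and behavioral
#'   noise use independent substreams derived from it.
#' @param task An [task_config()].
#' @param balanced If `TRUE`, subject parameters are drawn by stratified
#'   inverse-CDF sampling (normal quantile midpoints in random order,
#'   independently permuted per parameter) instead of independent draws.
#'   The marginal distribution is the same, but the cohort's sample mean
#'   matches the group mean exactly on the unconstrained scale, so
#'   recovery experiments measure estimation error rather than cohort
#'   sampling noise. Default `FALSE` (independent draws).
#' @return Object of class `rlddm_cohort_spec`.
#' @export
cohort_spec <- function(hyper, n_subjects, variant_id = 4, seed = 1L,
                        task = task_config(), balanced = FALSE) {
  if (is.null(names(hyper)) || !setequal(names(hyper), names(n_subjects))) {
    stop("`hyper` and `n_subjects` must share group names")
  }
  if (any(n_subjects < 1)) stop("need at least one subject per group")
  for (h in hyper) {
    stopifnot(inherits(h, "rlddm_hyperparameters"))
    if (any(h$sigma < 0)) stop("group spreads must be non-negative")
  }
  structure(list(hyper = hyper, n_subjects = n_subjects,
                 variant_id = variant_id, seed = as.integer(seed),
                 task = task, balanced = isTRUE(balanced)),
            class = "rlddm_cohort_spec")
}

#' Simulate a multi-group cohort
#'
#' Draws each subject's parameters from their group's hyperdistribution on
#' the unconstrained scale, generates a freshly randomized task layout per
#' subject, and forward-simulates the behavior. Fully reproducible from the
#' spec's master seed through per-subject substreams.
#'
#' @param spec An [cohort_spec()].
#' @param dt Euler step for the diffusion simulator.
#' @return A list of class `rlddm_cohort` with `trials` (the pooled trial
#'   table), `subject_params` (natural-scale generating parameters per
#'   subject) and the `spec`.
#' @export
#' @examples
#' spec <- cohort_spec(list(all = default_group_hyperparameters("all")),
#'                     c(all = 3), variant_id = 4, seed = 1)
#' cohort <- simulate_cohort(spec)
#' table(cohort$trials$subject_id)
simulate_cohort <- function(spec, dt = 0.001) {
  stopifnot(inherits(spec, "rlddm_cohort_spec"))
  variant <- get_variant(spec$variant_id)
  pn <- .variant_param_names(variant)
  trials <- list(); pars <- list()
  sub_counter <- 0L
  for (gi in seq_along(spec$hyper)) {
    g <- names(spec$hyper)[gi]
    h <- spec$hyper[[g]]
    missing_p <- setdiff(pn, names(h$mu))
    if (length(missing_p)) {
      stop("hyperparameters for group ", g, " lack: ",
           paste(missing_p, collapse = ", "))
    }
    ng <- spec$n_subjects[[g]]
    Xg <- NULL
    if (isTRUE(spec$balanced)) {
      # stratified draws: quantile midpoints, randomly permuted per
      # parameter, so the cohort mean equals the group mean exactly
      set.seed(.mix_seed(spec$seed, gi, 23L))
      Xg <- vapply(seq_along(pn), function(k) {
        h$mu[[pn[k]]] +
          h$sigma[[pn[k]]] * qnorm((sample(ng) - 0.5) / ng)
      }, numeric(ng))
      if (ng == 1L) Xg <- matrix(Xg, 1L)
    }
    for (j in seq_len(ng)) {
      sub_counter <- sub_counter + 1L
      sid <- sprintf("S%03d", sub_counter)
      if (is.null(Xg)) {
        set.seed(.mix_seed(spec$seed, sub_counter, 3L))
        x <- rnorm(length(pn), h$mu[pn], h$sigma[pn])
      } else {
        x <- Xg[j, ]
      }
      p <- mapply(.from_unconstrained, x, .param_transforms[pn])
      names(p) <- pn
      # keep tau inside the response window so the subject can respond
      p[["tau"]] <- min(p[["tau"]], spec$task$deadline - 0.2)
      task <- generate_task(spec$task, seed = .mix_seed(spec$seed, sub_counter, 5L))
      beh <- simulate_subject(as.list(p), task, variant,
                              seed = .mix_seed(spec$seed, sub_counter, 7L),
                              deadline = spec$task$deadline, dt = dt)
      beh <- cbind(subject_id = sid, group = g, beh, stringsAsFactors = FALSE)
      trials[[sub_counter]] <- beh
      pars[[sub_counter]] <- data.frame(subject_id = sid, group = g,
                                        t(p), stringsAsFactors = FALSE)
    }
  }
  structure(list(trials = do.call(rbind, trials),
                 subject_params = do.call(rbind, pars),
                 spec = spec),
            class = "rlddm_cohort")
}
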