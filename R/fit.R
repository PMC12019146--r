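#' MCMC sampler settings
#'
#' Two presets are provided. `"desk"` (the default everywhere) runs 2 chains
#' with 1,000 retained draws each and is sized for interactive use;
#' `"paper"` runs 4 chains of 10,000 iterations with 4,000 warm-up sweeps,
#' retaining every second draw. `thin` counts sampler sweeps between
#' retained draws; warm-up sweeps adapt the proposal scales and are
#' discarded.
#'
#' @param preset `"desk"` or `"paper"`.
#' @param chains,iter,warmup,thin Optional overrides; `iter` is the total
#'   number of sweeps per chain including warm-up, so each chain retains
#'   `(iter - warmup) / thin` draws.
#' @return Object of class `rlddm_mcmc_config`.
#' @export
#' @examples
#' mcmc_config("desk")
mcmc_config <- function(preset = c("desk", "paper"), chains = NULL,
                        iter = NULL, warmup = NULL, thin = NULL) {
  preset <- match.arg(preset)
  cfg <- if (preset == "desk") {
    list(chains = 2L, iter = 8500L, warmup = 2500L, thin = 6L)
  } else {
    list(chains = 4L, iter = 10000L, warmup = 4000L, thin = 2L)
  }
  if (!is.null(chains)) cfg$chains <- as.integer(chains)
  if (!is.null(iter)) cfg$iter <- as.integer(iter)
  if (!is.null(warmup)) cfg$warmup <- as.integer(warmup)
  if (!is.null(thin)) cfg$thin <- as.integer(thin)
  if (cfg$warmup >= cfg$iter) stop("`warmup` must be smaller than `iter`")
  if (cfg$chains < 1 || cfg$thin < 1) stop("invalid sampler settings")
  cfg$keep <- (cfg$iter - cfg$warmup) %/% cfg$thin
  structure(c(cfg, list(preset = preset)), class = "rlddm_mcmc_config")
}

# prior hyperparameters (weakly informative, standard for hierarchical
# sequential-sampling models): unconstrained group means ~ Normal(0, 1.5),
# group spreads ~ Half-Normal(0.5)
.PRIOR_MU_SD <- 1.5
.PRIOR_SIGMA_SCALE <- 0.5

# per-subject data in the integer layout the C++ likelihood expects
.subject_data <- function(tr) {
  tr <- tr[order(tr$run, tr$trial), , drop = FALSE]
  pairs <- sort(unique(as.character(tr$pair_id)))
  status <- match(as.character(tr$response),
                  c("missed", "correct", "incorrect")) - 1L
  responded <- status != 0L
  foil_idx <- if ("foil_pair_id" %in% names(tr)) {
    f <- match(as.character(tr$foil_pair_id), pairs)
    ifelse(is.na(f), 0L, f)
  } else rep(0L, nrow(tr))
  list(run = as.integer(tr$run), trial = as.integer(tr$trial),
       pair_idx = match(as.character(tr$pair_id), pairs),
       foil_idx = as.integer(foil_idx),
       status = status,
       feedback = ifelse(responded, as.integer(tr$feedback), 0L),
       n_pairs = length(pairs),
       rt = ifelse(responded, as.numeric(tr$rt_s), 0),
       n_responded = sum(responded),
       min_rt = if (any(responded)) min(tr$rt_s[responded]) else NA_real_)
}

# unconstrained subject vector -> total log likelihood (floored)
.subject_loglik <- function(x, sd_, pn, mapping_cpp, n_rates,
                            deadline = 2.5, missed_mode = 1L) {
  nat <- vapply(seq_along(pn),
                function(k) .from_unconstrained(x[k], .param_transforms[[pn[k]]]),
                numeric(1))
  names(nat) <- pn
  pv <- c(if (n_rates == 2L) c(nat[["eta_pos"]], nat[["eta_neg"]])
          else rep(nat[["eta"]], 2),
          nat[["a_base"]],
          if ("a_mod" %in% pn) nat[["a_mod"]] else 0,
          nat[["tau"]], nat[["z"]], nat[["v_mod"]])
  .seq_loglik_cpp(sd_$run, sd_$trial, sd_$pair_idx, sd_$foil_idx, sd_$status,
                  sd_$feedback, sd_$n_pairs, pv, mapping_cpp, TRUE, sd_$rt,
                  AS_INIT, deadline, missed_mode)
}

# slice sampler for one group spread on the log scale
.slice_sigma <- function(sigma, xs, mu) {
  n <- length(xs); ss <- sum((xs - mu)^2)
  logpost <- function(ls) {
    s <- exp(ls)
    -n * ls - ss / (2 * s^2) - s^2 / (2 * .PRIOR_SIGMA_SCALE^2) + ls
  }
  ls0 <- log(sigma)
  y <- logpost(ls0) - stats::rexp(1)
  w <- 1; lo <- ls0 - w * runif(1); hi <- lo + w
  for (i in 1:50) { if (logpost(lo) < y) break; lo <- lo - w }
  for (i in 1:50) { if (logpost(hi) < y) break; hi <- hi + w }
  for (i in 1:100) {
    ls1 <- runif(1, lo, hi)
    if (logpost(ls1) >= y) return(exp(ls1))
    if (ls1 < ls0) lo <- ls1 else hi <- ls1
  }
  sigma
}

#' Fit a hierarchical RLDDM
#'
#' Samples the joint posterior of group-level hyperparameters and subject
#' parameters for one model variant. Subject parameters live on
#' unconstrained scales (log/logit, see [group_hyperparameters()]) with
#' Normal group distributions; group means get Normal(0, 1.5) priors and
#' group spreads Half-Normal(0.5) priors. Each sweep combines (i)
#' component-wise adaptive random-walk Metropolis updates of the subject
#' parameters (scales tuned during warm-up to a 44% acceptance rate), (ii)
#' joint Metropolis moves per subject along the empirical posterior
#' covariance estimated during warm-up -- the drift modifier, boundary,
#' bias and nondecision time are strongly correlated, and axis-aligned
#' moves alone mix poorly along that ridge -- (iii) group-shift moves that
#' translate the group mean together with every subject along the pooled
#' covariance, (iv) an exact Gibbs draw of each group mean plus a
#' slice-sampling update of each group spread, and (v) interweaving moves
#' that re-propose each `(mu, sigma)` pair (and `sigma` alone) with the
#' subjects' standardized offsets held fixed, which breaks the funnel
#' coupling at small group spreads. Nondecision-time admissibility is
#' enforced through the likelihood (floored log density when `rt <= tau`).
#'
#' Missed trials are censored by default: each contributes the log
#' probability that the diffusion has not reached either boundary by the
#' deadline. Simply excluding them (`missed = "exclude"`) truncates the RT
#' distribution at the deadline and, at miss rates above a few percent,
#' biases the drift modifier up and the boundary, bias and learning rate
#' away from their generating values (see the methods vignette).
#'
#' Pointwise log densities of all responded trials are retained for every
#' kept draw, ready for WAIC. A warning is emitted when any split-R-hat
#' reaches 1.01.
#'
#' With a single subject the group spreads are unidentifiable; the fit then
#' warns and falls back to fixed weak priors (mean 0, spread 1.5) on the
#' subject's unconstrained parameters.
#'
#' @param dataset Trial table with columns `subject_id`, `run`, `trial`,
#'   `pair_id`, `response`, `rt_s`, `feedback` (an `rlddm_cohort` is also
#'   accepted).
#' @param variant An `rlddm_variant` or id in 1..6.
#' @param mcmc An [mcmc_config()].
#' @param seed Integer seed; chains use derived substreams.
#' @param missed Treatment of missed trials: `"censor"` (default) or
#'   `"exclude"`.
#' @param deadline Response deadline in seconds (the censoring point).
#' @param progress Print per-chain progress lines.
#' @return An object of class `rlddm_fit`; see [summarize_group_parameters()],
#'   [summarize_subject_parameters()], [extract_trialwise_series()],
#'   [compute_waic()].
#' @export
fit_hierarchical <- function(dataset, variant, mcmc = mcmc_config("desk"),
                             seed = 1L, missed = c("censor", "exclude"),
                             deadline = 2.5, progress = FALSE) {
  missed <- match.arg(missed)
  mm <- if (missed == "censor") 1L else 0L
  if (inherits(dataset, "rlddm_cohort")) dataset <- dataset$trials
  if (!inherits(variant, "rlddm_variant")) variant <- get_variant(variant)
  stopifnot(inherits(mcmc, "rlddm_mcmc_config"))
  req <- c("subject_id", "run", "trial", "pair_id", "response", "rt_s",
           "feedback")
  miss <- setdiff(req, names(dataset))
  if (length(miss)) stop("dataset lacks columns: ", paste(miss, collapse = ", "))

  subjects <- unique(as.character(dataset$subject_id))
  sdata <- lapply(subjects, function(s)
    .subject_data(dataset[dataset$subject_id == s, , drop = FALSE]))
  names(sdata) <- subjects
  n_resp <- vapply(sdata, `[[`, integer(1), "n_responded")
  if (any(n_resp == 0)) {
    stop("subject(s) with zero responded trials: ",
         paste(subjects[n_resp == 0], collapse = ", "))
  }
  n <- length(subjects)
  pn <- .variant_param_names(variant)
  d <- length(pn)
  mapping_cpp <- .mapping_cpp(variant$boundary_mapping)
  # fast likelihood closure: vectorized inverse transforms plus an index
  # template mapping the variant's parameter vector onto the 7 canonical
  # slots (eta_pos, eta_neg, a_base, a_mod, tau, z, v_mod); absent slots
  # point at the trailing zero
  islog <- .param_transforms[pn] == "log"
  slot_names <- c(if (variant$n_learning_rates == 2L) c("eta_pos", "eta_neg")
                  else c("eta", "eta"),
                  "a_base", "a_mod", "tau", "z", "v_mod")
  tmpl <- match(slot_names, pn)
  tmpl[is.na(tmpl)] <- d + 1L
  fast_ll <- function(x, sd_) {
    nat <- numeric(d)
    nat[islog] <- exp(x[islog])
    nat[!islog] <- plogis(x[!islog])
    .seq_total_cpp(sd_$run, sd_$trial, sd_$pair_idx, sd_$foil_idx,
                   sd_$status, sd_$feedback, sd_$n_pairs, c(nat, 0)[tmpl],
                   mapping_cpp, sd_$rt, AS_INIT, deadline, mm)
  }
  hier <- n > 1L
  if (!hier) {
    warning("single-subject dataset: group spreads are unidentifiable; ",
            "using fixed weak priors (mean 0, spread 1.5)")
  }

  # initial group locations (data-informed for tau)
  min_rt_all <- min(vapply(sdata, `[[`, numeric(1), "min_rt"))
  mu0 <- vapply(pn, function(p) switch(p,
    eta = , eta_pos = , eta_neg = qlogis(0.2),
    a_base = log(3), a_mod = qlogis(0.1),
    tau = log(0.8 * min_rt_all), z = qlogis(0.6), v_mod = log(1)),
    numeric(1))

  keep <- mcmc$keep
  total_resp <- sum(n_resp)
  chains_out <- vector("list", mcmc$chains)

  for (ch in seq_len(mcmc$chains)) {
    set.seed(.mix_seed(seed, ch, 17L))
    mu <- mu0 + rnorm(d, 0, 0.1)
    sigma <- rep(0.2, d)
    if (!hier) { mu <- rep(0, d); sigma <- rep(.PRIOR_MU_SD, d) }
    X <- matrix(rep(mu, each = n), n, d) + matrix(rnorm(n * d, 0, 0.05), n, d)
    colnames(X) <- pn
    # start each subject's tau just below their fastest RT (the posterior
    # concentrates near that bound)
    tk <- match("tau", pn)
    X[, tk] <- log(0.85 * vapply(sdata, `[[`, numeric(1), "min_rt"))
    ll <- vapply(seq_len(n), function(j) fast_ll(X[j, ], sdata[[j]]),
                 numeric(1))

    ls <- matrix(log(0.2), n, d)  # log proposal scales (component moves)
    acc <- matrix(0, n, d); batch <- 0L
    # joint-move machinery: per-subject empirical covariance from warm-up
    hist_keep <- min(mcmc$warmup, 1000L)
    Xhist <- array(NA_real_, c(hist_keep, n, d))
    hist_i <- 0L
    chol_S <- vector("list", n)   # Cholesky of scaled covariance
    ls_joint <- rep(log(1), n)    # global scale of the joint move
    acc_joint <- rep(0, n); n_joint <- 0L
    cov_start <- max(200L, mcmc$warmup %/% 4L)
    # group-shift move: translate the group mean and every subject together
    # along the pooled subject covariance (the group location otherwise
    # moves only through one-subject-at-a-time proposals)
    chol_G <- NULL
    ls_shift <- log(1); acc_shift <- 0; n_shift <- 0L
    # interweaving move (per parameter): update (mu_k, log sigma_k) with the
    # subjects' standardized offsets held fixed; breaks the funnel coupling
    # between near-zero group spreads and the subject parameters
    ls_iw <- rep(log(0.1), d); acc_iw <- rep(0, d); n_iw <- 0L
    ls_iw2 <- rep(log(0.2), d); acc_iw2 <- rep(0, d); n_iw2 <- 0L
    draws_hyper <- matrix(NA_real_, keep, 2 * d)
    colnames(draws_hyper) <- c(paste0("mu[", pn, "]"), paste0("sigma[", pn, "]"))
    draws_subj <- array(NA_real_, c(keep, n, d),
                        dimnames = list(NULL, subjects, pn))
    pointwise <- matrix(NA_real_, keep, total_resp)
    kept_i <- 0L

    for (it in seq_len(mcmc$iter)) {
      # component-wise MH on subject parameters
      for (j in seq_len(n)) {
        for (k in seq_len(d)) {
          prop <- X[j, ]
          prop[k] <- prop[k] + exp(ls[j, k]) * rnorm(1)
          ll_prop <- fast_ll(prop, sdata[[j]])
          lr <- (ll_prop - ll[j]) +
            stats::dnorm(prop[k], mu[k], sigma[k], log = TRUE) -
            stats::dnorm(X[j, k], mu[k], sigma[k], log = TRUE)
          if (is.finite(lr) && log(runif(1)) < lr) {
            X[j, ] <- prop; ll[j] <- ll_prop
            if (it <= mcmc$warmup) acc[j, k] <- acc[j, k] + 1
          }
        }
      }
      # joint moves per subject along the adapted covariance (repeated:
      # they are cheap relative to the component sweep and do the ridge
      # mixing)
      if (!is.null(chol_S[[1]])) {
        for (rep_ in 1:3) {
          n_joint <- n_joint + 1L
          for (j in seq_len(n)) {
            step <- exp(ls_joint[j]) *
              drop(rnorm(d) %*% chol_S[[j]])
            prop <- X[j, ] + step
            ll_prop <- fast_ll(prop, sdata[[j]])
            lr <- (ll_prop - ll[j]) +
              sum(stats::dnorm(prop, mu, sigma, log = TRUE)) -
              sum(stats::dnorm(X[j, ], mu, sigma, log = TRUE))
            if (is.finite(lr) && log(runif(1)) < lr) {
              X[j, ] <- prop; ll[j] <- ll_prop
              acc_joint[j] <- acc_joint[j] + 1
            }
          }
        }
      }
      # group-shift moves
      if (hier && !is.null(chol_G)) for (rep_ in 1:2) {
        n_shift <- n_shift + 1L
        shift <- exp(ls_shift) * drop(rnorm(d) %*% chol_G)
        Xp <- sweep(X, 2, shift, `+`)
        mup <- mu + shift
        llp <- vapply(seq_len(n), function(j) fast_ll(Xp[j, ], sdata[[j]]),
                      numeric(1))
        lr <- sum(llp - ll) +
          sum(stats::dnorm(mup, 0, .PRIOR_MU_SD, log = TRUE)) -
          sum(stats::dnorm(mu, 0, .PRIOR_MU_SD, log = TRUE))
        if (is.finite(lr) && log(runif(1)) < lr) {
          X <- Xp; mu <- mup; ll <- llp
          acc_shift <- acc_shift + 1
        }
      }
      # warm-up adaptation
      if (it <= mcmc$warmup) {
        hist_i <- hist_i %% hist_keep + 1L
        Xhist[hist_i, , ] <- X
        if (it %% 25L == 0L) {
          batch <- batch + 1L
          delta <- min(0.25, 1 / sqrt(batch))
          ls <- ls + ifelse(acc / 25 > 0.44, delta, -delta)
          acc[] <- 0
          if (n_joint > 0) {
            ls_joint <- ls_joint +
              ifelse(acc_joint / n_joint > 0.25, delta, -delta)
            acc_joint[] <- 0; n_joint <- 0L
          }
          if (n_shift > 0) {
            ls_shift <- ls_shift +
              if (acc_shift / n_shift > 0.25) delta else -delta
            acc_shift <- 0; n_shift <- 0L
          }
          if (n_iw > 0) {
            ls_iw <- ls_iw + ifelse(acc_iw / n_iw > 0.25, delta, -delta)
            acc_iw[] <- 0; n_iw <- 0L
          }
          if (n_iw2 > 0) {
            ls_iw2 <- ls_iw2 + ifelse(acc_iw2 / n_iw2 > 0.3, delta, -delta)
            acc_iw2[] <- 0; n_iw2 <- 0L
          }
        }
        if (it >= cov_start && it %% 100L == 0L) {
          m_avail <- min(it, hist_keep)
          pooled <- matrix(0, d, d)
          for (j in seq_len(n)) {
            S <- stats::cov(Xhist[seq_len(m_avail), j, , drop = TRUE])
            pooled <- pooled + S
            S <- 2.38^2 / d * S + diag(1e-8, d)
            cf <- tryCatch(chol(S), error = function(e) NULL)
            if (!is.null(cf)) chol_S[[j]] <- cf
          }
          # group-mean posterior scales like the subject covariance / n
          SG <- 2.38^2 / d * pooled / (n * n) + diag(1e-9, d)
          cfg_ <- tryCatch(chol(SG), error = function(e) NULL)
          if (!is.null(cfg_)) chol_G <- cfg_
        }
      }
      if (hier) {
        # exact Gibbs for group means, slice for group spreads
        for (k in seq_len(d)) {
          prec <- n / sigma[k]^2 + 1 / .PRIOR_MU_SD^2
          m <- (sum(X[, k]) / sigma[k]^2) / prec
          mu[k] <- rnorm(1, m, sqrt(1 / prec))
          sigma[k] <- .slice_sigma(sigma[k], X[, k], mu[k])
        }
        # interweaving: non-centered updates with the subjects' standardized
        # offsets held fixed, alternating joint (mu_k, sigma_k) proposals
        # with sigma-only proposals (separately adapted step sizes)
        for (rep_ in 1:4) {
        sig_only <- rep_ %% 2L == 0L
        if (sig_only) n_iw2 <- n_iw2 + 1L else n_iw <- n_iw + 1L
        for (k in seq_len(d)) {
          u <- (X[, k] - mu[k]) / sigma[k]
          if (sig_only) {
            mu_p <- mu[k]
            sig_p <- sigma[k] * exp(exp(ls_iw2[k]) * rnorm(1))
          } else {
            mu_p <- mu[k] + exp(ls_iw[k]) * rnorm(1)
            sig_p <- sigma[k] * exp(exp(ls_iw[k]) * rnorm(1))
          }
          Xp <- X
          Xp[, k] <- mu_p + sig_p * u
          llp <- vapply(seq_len(n), function(j) fast_ll(Xp[j, ], sdata[[j]]),
                        numeric(1))
          lr <- sum(llp - ll) +
            stats::dnorm(mu_p, 0, .PRIOR_MU_SD, log = TRUE) -
            stats::dnorm(mu[k], 0, .PRIOR_MU_SD, log = TRUE) +
            (-sig_p^2 + sigma[k]^2) / (2 * .PRIOR_SIGMA_SCALE^2) +
            log(sig_p) - log(sigma[k])
          if (is.finite(lr) && log(runif(1)) < lr) {
            mu[k] <- mu_p; sigma[k] <- sig_p; X <- Xp; ll <- llp
            if (sig_only) acc_iw2[k] <- acc_iw2[k] + 1
            else acc_iw[k] <- acc_iw[k] + 1
          }
        }
        }
      }
      if (it > mcmc$warmup && (it - mcmc$warmup) %% mcmc$thin == 0L &&
          kept_i < keep) {
        kept_i <- kept_i + 1L
        draws_hyper[kept_i, ] <- c(mu, sigma)
        draws_subj[kept_i, , ] <- X
        pointwise[kept_i, ] <- unlist(lapply(seq_len(n), function(j)
          .subject_loglik(X[j, ], sdata[[j]], pn, mapping_cpp,
                          variant$n_learning_rates, deadline, mm)$pointwise))
      }
    }
    if (progress) {
      message(sprintf("chain %d/%d done (%d draws kept)", as.integer(ch),
                      as.integer(mcmc$chains), as.integer(kept_i)))
    }
    chains_out[[ch]] <- list(hyper = draws_hyper[seq_len(kept_i), , drop = FALSE],
                             subject = draws_subj[seq_len(kept_i), , , drop = FALSE],
                             pointwise = pointwise[seq_len(kept_i), , drop = FALSE])
  }

  # convergence diagnostics over every sampled scalar
  kmin <- min(vapply(chains_out, function(c_) nrow(c_$hyper), integer(1)))
  hyper_arr <- array(NA_real_, c(kmin, mcmc$chains, 2 * d),
                     dimnames = list(NULL, NULL, colnames(chains_out[[1]]$hyper)))
  subj_names <- as.vector(outer(subjects, pn,
                                function(s, p) paste0("x[", s, ",", p, "]")))
  subj_arr <- array(NA_real_, c(kmin, mcmc$chains, n * d),
                    dimnames = list(NULL, NULL, subj_names))
  for (ch in seq_len(mcmc$chains)) {
    hyper_arr[, ch, ] <- chains_out[[ch]]$hyper[seq_len(kmin), ]
    subj_arr[, ch, ] <- matrix(chains_out[[ch]]$subject[seq_len(kmin), , ],
                               kmin, n * d)
  }
  sampled <- if (hier) {
    list(hyper = hyper_arr, subject = subj_arr)
  } else {
    list(subject = subj_arr)
  }
  rhat <- unlist(lapply(sampled, function(a) compute_rhat(a)))
  ess <- unlist(lapply(sampled, function(a) .ess_array(a)))
  if (any(rhat >= 1.01, na.rm = TRUE)) {
    warning(sprintf("%d parameter(s) have split R-hat >= 1.01 (max %.3f); ",
                    sum(rhat >= 1.01, na.rm = TRUE), max(rhat, na.rm = TRUE)),
            "consider longer chains")
  }

  structure(list(variant = variant, param_names = pn, subjects = subjects,
                 groups = vapply(subjects, function(s)
                   as.character(dataset$group[dataset$subject_id == s][1]),
                   character(1)),
                 chains = chains_out, hyper_array = hyper_arr,
                 subject_array = subj_arr,
                 pointwise = do.call(rbind, lapply(chains_out, `[[`, "pointwise")),
                 rhat = rhat, ess = ess, mcmc = mcmc, seed = seed,
                 hierarchical = hier, n_responded = n_resp),
            class = "rlddm_fit")
}

#' @export
print.rlddm_fit <- function(x, ...) {
  cat(sprintf("Hierarchical RLDDM fit: variant %d (%d rate%s, %s boundary)\n",
              x$variant$variant_id, x$variant$n_learning_rates,
              if (x$variant$n_learning_rates > 1) "s" else "",
              x$variant$boundary_mapping))
  cat(sprintf("  %d subjects, %d responded trials, %d chains x %d draws\n",
              length(x$subjects), sum(x$n_responded), length(x$chains),
              nrow(x$chains[[1]]$hyper)))
  cat(sprintf("  max split R-hat: %.4f\n", max(x$rhat, na.rm = TRUE)))
  if (x$hierarchical) print(summarize_group_parameters(x), digits = 3)
  invisible(x)
}

#' Posterior summaries of the group-level parameter means
#'
#' Transforms each draw of the group-level mean back to the natural scale
#' and summarizes the resulting posterior (mean, SD, central 95% interval).
#'
#' @param fit An `rlddm_fit`.
#' @return Data frame with one row per model parameter.
#' @export
summarize_group_parameters <- function(fit) {
  stopifnot(inherits(fit, "rlddm_fit"))
  if (!fit$hierarchical) stop("fit has no group level (single subject)")
  pn <- fit$param_names
  hyper <- do.call(rbind, lapply(fit$chains, `[[`, "hyper"))
  out <- lapply(pn, function(p) {
    nat <- .from_unconstrained(hyper[, paste0("mu[", p, "]")],
                               .param_transforms[[p]])
    data.frame(parameter = p, mean = mean(nat), sd = sd(nat),
               q2.5 = unname(quantile(nat, 0.025)),
               q97.5 = unname(quantile(nat, 0.975)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Posterior summaries of subject-level parameters
#'
#' @param fit An `rlddm_fit`.
#' @return Data frame keyed by subject and parameter with natural-scale
#'   posterior mean, SD and central 95% interval.
#' @export
summarize_subject_parameters <- function(fit) {
  stopifnot(inherits(fit, "rlddm_fit"))
  pn <- fit$param_names
  draws <- do.call(rbind, lapply(fit$chains, function(c_)
    matrix(c_$subject, nrow(c_$subject), length(fit$subjects) * length(pn))))
  out <- vector("list", length(fit$subjects) * length(pn))
  i <- 0L
  for (pk in seq_along(pn)) {
    for (sj in seq_along(fit$subjects)) {
      i <- i + 1L
      col <- (pk - 1L) * length(fit$subjects) + sj
      nat <- .from_unconstrained(draws[, col], .param_transforms[[pn[pk]]])
      out[[i]] <- data.frame(subject_id = fit$subjects[sj],
                             group = unname(fit$groups[sj]),
                             parameter = pn[pk],
                             mean = mean(nat), sd = sd(nat),
                             q2.5 = unname(quantile(nat, 0.025)),
                             q97.5 = unname(quantile(nat, 0.975)),
                             stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res[order(res$subject_id, res$parameter), ]
}
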