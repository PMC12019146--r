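#' Wiener first-passage-time log density
#'
#' Joint log density of response and reaction time under the drift-diffusion
#' model with boundary separation `boundary`, relative starting point `z`
#' (measured from the error boundary), drift `drift` and nondecision time
#' `tau`, with the diffusion coefficient fixed at 1. Accuracy coding is used:
#' the upper boundary is the correct response and positive drift drives
#' toward it. The error-response density follows from the reflection
#' identity `f_lower(t; v, z) = f_upper(t; -v, 1 - z)`.
#'
#' The density is evaluated with the small-time/large-time series pair,
#' choosing per evaluation whichever expansion needs fewer terms for a
#' truncation error below 1e-7; it is stable for decision times down to
#' 1e-4 s.
#'
#' @param rt Reaction time(s) in seconds.
#' @param response_correct Logical; `TRUE` for a correct response.
#' @param drift Unsigned drift magnitude (the sign toward the response is
#'   applied internally).
#' @param boundary Boundary separation (> 0).
#' @param z Relative starting point in (0, 1); `z > 0.5` biases toward the
#'   correct boundary.
#' @param tau Nondecision time in seconds (>= 0). RTs at or below `tau`
#'   yield `-Inf` (or the floor, see `floor`).
#' @param floor If `TRUE`, clamp the result at -700 instead of returning
#'   `-Inf`; used inside samplers to keep the posterior finite.
#' @return Log density value(s); vectorized over all arguments.
#' @export
#' @examples
#' wfpt_log_density(0.8, TRUE, drift = 1, boundary = 2, z = 0.5, tau = 0.3)
wfpt_log_density <- function(rt, response_correct, drift, boundary, z, tau,
                             floor = FALSE) {
  if (any(boundary <= 0)) stop("`boundary` must be > 0")
  if (any(z <= 0 | z >= 1)) stop("`z` must lie strictly inside (0, 1)")
  if (any(tau < 0)) stop("`tau` must be >= 0")
  n <- max(length(rt), length(response_correct), length(drift),
           length(boundary), length(z), length(tau))
  out <- .wfpt_log_cpp(rep_len(as.numeric(rt), n),
                       rep_len(as.logical(response_correct), n),
                       rep_len(as.numeric(drift), n),
                       rep_len(as.numeric(boundary), n),
                       rep_len(as.numeric(z), n),
                       rep_len(as.numeric(tau), n))
  if (floor) out <- pmax(out, -700)
  out
}

#' Probability of absorption at the correct boundary
#'
#' Closed-form probability that a diffusion with drift `drift`, boundary
#' separation `boundary` and relative start `z` is absorbed at the upper
#' (correct) boundary: `(1 - exp(-2 v z a)) / (1 - exp(-2 v a))` for
#' nonzero drift, and `z` in the driftless limit. Serves as an analytic
#' oracle for the density and the forward simulator.
#'
#' @inheritParams wfpt_log_density
#' @return Probability in \[0, 1\]; vectorized.
#' @export
#' @examples
#' upper_probability(1, 2, 0.5)  # (1 - exp(-2)) / (1 - exp(-4))
upper_probability <- function(drift, boundary, z) {
  if (any(boundary <= 0)) stop("`boundary` must be > 0")
  if (any(z <= 0 | z >= 1)) stop("`z` must lie strictly inside (0, 1)")
  n <- max(length(drift), length(boundary), length(z))
  v <- rep_len(drift, n); a <- rep_len(boundary, n); zz <- rep_len(z, n)
  out <- numeric(n)
  small <- abs(v) < 1e-10
  out[small] <- zz[small]
  if (any(!small)) {
    vv <- v[!small]; aa <- a[!small]; zn <- zz[!small]
    out[!small] <- expm1(-2 * vv * zn * aa) / expm1(-2 * vv * aa)
  }
  pmin(pmax(out, 0), 1)
}

#' Log likelihood of one subject's trial sequence
#'
#' Chains the delta-rule learning model through the diffusion observation
#' model: the associative strengths are replayed in presentation order
#' (reset to 0.5 at every run start, since each run introduces new
#' pairings), each trial's drift and boundary are derived from the current
#' state, and the Wiener first-passage-time log density is evaluated for
#' every responded trial. The drift averages the associative strengths of
#' the two characters on screen: the trial's pairing and, when a
#' `foil_pair_id` column is present, the foil character's own pairing
#' (without it, the foil association counts at its 0.5 resting value).
#' Missed trials trigger no associative update; by default they contribute
#' no likelihood term (`missed = "exclude"`), while `missed = "censor"`
#' adds, per missed trial, the log probability that the diffusion is still
#' unabsorbed at the deadline (the treatment the fitting routine uses, see
#' [fit_hierarchical()]). Censored contributions are reported in
#' `censor_loglik` and included in `total` but not in `pointwise`.
#'
#' @param trials Data frame with one row per trial, ordered by run then
#'   within-run trial index, with columns `run`, `trial`, `pair_id`,
#'   `response` (`"correct"`, `"incorrect"` or `"missed"`), `rt_s` (seconds,
#'   `NA` for missed) and `feedback` (0/1, `NA` for missed).
#' @param params Named list of subject parameters: `eta` (or `eta_pos` and
#'   `eta_neg`), `a_base`, `a_mod` (dynamic boundaries only), `tau`, `z`,
#'   `v_mod`.
#' @param variant An `rlddm_variant` (see [get_variant()]) or a variant id.
#' @param floor Passed to [wfpt_log_density()]; clamp instead of `-Inf`.
#' @param missed `"exclude"` or `"censor"` (see above).
#' @param deadline Response deadline in seconds (used by the censor term).
#' @return A list of class `rlddm_loglik` with `total`, `pointwise` (one
#'   entry per responded trial in trial order), `censor_loglik` and the
#'   per-trial derived series `as`, `pe`, `drift`, `boundary`.
#' @export
trial_sequence_loglik <- function(trials, params, variant, floor = FALSE,
                                  missed = c("exclude", "censor"),
                                  deadline = 2.5) {
  missed <- match.arg(missed)
  if (!inherits(variant, "rlddm_variant")) variant <- get_variant(variant)
  req <- c("run", "trial", "pair_id", "response", "rt_s", "feedback")
  miss <- setdiff(req, names(trials))
  if (length(miss)) stop("`trials` lacks columns: ", paste(miss, collapse = ", "))
  ord <- order(trials$run, trials$trial)
  if (!identical(ord, seq_len(nrow(trials)))) {
    stop("`trials` must be ordered by run then trial index")
  }
  if (any(duplicated(trials[c("run", "trial")]))) {
    stop("duplicated (run, trial) rows in `trials`")
  }
  pairs <- sort(unique(as.character(trials$pair_id)))
  pair_idx <- match(as.character(trials$pair_id), pairs)
  foil_idx <- if ("foil_pair_id" %in% names(trials)) {
    f <- match(as.character(trials$foil_pair_id), pairs)
    ifelse(is.na(f), 0L, f)
  } else rep(0L, nrow(trials))
  status <- match(as.character(trials$response),
                  c("missed", "correct", "incorrect")) - 1L
  if (anyNA(status)) stop("`response` must be 'correct', 'incorrect' or 'missed'")
  responded <- status != 0L
  if (any(responded & !is.finite(trials$rt_s))) {
    stop("responded trials must carry a finite rt_s")
  }
  fb <- ifelse(responded, as.integer(trials$feedback), 0L)
  if (any(responded & !(fb %in% c(0L, 1L)))) stop("`feedback` must be 0/1")
  pv <- .params_vector(params, variant)
  rt <- ifelse(responded, as.numeric(trials$rt_s), 0)
  res <- .seq_loglik_cpp(as.integer(trials$run), as.integer(trials$trial),
                         pair_idx, as.integer(foil_idx), status, fb,
                         length(pairs), pv,
                         .mapping_cpp(variant$boundary_mapping), floor,
                         rt, AS_INIT, deadline,
                         if (missed == "censor") 1L else 0L)
  structure(res, class = "rlddm_loglik")
}
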