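#' @useDynLib rlddm, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif qnorm var sd median quantile plogis qlogis
NULL

# initial associative strength of every pairing (uninformative association;
# pairings are novel at the start of each run)
AS_INIT <- 0.5

.mappings <- c("exponential", "linear", "static")

#' Registry of the six model variants
#'
#' The reinforcement-learning drift-diffusion model (RLDDM) of the
#' letter--speech-sound learning task comes in six variants crossing the
#' number of delta-rule learning rates (two rates, one for positive and one
#' for negative prediction errors, versus a single shared rate) with the
#' mapping that turns the boundary modifier into a trial-wise decision
#' boundary (exponential/power growth, linear growth, or a static boundary).
#'
#' Variants 1--3 carry two learning rates, variants 4--6 a single one;
#' variants 1 and 4 use the exponential mapping, 2 and 5 the linear mapping,
#' and 3 and 6 a static boundary.
#'
#' @return A data frame with columns `variant_id`, `n_learning_rates` and
#'   `boundary_mapping`, one row per variant.
#' @export
#' @examples
#' rlddm_variants()
rlddm_variants <- function() {
  data.frame(
    variant_id = 1:6,
    n_learning_rates = c(2L, 2L, 2L, 1L, 1L, 1L),
    boundary_mapping = rep(c("exponential", "linear", "static"), 2),
    stringsAsFactors = FALSE
  )
}

#' Look up a model variant
#'
#' @param variant_id Integer in 1..6.
#' @return An object of class `rlddm_variant` with fields `variant_id`,
#'   `n_learning_rates` and `boundary_mapping`.
#' @export
#' @examples
#' get_variant(4)  # single learning rate, exponential boundary growth
get_variant <- function(variant_id) {
  if (length(variant_id) != 1L || is.na(variant_id) ||
      variant_id != as.integer(variant_id) ||
      !(variant_id %in% 1:6)) {
    stop("`variant_id` must be a single integer in 1..6, got: ",
         deparse(substitute(variant_id)), " = ", paste(variant_id, collapse = ","))
  }
  reg <- rlddm_variants()
  row <- reg[reg$variant_id == variant_id, ]
  structure(
    list(variant_id = as.integer(variant_id),
         n_learning_rates = row$n_learning_rates,
         boundary_mapping = row$boundary_mapping),
    class = "rlddm_variant"
  )
}

#' @export
print.rlddm_variant <- function(x, ...) {
  cat(sprintf("RLDDM variant %d: %d learning rate%s, %s boundary\n",
              x$variant_id, x$n_learning_rates,
              if (x$n_learning_rates > 1) "s" else "", x$boundary_mapping))
  invisible(x)
}

#' Delta-rule update of associative strength
#'
#' Applies one trial's feedback to the associative state. The prediction
#' error is the observed outcome minus the current associative strength (AS)
#' of the updated pairing, and the AS moves by `eta * PE`. Two-rate variants
#' use `eta_pos` after positive prediction errors and `eta_neg` after
#' negative ones. All other pairings are left untouched.
#'
#' @param state Named numeric vector of associative strengths, one entry per
#'   pairing, each in \[0, 1\].
#' @param pairing Name of the pairing to update (must exist in `state`).
#' @param outcome Observed feedback, 0 or 1.
#' @param rates Learning rate(s) in (0, 1): a single value, or a vector/list
#'   with elements `eta_pos` and `eta_neg` for two-rate variants.
#' @param variant Optional `rlddm_variant`; when given, the number of rates
#'   must match the variant.
#' @return A list with `state` (the updated vector) and `prediction_error`.
#' @export
#' @examples
#' st <- c(p1 = 0.5, p2 = 0.5)
#' update_associative_strength(st, "p1", 1, rates = 0.19)
update_associative_strength <- function(state, pairing, outcome, rates,
                                        variant = NULL) {
  if (!pairing %in% names(state)) {
    stop("unknown pairing '", pairing, "'; state has: ",
         paste(names(state), collapse = ", "))
  }
  if (!outcome %in% c(0, 1)) stop("`outcome` must be 0 or 1")
  rates <- unlist(rates)
  if (any(rates <= 0 | rates >= 1)) {
    stop("learning rates must lie strictly inside (0, 1)")
  }
  if (!is.null(variant) && length(rates) != variant$n_learning_rates) {
    stop("variant ", variant$variant_id, " expects ",
         variant$n_learning_rates, " learning rate(s), got ", length(rates))
  }
  pe <- outcome - state[[pairing]]
  if (length(rates) == 1L) {
    eta <- rates
  } else {
    nm <- names(rates)
    if (!is.null(nm) && all(c("eta_pos", "eta_neg") %in% nm)) {
      eta <- if (pe >= 0) rates[["eta_pos"]] else rates[["eta_neg"]]
    } else {
      eta <- if (pe >= 0) rates[[1L]] else rates[[2L]]
    }
  }
  state[[pairing]] <- state[[pairing]] + eta * pe
  list(state = state, prediction_error = unname(pe))
}

#' Trial-wise drift rate from associative strengths
#'
#' The drift rate magnitude is the drift-rate modifier times the mean of the
#' associative strengths of the two character--sound combinations on screen
#' (the reinforced pairing and the foil combination). The sign (toward the
#' correct or the error boundary) is attached later, at likelihood evaluation
#' or simulation, under accuracy coding.
#'
#' @param as_correct_pair,as_incorrect_pair Associative strengths in \[0, 1\].
#' @param v_mod Drift-rate modifier, non-negative.
#' @return Unsigned drift rate (evidence units per second).
#' @export
#' @examples
#' compute_drift(0.5, 0.5, 0.97)
compute_drift <- function(as_correct_pair, as_incorrect_pair, v_mod) {
  if (any(v_mod < 0)) stop("`v_mod` must be non-negative")
  if (any(as_correct_pair < 0 | as_correct_pair > 1) ||
      any(as_incorrect_pair < 0 | as_incorrect_pair > 1)) {
    stop("associative strengths must lie in [0, 1]")
  }
  v_mod * (as_correct_pair + as_incorrect_pair) / 2
}

#' Decision boundary at a given trial
#'
#' Maps the boundary parameters onto the trial-wise boundary separation
#' `a_t`. The exponential mapping is the power law `a_base * t^a_mod`
#' (strictly increasing and concave in the within-run trial index for
#' `a_mod` in (0, 1), i.e. logarithmic-looking growth), the linear mapping is
#' `a_base + a_mod * (t - 1)`, and the static mapping returns `a_base`.
#' The trial index is 1-based within run.
#'
#' @param a_base Boundary separation on the first trial of a run (> 0).
#' @param a_mod Boundary modifier; in (0, 1) for the dynamic mappings,
#'   ignored (may be `NULL`/`NA`) for the static mapping.
#' @param trial_index 1-based within-run trial index (vectorized).
#' @param mapping One of `"exponential"`, `"linear"`, `"static"`.
#' @return Boundary separation(s) in evidence units.
#' @export
#' @examples
#' boundary_at_trial(2.75, 0.052, 1:40, "exponential")
boundary_at_trial <- function(a_base, a_mod, trial_index,
                              mapping = c("exponential", "linear", "static")) {
  mapping <- match.arg(mapping)
  if (any(a_base <= 0)) stop("`a_base` must be strictly positive")
  if (any(trial_index < 1)) stop("`trial_index` is 1-based and must be >= 1")
  if (mapping == "static") return(rep(a_base, length.out = length(trial_index)))
  if (is.null(a_mod) || any(is.na(a_mod))) {
    stop("`a_mod` is required for the ", mapping, " mapping")
  }
  if (mapping == "exponential") {
    if (any(a_mod <= 0 | a_mod >= 1)) {
      stop("`a_mod` must lie in (0, 1) for the exponential mapping")
    }
    a_base * trial_index^a_mod
  } else {
    a_base + a_mod * (trial_index - 1)
  }
}

.mapping_code <- function(mapping) {
  match(mapping, .mappings)  # 1 exponential, 2 linear, 3 static
}

# internal: mapping string -> code used by the C++ routines
# (C++: 0 static, 1 exponential, 2 linear)
.mapping_cpp <- function(mapping) {
  switch(mapping, exponential = 1L, linear = 2L, static = 0L,
         stop("unknown mapping: ", mapping))
}

# Validate a subject-parameter list against a variant; returns the
# canonical 7-slot vector used by the C++ kernels:
# eta_pos, eta_neg, a_base, a_mod, tau, z, v_mod.
.params_vector <- function(params, variant) {
  stopifnot(is.list(params))
  if (variant$n_learning_rates == 2L) {
    if (is.null(params$eta_pos) || is.null(params$eta_neg)) {
      stop("two-rate variant needs `eta_pos` and `eta_neg`")
    }
    ep <- params$eta_pos; en <- params$eta_neg
  } else {
    if (is.null(params$eta)) stop("single-rate variant needs `eta`")
    ep <- en <- params$eta
  }
  a_mod <- if (variant$boundary_mapping == "static") 0 else params$a_mod
  if (variant$boundary_mapping != "static" && is.null(params$a_mod)) {
    stop("dynamic-boundary variant needs `a_mod`")
  }
  v <- c(ep, en, params$a_base, a_mod, params$tau, params$z, params$v_mod)
  if (anyNA(v)) stop("subject parameters contain NA")
  if (any(c(ep, en) <= 0 | c(ep, en) >= 1)) stop("learning rates must be in (0,1)")
  if (params$a_base <= 0) stop("`a_base` must be > 0")
  if (params$tau <= 0) stop("`tau` must be > 0")
  if (params$z <= 0 || params$z >= 1) stop("`z` must be in (0,1)")
  if (params$v_mod <= 0) stop("`v_mod` must be > 0")
  if (variant$boundary_mapping == "exponential" && (a_mod <= 0 || a_mod >= 1)) {
    stop("`a_mod` must be in (0,1) for the exponential mapping")
  }
  v
}
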