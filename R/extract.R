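#' Trial-wise posterior-mean learning series
#'
#' Replays the generative recursion (associative strength, prediction
#' error, drift, boundary) at posterior draws of each subject's parameters
#' and averages across draws, yielding the per-trial series used as
#' parametric modulators in model-based fMRI analyses: the associative
#' strength at stimulus onset and the prediction error at feedback onset,
#' plus the trial-wise drift and boundary.
#'
#' @param fit An `rlddm_fit`.
#' @param dataset The trial table the fit was computed from.
#' @param max_draws Number of posterior draws to average over (subsampled
#'   evenly across chains).
#' @return Data frame with columns `subject_id`, `run`, `trial`, `as_mean`,
#'   `pe_mean`, `drift_mean`, `boundary_mean`, aligned to trial order
#'   (`pe_mean` is `NA` on missed trials).
#' @export
extract_trialwise_series <- function(fit, dataset, max_draws = 400L) {
  stopifnot(inherits(fit, "rlddm_fit"))
  if (inherits(dataset, "rlddm_cohort")) dataset <- dataset$trials
  ds_sub <- unique(as.character(dataset$subject_id))
  if (!setequal(ds_sub, fit$subjects)) {
    stop("dataset subjects do not match the fitted subjects")
  }
  pn <- fit$param_names
  variant <- fit$variant
  mapping_cpp <- .mapping_cpp(variant$boundary_mapping)
  draws <- do.call(rbind, lapply(fit$chains, function(c_)
    matrix(c_$subject, nrow(c_$subject), length(fit$subjects) * length(pn))))
  idx <- unique(round(seq(1, nrow(draws), length.out = min(max_draws, nrow(draws)))))
  out <- vector("list", length(fit$subjects))
  for (sj in seq_along(fit$subjects)) {
    s <- fit$subjects[sj]
    sd_ <- .subject_data(dataset[dataset$subject_id == s, , drop = FALSE])
    nt <- length(sd_$run)
    acc <- matrix(0, nt, 4)
    for (i in idx) {
      x <- draws[i, (seq_along(pn) - 1L) * length(fit$subjects) + sj]
      res <- .subject_loglik(x, sd_, pn, mapping_cpp,
                             variant$n_learning_rates)
      acc <- acc + cbind(res$as, res$pe, res$drift, res$boundary)
    }
    acc <- acc / length(idx)
    out[[sj]] <- data.frame(subject_id = s, run = sd_$run, trial = sd_$trial,
                            as_mean = acc[, 1], pe_mean = acc[, 2],
                            drift_mean = acc[, 3], boundary_mean = acc[, 4],
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
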