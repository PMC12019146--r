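#' Widely Applicable Information Criterion
#'
#' Computes WAIC from a pointwise log-density matrix (posterior samples in
#' rows, trials in columns): the log pointwise predictive density
#' `lppd = sum_i log mean_s exp(ll_si)` (evaluated with log-sum-exp), the
#' effective parameter count `p_waic = sum_i var_s(ll_si)` (sample variance,
#' n-1 denominator), and `waic = -2 (lppd - p_waic)` on the deviance scale.
#' Only responded trials enter the matrix, matching the likelihood's
#' inclusion rule.
#'
#' @param pointwise Numeric matrix, samples x trials, of log densities; an
#'   `rlddm_fit` is also accepted (its stored pointwise matrix is used).
#' @param variant_id Optional variant id to carry into the result.
#' @return Object of class `rlddm_waic` with `lppd`, `p_waic`, `waic`,
#'   `n_trials`, `n_samples` and `variant_id`.
#' @export
#' @examples
#' m <- rbind(log(0.5), log(0.25))
#' compute_waic(m)$lppd  # log(0.375)
compute_waic <- function(pointwise, variant_id = NA_integer_) {
  if (inherits(pointwise, "rlddm_fit")) {
    variant_id <- pointwise$variant$variant_id
    pointwise <- pointwise$pointwise
  }
  pointwise <- as.matrix(pointwise)
  if (nrow(pointwise) < 2L) stop("WAIC needs at least 2 posterior samples")
  if (!all(is.finite(pointwise))) stop("pointwise matrix must be finite")
  s <- nrow(pointwise)
  # column-wise log-sum-exp
  mx <- apply(pointwise, 2, max)
  lppd_i <- mx + log(colMeans(exp(sweep(pointwise, 2, mx))))
  p_i <- apply(pointwise, 2, stats::var)
  lppd <- sum(lppd_i)
  p_waic <- sum(p_i)
  structure(list(lppd = lppd, p_waic = p_waic,
                 waic = -2 * (lppd - p_waic),
                 n_trials = ncol(pointwise), n_samples = s,
                 variant_id = variant_id),
            class = "rlddm_waic")
}

#' @export
print.rlddm_waic <- function(x, ...) {
  cat(sprintf("WAIC %.1f (lppd %.1f, p_waic %.1f; %d trials, %d samples)\n",
              x$waic, x$lppd, x$p_waic, x$n_trials, x$n_samples))
  invisible(x)
}

#' Rank fitted model variants by WAIC
#'
#' Orders WAIC results ascending (rank 1 = lowest WAIC = preferred model).
#' Exact ties are broken by the lower effective parameter count, then the
#' lower variant id.
#'
#' @param results List of `rlddm_waic` objects.
#' @return Data frame with columns `variant_id`, `n_learning_rates`,
#'   `boundary_mapping`, `lppd`, `p_waic`, `waic`, `rank`, sorted by rank.
#' @export
rank_models <- function(results) {
  if (!length(results)) stop("need at least one WAIC result")
  reg <- rlddm_variants()
  tab <- do.call(rbind, lapply(results, function(r) {
    stopifnot(inherits(r, "rlddm_waic"))
    data.frame(variant_id = r$variant_id, lppd = r$lppd, p_waic = r$p_waic,
               waic = r$waic, stringsAsFactors = FALSE)
  }))
  ord <- order(tab$waic, tab$p_waic, tab$variant_id)
  tab <- tab[ord, , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  tab <- merge(tab, reg, by = "variant_id", all.x = TRUE, sort = FALSE)
  tab <- tab[order(tab$rank),
             c("variant_id", "n_learning_rates", "boundary_mapping",
               "lppd", "p_waic", "waic", "rank")]
  rownames(tab) <- NULL
  tab
}
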