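#' Split R-hat convergence diagnostic
#'
#' Rank-normalized split R-hat: each chain is split in half, the pooled
#' draws are rank-normalized through the inverse normal CDF, and the classic
#' between/within variance ratio is computed on the normalized draws.
#' Values near 1 indicate convergence; the package warns at 1.01.
#'
#' Chains that are exactly constant (zero variance) are reported as 1 and
#' flagged via the `"zero_variance"` attribute.
#'
#' @param samples A draws-by-chains matrix for one parameter, or a 3-D array
#'   (draws x chains x parameters).
#' @return Named numeric vector of R-hat values (scalar for a matrix).
#' @export
#' @examples
#' x <- matrix(rnorm(2000), 1000, 2)
#' compute_rhat(x)  # close to 1
compute_rhat <- function(samples) {
  if (is.matrix(samples)) {
    return(.rhat_one(samples))
  }
  if (length(dim(samples)) == 3L) {
    pn <- dimnames(samples)[[3]]
    out <- vapply(seq_len(dim(samples)[3]),
                  function(k) .rhat_one(samples[, , k, drop = TRUE]),
                  numeric(1))
    names(out) <- pn
    return(out)
  }
  stop("`samples` must be a draws x chains matrix or a 3-D array")
}

.rhat_one <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2L) stop("R-hat needs at least 2 chains")
  if (nrow(x) < 4L) stop("R-hat needs at least 4 draws per chain")
  half <- nrow(x) %/% 2L
  split_x <- cbind(x[seq_len(half), , drop = FALSE],
                   x[(half + 1L):(2L * half), , drop = FALSE])
  if (stats::var(as.vector(split_x)) == 0) {
    return(structure(1, zero_variance = TRUE))
  }
  # rank-normalize the pooled draws
  r <- matrix(rank(split_x, ties.method = "average"), nrow(split_x))
  z <- qnorm((r - 3 / 8) / (length(r) + 1 / 4))
  m <- ncol(z); n_ <- nrow(z)
  means <- colMeans(z)
  w <- mean(apply(z, 2, stats::var))
  b <- n_ * stats::var(means)
  if (w == 0) return(structure(1, zero_variance = TRUE))
  sqrt(((n_ - 1) / n_ * w + b / n_) / w)
}

# effective sample size via Geyer's initial positive sequence on the
# chain-demeaned draws; conservative but adequate for reporting
.ess_one <- function(x) {
  x <- as.matrix(x)
  n_ <- nrow(x); m <- ncol(x)
  if (stats::var(as.vector(x)) == 0) return(n_ * m)
  z <- sweep(x, 2, colMeans(x))
  max_lag <- min(n_ - 1L, 250L)
  rho <- rep(0, max_lag)
  denom <- mean(apply(x, 2, stats::var))
  for (l in seq_len(max_lag)) {
    s <- 0
    for (c_ in seq_len(m)) {
      s <- s + sum(z[seq_len(n_ - l), c_] * z[(l + 1):n_, c_]) / (n_ - l)
    }
    rho[l] <- (s / m) / denom
  }
  tau_sum <- 0
  l <- 1L
  while (l + 1L <= max_lag) {
    pair <- rho[l] + rho[l + 1L]
    if (pair < 0) break
    tau_sum <- tau_sum + pair
    l <- l + 2L
  }
  ess <- n_ * m / (1 + 2 * tau_sum)
  min(ess, n_ * m)
}

.ess_array <- function(a) {
  out <- vapply(seq_len(dim(a)[3]),
                function(k) .ess_one(a[, , k, drop = TRUE]), numeric(1))
  names(out) <- dimnames(a)[[3]]
  out
}
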