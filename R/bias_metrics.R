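#' Pool multiple-imputation coefficient sets by Rubin's rules
#'
#' The pooled point estimate of each coefficient is the arithmetic
#' mean of the per-imputation estimates; the pooled variance is
#' `W + (1 + 1/m) * B`, with `W` the mean within-imputation variance
#' and `B` the between-imputation variance of the estimates.
#'
#' @param fits List of `m` `"re_fit"` objects (or any lists with
#'   equal-length `beta` and `se` vectors).
#' @return A list with `beta`, `se` (sqrt of pooled variance), `m`,
#'   and the `within` / `between` variance components.
#' @export
#' @examples
#' f <- list(beta = c(a = 0.1), se = c(a = 0.1))
#' pool_rubin(list(f, f, f))$beta
pool_rubin <- function(fits) {
  stopifnot(length(fits) >= 1)
  k <- length(fits[[1]]$beta)
  if (any(vapply(fits, function(f) length(f$beta) != k ||
                   length(f$se) != k, logical(1)))) {
    stop("coefficient sets have mismatched lengths")
  }
  m <- length(fits)
  est <- do.call(rbind, lapply(fits, function(f) f$beta))
  wvar <- do.call(rbind, lapply(fits, function(f) f$se^2))
  beta <- colMeans(est)
  w <- colMeans(wvar)
  b <- if (m > 1) apply(est, 2, stats::var) else rep(0, k)
  total <- w + (1 + 1 / m) * b
  list(beta = beta, se = sqrt(total), m = m, within = w, between = b)
}

#' Mean of absolute biases of one coefficient value set
#'
#' `MAB = mean_k |beta_k - a_k|` over the eight coefficients
#' (intercept included), comparing an estimated coefficient value set
#' against the reference coefficients.
#'
#' @param beta Estimated coefficients, length 8 (a fit object's `beta`
#'   or a bare numeric vector).
#' @param reference Reference coefficients, length 8.
#' @return Nonnegative scalar MAB.
#' @export
#' @examples
#' compute_mab(rep(0.2, 8), rep(0.19, 8)) # 0.01
compute_mab <- function(beta, reference) {
  if (is.list(beta)) beta <- beta$beta
  beta <- as.numeric(beta)
  reference <- as.numeric(reference)
  if (length(beta) != length(reference) || anyNA(beta) || anyNA(reference)) {
    stop("beta and reference must be complete vectors of equal length")
  }
  mean(abs(beta - reference))
}

#' Grand mean of absolute biases for one (proportion, method) cell
#'
#' `GAB = mean_s MAB_s` over the simulated data sets, defined only
#' when every replicate produced an MAB: a single method failure makes
#' the GAB undefined (`NA`), mirroring the treatment of methods that
#' cannot handle high missingness.  Set `partial = TRUE` to instead
#' average the successful replicates (off by default).
#'
#' @param mabs Numeric vector of per-replicate MABs, with `NA` for
#'   replicates where the method failed.
#' @param n_replicates Expected number of replicates; defaults to
#'   `length(mabs)`.
#' @param partial If TRUE, average over successes even when some
#'   replicates failed.
#' @return A list with `gab` (numeric or `NA`), `n_contributing`, and
#'   `defined`.
#' @export
compute_gab <- function(mabs, n_replicates = length(mabs),
                        partial = FALSE) {
  if (length(mabs) == 0) stop("no bias records supplied")
  ok <- !is.na(mabs)
  n_contributing <- sum(ok)
  defined <- n_contributing == n_replicates && length(mabs) == n_replicates
  gab <- if (defined || (partial && n_contributing > 0)) {
    mean(mabs[ok])
  } else {
    NA_real_
  }
  list(gab = gab, n_contributing = n_contributing, defined = defined)
}
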