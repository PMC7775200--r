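# conditional moments of the missing block given the observed block of
# a multivariate normal: mean mu_M + S_MO S_OO^-1 (x_O - mu_O) and
# covariance S_MM - S_MO S_OO^-1 S_OM
conditional_normal_moments <- function(mu, sigma, obs_idx, obs_vals) {
  mis_idx <- setdiff(seq_along(mu), obs_idx)
  if (length(obs_idx) == 0) {
    return(list(mean = mu[mis_idx],
                cov = sigma[mis_idx, mis_idx, drop = FALSE]))
  }
  s_oo <- sigma[obs_idx, obs_idx, drop = FALSE]
  s_mo <- sigma[mis_idx, obs_idx, drop = FALSE]
  ch <- tryCatch(chol(s_oo), error = function(e) NULL)
  if (is.null(ch)) stop("singular observed-block covariance")
  w <- s_mo %*% chol2inv(ch)
  list(mean = as.numeric(mu[mis_idx] + w %*% (obs_vals - mu[obs_idx])),
       cov = sigma[mis_idx, mis_idx, drop = FALSE] - w %*% t(s_mo))
}

# EM for the mean and covariance of a multivariate normal with missing
# data; rows grouped by missingness pattern.  ridge*I is added to the
# covariance each M-step to delay (not eliminate) singularity failure.
em_mvn <- function(x, ridge = 1e-4, tol = 1e-6, max_iter = 1000L) {
  n <- nrow(x)
  d <- ncol(x)
  mu <- colMeans(x, na.rm = TRUE)
  v <- apply(x, 2, stats::var, na.rm = TRUE)
  v[!is.finite(v) | v < 1e-6] <- 1e-6
  if (any(!is.finite(mu))) stop("a column has no observed values")
  sigma <- diag(v, d)
  pattern <- apply(!is.na(x), 1, paste, collapse = "")
  groups <- split(seq_len(n), pattern)
  for (it in seq_len(max_iter)) {
    s1 <- numeric(d)
    s2 <- matrix(0, d, d)
    for (g in groups) {
      obs <- which(!is.na(x[g[1], ]))
      mis <- setdiff(seq_len(d), obs)
      xg <- x[g, , drop = FALSE]
      if (length(mis) == 0) {
        s1 <- s1 + colSums(xg)
        s2 <- s2 + crossprod(xg)
        next
      }
      if (length(obs) == 0) {
        ex <- matrix(mu, length(g), d, byrow = TRUE)
        s1 <- s1 + colSums(ex)
        s2 <- s2 + crossprod(ex) + length(g) * sigma
        next
      }
      s_oo <- sigma[obs, obs, drop = FALSE]
      ch <- tryCatch(chol(s_oo), error = function(e) NULL)
      if (is.null(ch)) stop("singular covariance during EM")
      w <- sigma[mis, obs, drop = FALSE] %*% chol2inv(ch)
      cc <- sigma[mis, mis, drop = FALSE] -
        w %*% t(sigma[mis, obs, drop = FALSE])
      em <- t(mu[mis] + w %*% (t(xg[, obs, drop = FALSE]) - mu[obs]))
      ex <- xg
      ex[, mis] <- em
      s1 <- s1 + colSums(ex)
      s2g <- crossprod(ex)
      s2g[mis, mis] <- s2g[mis, mis] + length(g) * cc
      s2 <- s2 + s2g
    }
    mu_new <- s1 / n
    sigma_new <- s2 / n - tcrossprod(mu_new) + diag(ridge, d)
    delta <- max(abs(mu_new - mu), abs(sigma_new - sigma))
    mu <- mu_new
    sigma <- sigma_new
    if (delta < tol) {
      return(list(mu = mu, sigma = sigma, iterations = it, converged = TRUE))
    }
  }
  stop("EM did not converge within ", max_iter, " iterations")
}

# draw imputations for the missing cells of x from the row-wise
# conditional normal under (mu, sigma); clipped to [0, 1]
mvn_draw_imputations <- function(x, mu, sigma) {
  out <- x
  pattern <- apply(!is.na(x), 1, paste, collapse = "")
  for (g in split(seq_len(nrow(x)), pattern)) {
    obs <- which(!is.na(x[g[1], ]))
    mis <- setdiff(seq_len(ncol(x)), obs)
    if (length(mis) == 0) next
    for (i in g) {
      cm <- conditional_normal_moments(mu, sigma, obs, x[i, obs])
      cc <- (cm$cov + t(cm$cov)) / 2
      ch <- tryCatch(chol(cc + diag(1e-10, length(mis))),
                     error = function(e) NULL)
      if (is.null(ch)) stop("singular conditional covariance")
      draw <- cm$mean + as.numeric(t(ch) %*% stats::rnorm(length(mis)))
      out[i, mis] <- pmin(pmax(draw, 0), 1)
    }
  }
  out
}

#' EM-based multiple imputation
#'
#' Bootstrap-EM multiple imputation under a multivariate-normal model
#' of the eight measured variables: for each of `m` imputations the
#' rows are bootstrap-resampled, the normal mean and covariance are
#' estimated on the resample by EM (ridge `1e-4 * I` on the
#' covariance; convergence when the largest parameter change falls
#' below `1e-6`), and each missing cell of the original data is drawn
#' from its conditional normal given the row's observed values under
#' that resample's parameters, clipped to `[0, 1]`.
#'
#' @inheritParams listwise_delete
#' @param m Number of imputations (5 in the benchmark).
#' @param seed Integer seed.
#' @param ridge Ridge added to the covariance each M-step.
#' @return A `handling_result` with `m` completed panels and
#'   diagnostics (per-imputation EM iteration counts), or a
#'   [method_failure()] when the estimated covariance becomes
#'   singular or EM cannot run.
#' @export
em_mi <- function(incomplete, m = 5L, seed = 1L, ridge = 1e-4) {
  vars <- measured_vars(incomplete)
  x <- measured_matrix(incomplete)
  if (!anyNA(x)) {
    fit <- tryCatch(em_mvn(x, ridge = ridge), error = function(e) e)
    if (inherits(fit, "error")) {
      return(method_failure("em_mi", conditionMessage(fit)))
    }
    return(handling_result("em_mi", rep(list(incomplete), m),
                           list(em_iterations = rep(fit$iterations, m),
                                note = "no missing cells")))
  }
  set.seed(seed)
  completed <- vector("list", m)
  iters <- integer(m)
  for (imp in seq_len(m)) {
    boot <- x[sample.int(nrow(x), replace = TRUE), , drop = FALSE]
    fit <- tryCatch(em_mvn(boot, ridge = ridge), error = function(e) e)
    if (inherits(fit, "error")) {
      return(method_failure("em_mi", conditionMessage(fit),
                            list(imputation = imp)))
    }
    filled <- tryCatch(mvn_draw_imputations(x, fit$mu, fit$sigma),
                       error = function(e) e)
    if (inherits(filled, "error")) {
      return(method_failure("em_mi", conditionMessage(filled),
                            list(imputation = imp)))
    }
    out <- incomplete
    out[, vars] <- filled
    completed[[imp]] <- out
    iters[imp] <- fit$iterations
  }
  handling_result("em_mi", completed, list(em_iterations = iters))
}

#' Predictive-mean-matching multiple imputation
#'
#' Chained-equations imputation over the eight measured variables with
#' the other seven measured variables plus the time variable as
#' predictors.  Missing cells start as random draws from each
#' variable's observed values; then for `n_sweeps` sweeps each target
#' variable is regressed (Bayesian linear regression on the rows where
#' it is observed, with a posterior draw of the coefficients), every
#' missing cell's prediction under the coefficient draw is matched to
#' the `donors` observed rows whose posterior-mean predictions are
#' closest (type-1 matching), and a uniformly chosen donor's observed
#' value is imputed.  The whole chain is repeated independently `m`
#' times.
#'
#' @inheritParams listwise_delete
#' @param m Number of imputations (5 in the benchmark).
#' @param seed Integer seed.
#' @param n_sweeps Chained-equation sweeps per imputation.
#' @param donors Donor-pool size d (default 5).
#' @return A `handling_result` with `m` completed panels, or a
#'   [method_failure()] when a variable has too few observed values to
#'   build a donor pool or fit its regression.
#' @export
pmm_mi <- function(incomplete, m = 5L, seed = 1L, n_sweeps = 10L,
                   donors = 5L) {
  vars <- measured_vars(incomplete)
  x <- measured_matrix(incomplete)
  if (!anyNA(x)) {
    return(handling_result("pmm_mi", rep(list(incomplete), m),
                           list(note = "no missing cells")))
  }
  n_days <- max(incomplete$day_index)
  time <- if (n_days > 1) (incomplete$day_index - 1) / (n_days - 1) else
    rep(0, nrow(incomplete))
  obs_mask <- !is.na(x)
  n_obs <- colSums(obs_mask)
  p_cols <- ncol(x) + 1 # other 7 measured + time, plus intercept below
  if (any(n_obs < donors + 1)) {
    return(method_failure("pmm_mi", paste0(
      "too few observed values for donor pool in: ",
      paste(vars[n_obs < donors + 1], collapse = ", "))))
  }
  if (any(n_obs < p_cols + 2)) {
    return(method_failure("pmm_mi", paste0(
      "too few observed values to fit regression for: ",
      paste(vars[n_obs < p_cols + 2], collapse = ", "))))
  }
  set.seed(seed)
  completed <- vector("list", m)
  for (imp in seq_len(m)) {
    cur <- x
    for (j in seq_len(ncol(x))) {
      miss <- !obs_mask[, j]
      if (any(miss)) {
        cur[miss, j] <- sample(x[obs_mask[, j], j], sum(miss),
                               replace = TRUE)
      }
    }
    for (sweep_i in seq_len(n_sweeps)) {
      for (j in seq_len(ncol(x))) {
        miss <- !obs_mask[, j]
        if (!any(miss)) next
        pred <- cbind(1, cur[, -j, drop = FALSE], time)
        po <- pred[!miss, , drop = FALSE]
        yo <- x[!miss, j]
        df <- nrow(po) - ncol(po)
        qr_o <- qr(po)
        if (qr_o$rank < ncol(po)) {
          # ridge-stabilize collinear predictors
          gram <- crossprod(po) + diag(1e-5, ncol(po))
          beta_hat <- solve(gram, crossprod(po, yo))
          cov_u <- solve(gram)
        } else {
          beta_hat <- qr.coef(qr_o, yo)
          r_inv <- backsolve(qr.R(qr_o), diag(ncol(po)))
          cov_u <- tcrossprod(r_inv)[order(qr_o$pivot), order(qr_o$pivot)]
        }
        resid <- yo - po %*% beta_hat
        sigma2 <- sum(resid^2) / stats::rchisq(1, max(df, 1))
        ch <- chol((cov_u + t(cov_u)) / 2 + diag(1e-12, ncol(po)))
        beta_draw <- beta_hat +
          sqrt(sigma2) * as.numeric(t(ch) %*% stats::rnorm(ncol(po)))
        yhat_obs <- as.numeric(po %*% beta_hat)
        yhat_mis <- as.numeric(pred[miss, , drop = FALSE] %*% beta_draw)
        mis_rows <- which(miss)
        for (ii in seq_along(mis_rows)) {
          pool <- order(abs(yhat_obs - yhat_mis[ii]))[seq_len(donors)]
          cur[mis_rows[ii], j] <- yo[sample(pool, 1)]
        }
      }
    }
    out <- incomplete
    out[, vars] <- cur
    completed[[imp]] <- out
  }
  handling_result("pmm_mi", completed,
                  list(n_sweeps = n_sweeps, donors = donors))
}

#' Apply a handling method by name
#'
#' Dispatcher used by the pipeline: runs one of the six methods on an
#' incomplete panel, converting any error raised inside a method into
#' a typed [method_failure()] so a sweep never crashes.
#'
#' @inheritParams listwise_delete
#' @param method One of [handling_methods()].
#' @param m Number of imputations for the multiple-imputation methods.
#' @param seed Seed passed to the stochastic methods.
#' @return A `handling_result` or [method_failure()].
#' @export
handle_missing <- function(incomplete, method, m = 5L, seed = 1L) {
  method <- match.arg(method, handling_methods())
  res <- tryCatch(
    switch(method,
      listwise = listwise_delete(incomplete),
      mean = mean_impute(incomplete),
      knn = knn_impute(incomplete),
      lowrank = soft_impute(incomplete, seed = seed),
      em_mi = em_mi(incomplete, m = m, seed = seed),
      pmm_mi = pmm_mi(incomplete, m = m, seed = seed)
    ),
    error = function(e) method_failure(method, conditionMessage(e))
  )
  res
}
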