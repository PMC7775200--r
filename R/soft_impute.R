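# soft-thresholded SVD of M, with singular values beyond max_rank
# hard-truncated; returns the reconstruction and the thresholded spectrum
svd_soft_threshold <- function(m, lambda, max_rank) {
  s <- svd(m)
  d <- pmax(s$d - lambda, 0)
  if (max_rank < length(d)) d[-seq_len(max_rank)] <- 0
  list(z = s$u %*% (d * t(s$v)), d = d)
}

# one soft-impute path: iterate Z <- SVT(P_obs(X) + P_miss(Z), lambda)
# to convergence for each lambda in turn, warm-starting from the
# previous solution.  Convergence uses the squared-Frobenius ratio
# ||Z_new - Z||_F^2 / max(||Z||_F^2, 1) < tol, the criterion of the
# standard soft-impute algorithm.
soft_impute_path <- function(xc, obs, lambdas, max_rank,
                             tol = 1e-5, max_iter = 500L) {
  z <- matrix(0, nrow(xc), ncol(xc))
  fill <- ifelse(obs, xc, 0)
  solutions <- vector("list", length(lambdas))
  iters <- integer(length(lambdas))
  for (li in seq_along(lambdas)) {
    lam <- lambdas[li]
    for (it in seq_len(max_iter)) {
      m <- ifelse(obs, fill, z)
      res <- svd_soft_threshold(m, lam, max_rank)
      delta <- sum((res$z - z)^2) / max(sum(z^2), 1)
      z <- res$z
      if (delta < tol) break
    }
    if (delta >= tol) {
      stop("soft-impute did not converge within ", max_iter,
           " iterations at lambda = ", signif(lam, 4),
           " (last relative change ", signif(delta, 4), ")")
    }
    solutions[[li]] <- list(z = z, d = res$d)
    iters[li] <- it
  }
  list(solutions = solutions, iters = iters)
}

#' Low-rank matrix-completion imputation (soft-impute)
#'
#' Treats the partially observed panel as a low-rank matrix and
#' completes it by iterative singular-value soft-thresholding:
#' `Z <- SVT(P_obs(X) + P_miss(Z), lambda)` until the squared relative
#' Frobenius change falls below `tol`.  By default the matrix is the
#' full design view — the eight measured variables plus the
#' fully-observed unit dummies and time column (884 x 49 for the
#' default reference) — so the completion can borrow the unit and
#' time structure; `use_design = FALSE` restricts it to the measured
#' block.  Columns are centered on observed means.
#'
#' The shrinkage `lambda` is chosen by warm starts over a decreasing
#' log-spaced grid from `lambda_max` (the largest singular value of
#' the zero-filled observed matrix, which yields the all-zero
#' solution) down to `lambda_max / 100`, scoring each value on a
#' held-out validation mask of 5% of the observed measured cells.
#' Imputations come from the best-lambda solution refit on all
#' observed cells, clipped to `[0, 1]`.
#'
#' @inheritParams listwise_delete
#' @param lambda Optional fixed shrinkage; skips warm-start selection.
#' @param max_rank Rank cap (default `min(dim) - 1`).
#' @param n_lambda Grid size for warm starts.
#' @param val_frac Fraction of observed measured cells held out for
#'   validation.
#' @param tol Convergence tolerance on the squared relative Frobenius
#'   change.
#' @param max_iter Iteration cap per lambda (exceeding it is an error
#'   carrying diagnostics).
#' @param center Center columns on observed means first (default TRUE;
#'   disable only for raw matrix-completion experiments).
#' @param use_design Include unit dummies and the time variable as
#'   additional (fully observed) columns of the completion matrix.
#' @param seed Seed for the validation mask.
#' @return A `handling_result` with one completed panel and
#'   diagnostics (`lambda`, `rank`, `iterations`, `lambda_grid`,
#'   `validation_rmse`), or a [method_failure()] when a column has no
#'   observed cells.
#' @export
soft_impute <- function(incomplete, lambda = NULL, max_rank = NULL,
                        n_lambda = 20L, val_frac = 0.05,
                        tol = 1e-5, max_iter = 500L,
                        center = TRUE, use_design = TRUE, seed = 1L) {
  vars <- measured_vars(incomplete)
  xm <- measured_matrix(incomplete)
  obs_m <- !is.na(xm)
  if (any(colSums(obs_m) == 0)) {
    return(method_failure("lowrank", paste0(
      "no observed cells in column(s): ",
      paste(vars[colSums(obs_m) == 0], collapse = ", "))))
  }
  if (all(obs_m)) {
    return(handling_result("lowrank", list(incomplete),
                           list(lambda = 0, rank = NA_integer_,
                                iterations = 0L, note = "no missing cells")))
  }
  use_design <- use_design &&
    all(c("unit_id", "day_index") %in% names(incomplete)) &&
    length(unique(incomplete$unit_id)) > 1 &&
    max(incomplete$day_index) > 1
  if (use_design) {
    x <- as.matrix(build_design(incomplete))
    mcols <- which(colnames(x) %in% vars)
  } else {
    x <- xm
    mcols <- seq_len(ncol(xm))
  }
  obs <- !is.na(x)
  if (is.null(max_rank)) max_rank <- min(dim(x)) - 1L
  mu <- if (center) colMeans(x, na.rm = TRUE) else rep(0, ncol(x))
  xc <- sweep(x, 2, mu)

  lambda_max <- svd(ifelse(obs, xc, 0))$d[1]
  if (is.null(lambda)) {
    lambdas <- exp(seq(log(lambda_max), log(lambda_max / 100),
                       length.out = n_lambda))
    # validation pass: hold out 5% of the observed measured cells
    set.seed(seed)
    cand <- which(obs & col(obs) %in% mcols)
    n_val <- max(1L, round(val_frac * length(cand)))
    val_idx <- sample(cand, n_val)
    train_obs <- obs
    train_obs[val_idx] <- FALSE
    if (any(colSums(train_obs) == 0)) {
      # degenerate holdout; fall back to full observed mask for training
      train_obs <- obs
    }
    val_path <- soft_impute_path(xc, train_obs, lambdas, max_rank,
                                 tol, max_iter)
    rmse <- vapply(val_path$solutions, function(sol) {
      sqrt(mean((sol$z[val_idx] - xc[val_idx])^2))
    }, numeric(1))
    best <- which.min(rmse)
    lambdas_final <- lambdas[seq_len(best)]
  } else {
    rmse <- NULL
    best <- 1L
    lambdas_final <- lambda
  }
  # final pass on all observed cells, warm-started down to best lambda
  path <- soft_impute_path(xc, obs, lambdas_final, max_rank, tol, max_iter)
  sol <- path$solutions[[length(path$solutions)]]
  completed <- sweep(ifelse(obs, xc, sol$z), 2, -mu)
  completed[!obs] <- pmin(pmax(completed[!obs], 0), 1)
  out <- incomplete
  out[, vars] <- completed[, mcols]
  handling_result(
    "lowrank", list(out),
    list(lambda = lambdas_final[length(lambdas_final)],
         rank = sum(sol$d > 1e-6),
         iterations = sum(path$iters),
         lambda_grid = if (is.null(lambda)) lambdas else lambda,
         validation_rmse = rmse,
         use_design = use_design)
  )
}
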