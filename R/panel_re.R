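#' Fit the one-way random-effects index model by feasible GLS
#'
#' Estimates the eight coefficients (intercept plus seven behavior
#' slopes) of the linear wellness index
#' `y_it = b0 + sum_k b_k x_k,it + mu_i + u_it`
#' with Swamy-Arora variance components: the idiosyncratic variance
#' from within (fixed-effects) residuals, the unit-effect variance from
#' the between regression on unit means (truncated at zero when the
#' moment estimate is negative), per-unit quasi-demeaning weights
#' `theta_i = 1 - sqrt(sigma_u^2 / (sigma_u^2 + T_i * sigma_mu^2))`
#' for an unbalanced panel, and OLS on the quasi-demeaned data.
#'
#' Unit identity comes from `unit_id`; dummy design columns, if
#' present, are ignored by the fit.
#'
#' @param panel Complete panel data frame with `unit_id` and the eight
#'   measured columns ([measured_vars()]).
#' @param var_components Optional list with `sigma_mu2` and `sigma_u2`
#'   to use directly (GLS with known variances), bypassing the
#'   Swamy-Arora estimation step.
#'
#' @return A list of class `"re_fit"` with `beta` and `se` (named
#'   length-8 vectors), `varcomp` (`sigma_mu2`, `sigma_u2`, per-unit
#'   `theta`), `n_rows` and `n_units` — or a [method_failure()] value
#'   when the model is not estimable (rank-deficient regressors, fewer
#'   rows than parameters, all units singleton, or fewer than two
#'   units).
#' @export
#' @examples
#' ref <- generate_reference(generator_config(seed = 1))
#' fit <- fit_random_effects(ref$panel)
#' round(fit$beta, 3)
fit_random_effects <- function(panel, var_components = NULL) {
  vars <- measured_vars(panel)
  behaviors <- vars[vars != "y"]
  if (anyNA(panel[, vars])) {
    stop("fit_random_effects() requires a complete panel")
  }
  n <- nrow(panel)
  k <- length(behaviors) # 7 slopes
  if (n < k + 2) {
    return(method_failure("panel_re", sprintf(
      "too few rows (%d) to estimate %d coefficients", n, k + 1)))
  }
  x <- as.matrix(panel[, behaviors])
  y <- panel$y
  id <- as.character(panel$unit_id)
  units <- unique(id)
  if (length(units) < 2) {
    return(method_failure("panel_re", "fewer than two units"))
  }
  if (qr(cbind(1, x))$rank < k + 1) {
    return(method_failure("panel_re", "regressor matrix is rank deficient"))
  }
  t_i <- table(id)[units]

  if (is.null(var_components)) {
    if (all(t_i == 1)) {
      return(method_failure(
        "panel_re", "all units singleton: within variance undefined"))
    }
    # within step: unit-demeaned OLS
    xm <- rowsum(x, id)[units, , drop = FALSE] / as.numeric(t_i)
    ym <- as.numeric(rowsum(y, id)[units, ]) / as.numeric(t_i)
    idx <- match(id, units)
    xw <- x - xm[idx, , drop = FALSE]
    yw <- y - ym[idx]
    df_within <- n - length(units) - k
    if (df_within < 1) {
      return(method_failure("panel_re", sprintf(
        "within degrees of freedom %d < 1", df_within)))
    }
    fw <- stats::lm.fit(xw, yw)
    sigma_u2 <- sum(fw$residuals^2) / df_within
    # between step: regression on unit means
    df_between <- length(units) - k - 1
    if (df_between < 1) {
      return(method_failure("panel_re", sprintf(
        "between degrees of freedom %d < 1 (%d units)",
        df_between, length(units))))
    }
    fb <- stats::lm.fit(cbind(1, xm), ym)
    sigma_b2 <- sum(fb$residuals^2) / df_between
    sigma_mu2 <- max(0, sigma_b2 - sigma_u2 * mean(1 / as.numeric(t_i)))
    if (sigma_u2 < 1e-12) {
      # perfect within fit: GLS degenerates; pooled OLS is exact here
      sigma_u2 <- 1
      sigma_mu2 <- 0
    }
  } else {
    sigma_mu2 <- var_components$sigma_mu2
    sigma_u2 <- var_components$sigma_u2
    stopifnot(sigma_mu2 >= 0, sigma_u2 > 0)
  }

  theta <- 1 - sqrt(sigma_u2 / (sigma_u2 + as.numeric(t_i) * sigma_mu2))
  names(theta) <- units
  idx <- match(id, units)
  xm <- rowsum(x, id)[units, , drop = FALSE] / as.numeric(t_i)
  ym <- as.numeric(rowsum(y, id)[units, ]) / as.numeric(t_i)
  xs <- cbind(intercept = 1 - theta[idx],
              x - theta[idx] * xm[idx, , drop = FALSE])
  ys <- y - theta[idx] * ym[idx]
  fit <- stats::lm.fit(xs, ys)
  if (fit$rank < k + 1) {
    return(method_failure("panel_re",
                          "quasi-demeaned regressors rank deficient"))
  }
  beta <- fit$coefficients
  s2 <- sum(fit$residuals^2) / (n - k - 1)
  piv <- fit$qr$pivot
  xtx_inv <- matrix(NA_real_, k + 1, k + 1)
  xtx_inv[piv, piv] <- chol2inv(qr.R(fit$qr))
  se <- sqrt(s2 * diag(xtx_inv))
  names(beta) <- names(se) <- c("intercept", behaviors)
  structure(
    list(beta = beta, se = se,
         varcomp = list(sigma_mu2 = unname(sigma_mu2),
                        sigma_u2 = unname(sigma_u2), theta = theta),
         n_rows = n, n_units = length(units)),
    class = "re_fit"
  )
}

#' @export
print.re_fit <- function(x, ...) {
  cat("One-way random-effects fit (", x$n_rows, " rows, ",
      x$n_units, " units)\n", sep = "")
  print(data.frame(estimate = round(x$beta, 4), se = round(x$se, 4)))
  cat("sigma_mu^2 =", signif(x$varcomp$sigma_mu2, 4),
      " sigma_u^2 =", signif(x$varcomp$sigma_u2, 4), "\n")
  invisible(x)
}
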