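# shared fixtures and independent oracles for the test suite

# default synthetic reference, generated once per test run
default_reference <- local({
  ref <- NULL
  function() {
    if (is.null(ref)) ref <<- generate_reference(generator_config(seed = 1))
    ref
  }
})

# a small complete panel with continuous behavior columns, built directly
# (not via the generator) so tests do not depend on it
toy_panel <- function(n_units = 4, n_days = 3, seed = 11,
                      sigma_mu = 0.05, sigma_u = 0.05,
                      beta = default_true_coefficients()) {
  set.seed(seed)
  n <- n_units * n_days
  x <- matrix(runif(n * 7), n, 7,
              dimnames = list(NULL, names(beta)[-1]))
  id <- rep(seq_len(n_units), each = n_days)
  mu <- rnorm(n_units, 0, sigma_mu)
  y <- beta[[1]] + as.numeric(x %*% unname(beta[-1])) +
    mu[id] + rnorm(n, 0, sigma_u)
  data.frame(unit_id = id, day_index = rep(seq_len(n_days), n_units),
             x, y = y)
}

# brute-force GLS oracle: beta = (X' Omega^-1 X)^-1 X' Omega^-1 y with
# Omega = sigma_u^2 I + sigma_mu^2 * blockdiag(ones), by direct inversion
gls_oracle <- function(panel, sigma_mu2, sigma_u2) {
  x <- cbind(1, as.matrix(panel[, measured_vars(panel)[1:7]]))
  y <- panel$y
  n <- nrow(panel)
  same <- outer(panel$unit_id, panel$unit_id, "==")
  omega <- sigma_u2 * diag(n) + sigma_mu2 * same
  oi <- solve(omega)
  as.numeric(solve(t(x) %*% oi %*% x, t(x) %*% oi %*% y))
}

# direct per-pair Dunnett C interval oracle (Welch df, studentized-range
# quantile), independent of dtk_pairwise's bookkeeping
dtk_oracle_wins <- function(samples, alpha = 0.05) {
  j <- length(samples)
  wins <- setNames(integer(j), names(samples))
  for (a in seq_len(j - 1)) {
    for (b in (a + 1):j) {
      xa <- samples[[a]]; xb <- samples[[b]]
      va <- var(xa) / length(xa); vb <- var(xb) / length(xb)
      den <- va^2 / (length(xa) - 1) + vb^2 / (length(xb) - 1)
      nu <- if (den > 0) (va + vb)^2 / den else Inf
      hw <- qtukey(1 - alpha, j, nu) / sqrt(2) * sqrt(va + vb)
      d <- mean(xa) - mean(xb)
      if (d + hw < 0) wins[a] <- wins[a] + 1L
      if (d - hw > 0) wins[b] <- wins[b] + 1L
    }
  }
  wins
}

expect_no_na <- function(panel) {
  expect_false(anyNA(panel[, measured_vars(panel)]))
}
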