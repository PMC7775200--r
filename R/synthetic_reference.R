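#' Min-max normalization
#'
#' Rescales a raw measurement from its native range to `[0, 1]`, the
#' scale on which all behavior variables and the proxy score live.
#'
#' @param x Numeric vector of raw values.
#' @param x_min,x_max Range of the variable; `x_max` must exceed `x_min`
#'   and all of `x` must lie within the range.
#'
#' @return `(x - x_min) / (x_max - x_min)`, elementwise in `[0, 1]`.
#' @export
#' @examples
#' normalize_minmax(50, 0, 100) # 0.5
normalize_minmax <- function(x, x_min, x_max) {
  if (!is.numeric(x) || !is.numeric(x_min) || !is.numeric(x_max)) {
    stop("normalize_minmax() expects numeric inputs")
  }
  if (x_max <= x_min) {
    stop("degenerate range: x_max must be strictly greater than x_min ",
         "(constant variable cannot be normalized)")
  }
  if (any(x < x_min | x > x_max, na.rm = TRUE)) {
    stop("values outside [x_min, x_max]")
  }
  (x - x_min) / (x_max - x_min)
}

#' Marginal specifications of the seven behavior variables
#'
#' Target marginals for the synthetic behavior block, on the normalized
#' `[0, 1]` scale.  Meal quality ratings are graded on
#' \{0, 0.33, 0.66, 1\}, exercise is binary \{0, 1\}, and the three
#' achievement percentages are continuous on `[0, 1]`.
#'
#' @return A data frame with columns `variable`, `mean`, `sd`, `type`.
#' @export
default_behavior_specs <- function() {
  data.frame(
    variable = c("breakfast", "lunch", "dinner", "exercise",
                 "step_ach", "sleep_ach", "golden_ach"),
    mean = c(0.242, 0.635, 0.755, 0.053, 0.746, 0.860, 0.142),
    sd   = c(0.362, 0.323, 0.275, 0.224, 0.286, 0.193, 0.251),
    type = c("graded", "graded", "graded", "binary",
             "continuous", "continuous", "continuous"),
    stringsAsFactors = FALSE
  )
}

#' Default ground-truth index coefficients
#'
#' Intercept plus the seven behavior slopes used to generate the proxy
#' score in the synthetic reference panel.
#'
#' @return Named numeric vector of length 8.
#' @export
default_true_coefficients <- function() {
  c(intercept = 0.305,
    breakfast = 0.097, lunch = 0.105, dinner = 0.088, exercise = 0.087,
    step_ach = 0.061, sleep_ach = 0.131, golden_ach = 0.066)
}

#' Configuration for the synthetic reference generator
#'
#' Describes the panel to emulate: 41 students observed daily for 28
#' days yields 1148 collected student-day observations, of which 264
#' are dropped (emulating device-failure exclusions) to leave an
#' 884-row complete reference panel.  The behavior block is generated
#' from a rank-`latent_rank` Gaussian copula so that the measured
#' matrix is approximately low rank, and the proxy score follows the
#' one-way random-effects model
#' `y_it = b0 + sum_k b_k x_k,it + mu_i + u_it` with
#' `mu_i ~ N(0, sigma_mu^2)` and `u_it ~ N(0, sigma_u^2)`.
#'
#' @param n_units Number of panel units (students).
#' @param n_days Number of days per unit.
#' @param n_collected Collected student-day rows; at most
#'   `n_units * n_days`.
#' @param n_excluded Rows dropped uniformly at random before the
#'   reference panel is formed.
#' @param behavior_specs Data frame as [default_behavior_specs()].
#' @param true_coefficients Named length-8 vector (intercept first).
#' @param sigma_mu SD of the unit random effect, on the `[0, 1]` scale.
#' @param sigma_u SD of the idiosyncratic error.
#' @param latent_rank Rank of the shared latent factor structure behind
#'   the behavior block; must be below `min(n_reference_rows, 8)`.
#' @param latent_noise Share (0-1) of each latent column's SD that is
#'   independent noise rather than common factors.
#' @param seed Integer seed; the generator is fully reproducible.
#'
#' @return A list of class `"generator_config"`.
#' @export
generator_config <- function(n_units = 41L, n_days = 28L,
                             n_collected = 1148L, n_excluded = 264L,
                             behavior_specs = default_behavior_specs(),
                             true_coefficients = default_true_coefficients(),
                             sigma_mu = 0.05, sigma_u = 0.1,
                             latent_rank = 5L, latent_noise = 0.3,
                             seed = 1L) {
  stopifnot(n_units >= 2, n_days >= 1, n_collected >= 1,
            n_excluded >= 0, n_excluded < n_collected,
            length(true_coefficients) == 8,
            sigma_mu >= 0, sigma_u >= 0,
            latent_noise >= 0, latent_noise <= 1)
  if (n_collected > n_units * n_days) {
    stop("n_collected exceeds the ", n_units, " x ", n_days, " unit-day grid")
  }
  n_ref <- n_collected - n_excluded
  if (latent_rank >= min(n_ref, 8L)) {
    stop("latent_rank must be below min(n_reference_rows, 8)")
  }
  req <- c("variable", "mean", "sd", "type")
  if (!all(req %in% names(behavior_specs)) || nrow(behavior_specs) != 7) {
    stop("behavior_specs must have 7 rows and columns variable/mean/sd/type")
  }
  structure(
    list(n_units = as.integer(n_units), n_days = as.integer(n_days),
         n_collected = as.integer(n_collected),
         n_excluded = as.integer(n_excluded),
         behavior_specs = behavior_specs,
         true_coefficients = true_coefficients,
         sigma_mu = sigma_mu, sigma_u = sigma_u,
         latent_rank = as.integer(latent_rank),
         latent_noise = latent_noise, seed = as.integer(seed)),
    class = "generator_config"
  )
}

# Quantile map from copula uniforms to one target marginal.
# graded: latent normal (location, scale) solved so that discretizing at
# the midpoints of {0,.33,.66,1} reproduces the target mean and SD.
# binary: success probability = target mean.
# continuous: moment-matched beta; requires sd^2 < mean*(1-mean).
marginal_transform <- function(u, spec) {
  m <- spec$mean
  s <- spec$sd
  switch(spec$type,
    binary = as.numeric(u > 1 - m),
    graded = {
      support <- c(0, 0.33, 0.66, 1)
      cuts <- c(0.165, 0.495, 0.83)
      moments <- function(par) {
        pr <- diff(c(0, stats::pnorm(cuts, par[1], exp(par[2])), 1))
        c(sum(pr * support), sqrt(sum(pr * support^2) - sum(pr * support)^2))
      }
      obj <- function(par) sum((moments(par) - c(m, s))^2)
      fit <- stats::optim(c(m, log(max(s, 0.05))), obj)
      if (fit$value > 1e-5) {
        stop("graded marginal for '", spec$variable,
             "' unreachable on {0,0.33,0.66,1} (mean ", m, ", sd ", s, ")")
      }
      pr <- diff(c(0, stats::pnorm(cuts, fit$par[1], exp(fit$par[2])), 1))
      support[findInterval(u, cumsum(pr)[1:3]) + 1]
    },
    continuous = {
      v <- s^2
      if (v >= m * (1 - m)) {
        stop("continuous marginal for '", spec$variable,
             "' unreachable on [0,1]: sd too large for the mean")
      }
      k <- m * (1 - m) / v - 1
      stats::qbeta(u, m * k, (1 - m) * k)
    },
    stop("unknown marginal type '", spec$type, "'")
  )
}

#' Generate the synthetic reference panel
#'
#' Draws the complete reference data set the benchmark perturbs:
#' `n_collected` unit-day rows whose seven behavior variables share a
#' low-rank latent Gaussian structure mapped through each variable's
#' target marginal, a proxy score generated from the one-way
#' random-effects model with the configured true coefficients, and a
#' uniform-at-random exclusion of `n_excluded` rows.  The reference
#' coefficients are then estimated by fitting the random-effects model
#' ([fit_random_effects()]) to the retained rows.
#'
#' @param config A [generator_config()].
#'
#' @return A list of class `"reference_data"` with elements
#'   `panel` (the reference rows: `unit_id`, `day_index`, seven
#'   behaviors, `y`), `reference_coefficients` (named length-8 vector
#'   estimated from the panel), `fit` (the full random-effects fit),
#'   `true_coefficients`, `n_clipped_y`, and `config`.
#' @export
#' @examples
#' ref <- generate_reference(generator_config(seed = 7))
#' nrow(ref$panel) # 884
generate_reference <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  n <- config$n_collected
  specs <- config$behavior_specs
  r <- config$latent_rank
  tau <- config$latent_noise

  # rank-r factor scores shared across the 7 behaviors, plus
  # independent noise; each latent column is marginally N(0, 1)
  f <- matrix(stats::rnorm(n * r), n, r)
  l <- matrix(stats::rnorm(7 * r), 7, r)
  l <- l / sqrt(rowSums(l^2))
  z <- sqrt(1 - tau^2) * (f %*% t(l)) + tau * matrix(stats::rnorm(n * 7), n, 7)
  u <- stats::pnorm(z)

  x <- matrix(NA_real_, n, 7, dimnames = list(NULL, specs$variable))
  for (j in seq_len(7)) {
    x[, j] <- marginal_transform(u[, j], specs[j, ])
  }

  grid <- expand.grid(day_index = seq_len(config$n_days),
                      unit_id = seq_len(config$n_units))[, 2:1]
  grid <- grid[seq_len(n), ]
  mu <- stats::rnorm(config$n_units, 0, config$sigma_mu)
  beta <- unname(config$true_coefficients)
  y_raw <- beta[1] + as.numeric(x %*% beta[-1]) +
    mu[grid$unit_id] + stats::rnorm(n, 0, config$sigma_u)
  n_clipped <- sum(y_raw < 0 | y_raw > 1)
  y <- pmin(pmax(y_raw, 0), 1)

  panel <- data.frame(unit_id = grid$unit_id, day_index = grid$day_index,
                      x, y = y, check.names = FALSE)
  keep <- sort(sample.int(n, n - config$n_excluded))
  panel <- panel[keep, ]
  rownames(panel) <- NULL

  fit <- fit_random_effects(panel)
  if (is_method_failure(fit)) {
    stop("reference panel not estimable: ", fit$reason)
  }
  structure(
    list(panel = panel,
         reference_coefficients = fit$beta,
         fit = fit,
         true_coefficients = config$true_coefficients,
         n_clipped_y = n_clipped,
         config = config),
    class = "reference_data"
  )
}

#' @export
print.reference_data <- function(x, ...) {
  cat("Synthetic reference panel: ", nrow(x$panel), " rows, ",
      length(unique(x$panel$unit_id)), " units\n", sep = "")
  cat("Reference coefficients:\n")
  print(round(x$reference_coefficients, 3))
  invisible(x)
}

#' Names of the eight measured variables
#'
#' The seven behavior variables plus the proxy score `y`: the columns
#' eligible for missingness injection and imputation.
#'
#' @param panel Optional panel data frame (used for validation only).
#' @return Character vector of length 8.
#' @export
measured_vars <- function(panel = NULL) {
  vars <- c(default_behavior_specs()$variable, "y")
  if (!is.null(panel) && !all(vars %in% names(panel))) {
    stop("panel is missing measured columns: ",
         paste(setdiff(vars, names(panel)), collapse = ", "))
  }
  vars
}

#' Build the full design view of a panel
#'
#' Appends the design columns that make the default reference data set
#' 884 x 49: one-hot dummies for every unit except the first (the
#' reference category) and a time variable mapping day 1 to 0 and the
#' last day to 1 linearly, `(day_index - 1) / (n_days - 1)`.  Column
#' order is: dummies `unit_2 ... unit_<n>`, `time`, the seven
#' behaviors, `y`.
#'
#' @param panel Panel data frame with `unit_id`, `day_index` and the
#'   eight measured columns.
#' @param n_days Number of days in the collection period; defaults to
#'   `max(panel$day_index)`.
#'
#' @return Data frame with `n_units - 1 + 1 + 8` columns.
#' @export
build_design <- function(panel, n_days = max(panel$day_index)) {
  vars <- measured_vars(panel)
  stopifnot(all(c("unit_id", "day_index") %in% names(panel)), n_days >= 2)
  units <- sort(unique(panel$unit_id))
  dummies <- sapply(units[-1], function(u) as.numeric(panel$unit_id == u))
  dummies <- matrix(dummies, nrow = nrow(panel),
                    dimnames = list(NULL, paste0("unit_", units[-1])))
  out <- data.frame(dummies,
                    time = (panel$day_index - 1) / (n_days - 1),
                    panel[, vars], check.names = FALSE)
  rownames(out) <- NULL
  out
}

#' Read and write panels as long-format CSV
#'
#' The on-disk interchange format is a plain CSV with header
#' `unit_id, day_index, breakfast, ..., golden_ach, y`; missing cells
#' are empty fields.
#'
#' @param panel Panel data frame.
#' @param path File path.
#' @return `read_panel()` returns the panel data frame;
#'   `write_panel()` returns `path` invisibly.
#' @export
write_panel <- function(panel, path) {
  utils::write.csv(panel, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
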