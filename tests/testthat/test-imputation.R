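incomplete_toy <- function(p = 20, seed = 4, n_units = 8, n_days = 10) {
  panel <- toy_panel(n_units = n_units, n_days = n_days, seed = seed)
  inject_mcar(panel, p, seed = seed + 1)$incomplete
}

test_that("listwise deletion keeps exactly the complete rows", {
  panel <- toy_panel(n_units = 5, n_days = 1, seed = 2)
  panel$breakfast[1] <- NA
  panel$y[2] <- NA
  res <- listwise_delete(panel)
  expect_s3_class(res, "handling_result")
  expect_equal(nrow(res$completed[[1]]), 3)
  # identity on complete input
  full <- toy_panel(seed = 3)
  expect_equal(listwise_delete(full)$completed[[1]], full)
  # all-incomplete input is a typed failure, not an error
  panel[, "lunch"] <- NA
  expect_true(is_method_failure(listwise_delete(panel)))
})

test_that("mean imputation substitutes observed column means", {
  panel <- toy_panel(n_units = 3, n_days = 1, seed = 5)
  panel$dinner <- c(0.2, NA, 0.4)
  res <- mean_impute(panel)
  expect_equal(res$completed[[1]]$dinner[2], 0.3)
  expect_equal(mean(res$completed[[1]]$dinner), mean(c(0.2, 0.4)))
  expect_equal(mean_impute(toy_panel(seed = 6))$completed[[1]],
               toy_panel(seed = 6))
  panel$dinner <- NA_real_
  expect_true(is_method_failure(mean_impute(panel)))
})

test_that("neighborhood size is the odd integer nearest sqrt(n)", {
  expect_equal(choose_k(884), 29)
  expect_equal(choose_k(9), 3)
  expect_equal(choose_k(100), 9) # tie between 9 and 11 broken downward
  expect_equal(choose_k(1), 1)
  expect_equal(choose_k(2), 1)
})

test_that("knn imputation matches a brute-force neighbor oracle", {
  # 3 complete donor rows plus one row missing its dinner value
  beta <- default_true_coefficients()
  base <- toy_panel(n_units = 4, n_days = 1, seed = 7)
  target <- base
  target$dinner[4] <- NA
  res <- knn_impute(target, k = 3)
  x <- as.matrix(base[, measured_vars()])
  obs <- setdiff(seq_len(8), which(colnames(x) == "dinner"))
  d <- sqrt(rowMeans((x[1:3, obs, drop = FALSE] -
                        rep(x[4, obs], each = 3))^2))
  w <- exp(-d^2)
  expect_equal(res$completed[[1]]$dinner[4],
               sum(w * x[1:3, "dinner"]) / sum(w))
  # k = 1 copies the unique nearest neighbor
  res1 <- knn_impute(target, k = 1)
  expect_equal(res1$completed[[1]]$dinner[4], x[1:3, "dinner"][which.min(d)])
  # identical donors make the neighborhood degenerate: any k agrees
  same <- base
  same[1:3, measured_vars()] <- rep(x[1, ], each = 3)
  same$dinner[4] <- NA
  for (k in c(1, 3)) {
    r <- knn_impute(same, k = k)
    expect_equal(r$completed[[1]]$dinner[4], unname(x[1, "dinner"]))
  }
})

test_that("knn fails as a value when donors are infeasible", {
  panel <- toy_panel(n_units = 4, n_days = 1, seed = 8)
  panel$breakfast <- NA_real_ # no complete rows
  expect_true(is_method_failure(knn_impute(panel)))
  panel2 <- toy_panel(n_units = 4, n_days = 1, seed = 8)
  panel2$lunch[1] <- NA
  expect_true(is_method_failure(knn_impute(panel2, k = 5)))
  # a row with nothing observed has no distances
  panel3 <- toy_panel(n_units = 4, n_days = 1, seed = 8)
  panel3[1, measured_vars()] <- NA_real_
  expect_true(is_method_failure(knn_impute(panel3, k = 1)))
})

test_that("soft impute recovers a noiseless rank-1 matrix", {
  set.seed(21)
  u <- runif(30, 0.2, 1)
  v <- runif(8, 0.2, 1)
  x <- outer(u, v)
  x <- x / max(x)
  panel <- data.frame(unit_id = rep(1:6, each = 5),
                      day_index = rep(1:5, 6),
                      x)
  names(panel)[3:10] <- measured_vars()
  masked <- inject_mcar(panel, 30, seed = 22)$incomplete
  res <- soft_impute(masked, lambda = 1e-6, max_rank = 1,
                     center = FALSE, use_design = FALSE,
                     tol = 1e-14, max_iter = 20000)
  got <- as.matrix(res$completed[[1]][, measured_vars()])
  expect_lt(max(abs(got - x)), 1e-3)
  expect_equal(res$diagnostics$rank, 1)
})

test_that("soft impute is identity without missing cells and shrinks to
           column means at lambda_max", {
  panel <- toy_panel(seed = 9)
  expect_equal(soft_impute(panel)$completed[[1]], panel)
  masked <- incomplete_toy(p = 20, seed = 10)
  x <- as.matrix(masked[, measured_vars()])
  xc <- sweep(x, 2, colMeans(x, na.rm = TRUE))
  lambda_max <- svd(ifelse(is.na(xc), 0, xc))$d[1]
  res <- soft_impute(masked, lambda = lambda_max * 1.0000001,
                     use_design = FALSE)
  out <- as.matrix(res$completed[[1]][, measured_vars()])
  mu <- colMeans(x, na.rm = TRUE)
  for (j in seq_len(8)) {
    miss <- is.na(x[, j])
    if (any(miss)) expect_equal(unname(out[miss, j]),
                                rep(unname(mu[j]), sum(miss)))
  }
})

test_that("soft impute warm starts record diagnostics and clip to [0,1]", {
  masked <- incomplete_toy(p = 30, seed = 12)
  res <- soft_impute(masked, seed = 5)
  expect_no_na(res$completed[[1]])
  vals <- as.matrix(res$completed[[1]][, measured_vars()])
  expect_true(all(vals >= 0 & vals <= 1 | !is.na(masked[, measured_vars()])))
  expect_length(res$diagnostics$validation_rmse, 20)
  expect_true(res$diagnostics$lambda %in% res$diagnostics$lambda_grid)
  expect_gte(res$diagnostics$rank, 1)
})

test_that("conditional-normal imputation reproduces the closed form", {
  mu <- c(0.3, 0.6)
  sigma <- matrix(c(0.04, 0.024, 0.024, 0.09), 2)
  cm <- lwibench:::conditional_normal_moments(mu, sigma, obs_idx = 2,
                                              obs_vals = 0.9)
  expect_equal(cm$mean, 0.3 + 0.024 / 0.09 * (0.9 - 0.6))
  expect_equal(cm$cov[1, 1], 0.04 - 0.024^2 / 0.09)
  # draws average to the conditional mean
  set.seed(30)
  draws <- replicate(4000, {
    z <- rnorm(1)
    cm$mean + sqrt(cm$cov[1, 1]) * z
  })
  expect_lt(abs(mean(draws) - cm$mean), 4 * sqrt(cm$cov[1, 1] / 4000))
})

test_that("em imputation yields m completed data sets and honors complete
           data", {
  masked <- incomplete_toy(p = 15, seed = 13, n_units = 10, n_days = 10)
  res <- em_mi(masked, m = 5, seed = 14)
  expect_length(res$completed, 5)
  for (d in res$completed) {
    expect_no_na(d)
    obs <- !is.na(masked[, measured_vars()])
    expect_equal(as.matrix(d[, measured_vars()])[obs],
                 as.matrix(masked[, measured_vars()])[obs])
  }
  full <- toy_panel(seed = 15)
  rc <- em_mi(full, m = 5, seed = 16)
  expect_length(rc$completed, 5)
  expect_equal(rc$completed[[1]], full)
})

test_that("pmm imputations are drawn from observed values", {
  masked <- incomplete_toy(p = 25, seed = 17, n_units = 10, n_days = 10)
  res <- pmm_mi(masked, m = 5, seed = 18)
  expect_length(res$completed, 5)
  x <- as.matrix(masked[, measured_vars()])
  for (d in res$completed) {
    expect_no_na(d)
    xd <- as.matrix(d[, measured_vars()])
    for (j in seq_len(8)) {
      miss <- is.na(x[, j])
      expect_true(all(xd[miss, j] %in% x[!miss, j]))
    }
  }
})

test_that("pmm with a perfectly linear target and one donor copies the
           closest predictor profile", {
  set.seed(19)
  n <- 60
  x <- matrix(runif(n * 7), n, 7)
  colnames(x) <- measured_vars()[1:7]
  y <- 0.2 + x %*% runif(7, 0.05, 0.1) # exact linear function, in [0,1]
  panel <- data.frame(unit_id = rep(1:6, each = 10),
                      day_index = rep(1:10, 6), x, y = as.numeric(y))
  target <- panel
  target$y[1] <- NA
  res <- pmm_mi(target, m = 1, seed = 20, n_sweeps = 1, donors = 1)
  # with a noiseless linear relation the predicted value for row 1 is
  # (up to the posterior draw) its true y; the closest donor by
  # prediction is the row whose true y is nearest
  imputed <- res$completed[[1]]$y[1]
  expect_true(imputed %in% panel$y[-1])
  expect_lt(abs(imputed - panel$y[1]), sort(abs(panel$y[-1] - panel$y[1]))[3])
})

test_that("pmm fails as a value when the donor pool is unconstructible", {
  panel <- toy_panel(n_units = 4, n_days = 1, seed = 21)
  panel$golden_ach <- c(0.1, NA, NA, NA) # one observed value < donors+1
  expect_true(is_method_failure(pmm_mi(panel)))
})

test_that("all handlers preserve observed cells and stay in [0,1]", {
  masked <- incomplete_toy(p = 20, seed = 23, n_units = 10, n_days = 10)
  x <- as.matrix(masked[, measured_vars()])
  obs <- !is.na(x)
  for (method in setdiff(handling_methods(), "listwise")) {
    res <- handle_missing(masked, method, m = 2, seed = 24)
    expect_s3_class(res, "handling_result")
    for (d in res$completed) {
      xd <- as.matrix(d[, measured_vars()])
      expect_equal(xd[obs], x[obs], info = method)
      expect_true(all(xd >= 0 & xd <= 1), info = method)
    }
  }
})

test_that("stochastic handlers are deterministic given the seed", {
  masked <- incomplete_toy(p = 20, seed = 25, n_units = 10, n_days = 10)
  for (method in c("lowrank", "em_mi", "pmm_mi")) {
    a <- handle_missing(masked, method, m = 2, seed = 31)
    b <- handle_missing(masked, method, m = 2, seed = 31)
    expect_equal(a$completed, b$completed, info = method)
  }
})
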