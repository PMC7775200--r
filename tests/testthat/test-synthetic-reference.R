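test_that("min-max normalization maps range endpoints and midpoints", {
  expect_equal(normalize_minmax(50, 0, 100), 0.5)
  expect_equal(normalize_minmax(0, 0, 100), 0)
  expect_equal(normalize_minmax(100, 0, 100), 1)
  expect_equal(normalize_minmax(c(6.7, 100), 6.7, 100), c(0, 1))
  expect_error(normalize_minmax(1, 3, 3), "degenerate")
  expect_error(normalize_minmax(5, 0, 4), "outside")
})

test_that("reference panel has the study dimensions and valid values", {
  ref <- default_reference()
  expect_equal(nrow(ref$panel), 1148 - 264)
  design <- build_design(ref$panel)
  expect_equal(ncol(design), 49)
  expect_equal(sum(startsWith(names(design), "unit_")), 40)
  expect_true(all(as.matrix(design) >= 0 & as.matrix(design) <= 1))
  expect_false(any(duplicated(ref$panel[, c("unit_id", "day_index")])))
  specs <- default_behavior_specs()
  for (v in specs$variable[specs$type == "graded"]) {
    expect_true(all(ref$panel[[v]] %in% c(0, 0.33, 0.66, 1)))
  }
  expect_true(all(ref$panel$exercise %in% c(0, 1)))
  expect_length(ref$reference_coefficients, 8)
})

test_that("time variable maps days linearly onto [0, 1]", {
  panel <- toy_panel(n_units = 3, n_days = 28)
  design <- build_design(panel)
  expect_equal(design$time[panel$day_index == 1][1], 0)
  expect_equal(design$time[panel$day_index == 28][1], 1)
  expect_equal(design$time[panel$day_index == 15][1], 14 / 27)
})

test_that("generation is reproducible and seed-sensitive", {
  a <- generate_reference(generator_config(seed = 5))
  b <- generate_reference(generator_config(seed = 5))
  c <- generate_reference(generator_config(seed = 6))
  expect_identical(a$panel, b$panel)
  expect_identical(a$reference_coefficients, b$reference_coefficients)
  expect_false(identical(a$panel, c$panel))
})

test_that("behavior marginals match their configured means", {
  # average over several generated panels; each sample mean should sit
  # within 3 Monte-Carlo standard errors of the target
  ref <- default_reference()
  specs <- default_behavior_specs()
  for (j in seq_len(nrow(specs))) {
    v <- specs$variable[j]
    se <- specs$sd[j] / sqrt(nrow(ref$panel))
    expect_lt(abs(mean(ref$panel[[v]]) - specs$mean[j]), 3 * se)
  }
  # proxy-score mean is implied by the true coefficients
  beta <- default_true_coefficients()
  implied <- beta[[1]] + sum(unname(beta[-1]) * specs$mean)
  expect_lt(abs(mean(ref$panel$y) - implied), 0.02)
})

test_that("measured block is approximately low rank", {
  ref <- default_reference()
  x <- scale(as.matrix(ref$panel[, measured_vars()]), scale = FALSE)
  d <- svd(x)$d
  r <- ref$config$latent_rank
  expect_gte(sum(d[seq_len(r + 1)]^2) / sum(d^2), 0.90)
})

test_that("noiseless continuous generation recovers the true coefficients", {
  specs <- default_behavior_specs()
  specs$type <- "continuous"
  specs$mean[specs$variable == "exercise"] <- 0.3
  specs$sd[specs$variable == "exercise"] <- 0.2
  cfg <- generator_config(n_units = 10, n_days = 20, n_collected = 200,
                          n_excluded = 20, behavior_specs = specs,
                          sigma_mu = 0, sigma_u = 0, seed = 3)
  ref <- generate_reference(cfg)
  expect_equal(unname(ref$reference_coefficients),
               unname(default_true_coefficients()), tolerance = 1e-8)
})

test_that("unreachable marginal specifications are rejected by name", {
  specs <- default_behavior_specs()
  specs$sd[specs$variable == "step_ach"] <- 0.6 # sd^2 > m(1-m)
  cfg <- generator_config(behavior_specs = specs, seed = 2)
  expect_error(generate_reference(cfg), "step_ach")
})

test_that("generator configuration invariants are enforced", {
  expect_error(generator_config(latent_rank = 8), "latent_rank")
  expect_error(generator_config(n_collected = 2000), "grid")
  cfg <- generator_config()
  expect_equal(cfg$n_collected - cfg$n_excluded, 884)
})

test_that("panels round-trip through CSV", {
  panel <- toy_panel()
  path <- withr::local_tempfile(fileext = ".csv")
  write_panel(panel, path)
  back <- read_panel(path)
  expect_equal(back, panel, tolerance = 1e-12)
})
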