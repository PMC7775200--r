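#' Configuration of a full benchmark experiment
#'
#' Bundles every knob of the end-to-end sweep.  `scale = "full"` is
#' the complete study design (the 1-80% grid with 200 replicates);
#' `scale = "smoke"` is a scaled-down design (proportions 10/40/70%,
#' 20 replicates) that preserves the qualitative findings and runs in
#' minutes on one CPU.
#'
#' @param generator A [generator_config()].
#' @param grid Percent proportions ([default_grid()] for full scale).
#' @param n_replicates Simulated data sets per proportion.
#' @param methods Subset of [handling_methods()].
#' @param m_imputations Imputations per multiple-imputation method.
#' @param alpha DTK significance level.
#' @param master_seed Master seed; every random draw in the sweep
#'   derives from it.
#' @param output_dir Optional directory for persisted CSV results;
#'   `NULL` keeps everything in memory.
#' @param scale `"full"` or `"smoke"`; smoke overrides `grid` and
#'   `n_replicates`.
#' @return A list of class `"experiment_config"`.
#' @export
experiment_config <- function(generator = generator_config(),
                              grid = default_grid(),
                              n_replicates = 200L,
                              methods = handling_methods(),
                              m_imputations = 5L,
                              alpha = 0.05,
                              master_seed = 1L,
                              output_dir = NULL,
                              scale = c("full", "smoke")) {
  scale <- match.arg(scale)
  if (scale == "smoke") {
    grid <- c(10, 40, 70)
    n_replicates <- 20L
  }
  methods <- match.arg(methods, handling_methods(), several.ok = TRUE)
  stopifnot(n_replicates >= 2, length(methods) >= 1, alpha > 0, alpha < 1)
  structure(
    list(generator = generator, grid = proportion_grid(grid),
         n_replicates = as.integer(n_replicates), methods = methods,
         m_imputations = as.integer(m_imputations), alpha = alpha,
         master_seed = as.integer(master_seed),
         output_dir = output_dir, scale = scale),
    class = "experiment_config"
  )
}

# canonical JSON of a config (for provenance / resume checks)
config_json <- function(config) {
  x <- config[setdiff(names(config), "output_dir")]
  x$generator <- x$generator[setdiff(names(x$generator), "behavior_specs")]
  x$behavior_specs <- config$generator$behavior_specs
  jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
}

# evaluate one (pattern, method) replicate: handle missing data, fit
# the random-effects model to each completed set, pool if needed, and
# return the MAB (or the failure)
evaluate_replicate <- function(pattern, method, reference_coefficients,
                               m_imputations, seed) {
  res <- handle_missing(pattern$incomplete, method,
                        m = m_imputations, seed = seed)
  if (is_method_failure(res)) return(res)
  fits <- lapply(res$completed, fit_random_effects)
  fail <- vapply(fits, is_method_failure, logical(1))
  if (any(fail)) {
    f <- fits[[which(fail)[1]]]
    return(method_failure(method, paste0("model fit failed: ", f$reason)))
  }
  pooled <- if (length(fits) > 1) pool_rubin(fits) else fits[[1]]
  list(mab = compute_mab(pooled$beta, reference_coefficients),
       beta = pooled$beta)
}

#' Run the end-to-end benchmark
#'
#' Generates the synthetic reference panel once, then for each
#' missingness proportion simulates incomplete data sets, applies each
#' handling method, fits the random-effects index model, pools
#' multiple imputations, computes per-replicate MABs and per-method
#' GABs, and runs the DTK pairwise comparison and range win sums.
#' Method failures are recorded (the GAB becomes undefined), never
#' raised.  When `output_dir` is set, the reference panel, per-
#' proportion bias records and all summary tables are written as CSV
#' with a `config.json` provenance file; rerunning against the same
#' directory resumes from the persisted per-proportion records and
#' refuses to resume when the stored configuration differs.
#'
#' @param config An [experiment_config()].
#' @return A list of class `"experiment_results"`: `reference`,
#'   `bias_records` (data frame `p, s, method, mab, failed, reason`),
#'   `gab` (data frame `p, method, gab, n_contributing, defined`),
#'   `outcomes` (per-proportion `"comparison_outcome"`), `win_table`,
#'   `range_sums`, `config`.
#' @export
run_experiment <- function(config = experiment_config(scale = "smoke")) {
  stopifnot(inherits(config, "experiment_config"))
  dir <- config$output_dir
  cj <- config_json(config)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    cfg_path <- file.path(dir, "config.json")
    if (file.exists(cfg_path)) {
      stored <- paste(readLines(cfg_path, warn = FALSE), collapse = "\n")
      if (!identical(stored, as.character(cj))) {
        stop("output_dir holds results from a different configuration; ",
             "refusing to resume")
      }
    } else {
      writeLines(as.character(cj), cfg_path)
    }
  }
  gen <- config$generator
  gen$seed <- derive_seed(config$master_seed, 0, 0)
  reference <- generate_reference(gen)
  if (!is.null(dir)) {
    write_panel(reference$panel, file.path(dir, "reference.csv"))
  }

  records <- list()
  for (p in config$grid) {
    p_path <- if (!is.null(dir)) {
      file.path(dir, sprintf("bias_p%03d.csv", round(p)))
    }
    if (!is.null(p_path) && file.exists(p_path)) {
      rec_p <- utils::read.csv(p_path, stringsAsFactors = FALSE)
    } else {
      batch <- simulate_batch(reference$panel, p, config$n_replicates,
                              config$master_seed)
      rows <- list()
      for (s in seq_along(batch)) {
        for (method in config$methods) {
          seed_ms <- derive_seed(config$master_seed, p,
                                 s * 131 + match(method, handling_methods()))
          ev <- evaluate_replicate(batch[[s]], method,
                                   reference$reference_coefficients,
                                   config$m_imputations, seed_ms)
          rows[[length(rows) + 1]] <- data.frame(
            p = p, s = s, method = method,
            mab = if (is_method_failure(ev)) NA_real_ else ev$mab,
            failed = is_method_failure(ev),
            reason = if (is_method_failure(ev)) ev$reason else "",
            stringsAsFactors = FALSE)
        }
      }
      rec_p <- do.call(rbind, rows)
      if (!is.null(p_path)) utils::write.csv(rec_p, p_path,
                                             row.names = FALSE)
    }
    records[[as.character(p)]] <- rec_p
  }
  bias_records <- do.call(rbind, records)
  rownames(bias_records) <- NULL

  gab_rows <- list()
  outcomes <- list()
  for (p in config$grid) {
    rec_p <- records[[as.character(p)]]
    samples <- list()
    for (method in config$methods) {
      mabs <- rec_p$mab[rec_p$method == method]
      g <- compute_gab(mabs, config$n_replicates)
      gab_rows[[length(gab_rows) + 1]] <- data.frame(
        p = p, method = method, gab = g$gab,
        n_contributing = g$n_contributing, defined = g$defined,
        stringsAsFactors = FALSE)
      samples[[method]] <- if (g$defined) mabs else NULL
    }
    if (sum(!vapply(samples, is.null, logical(1))) >= 2) {
      outcomes[[as.character(p)]] <- dtk_pairwise(samples, config$alpha)
    }
  }
  gab <- do.call(rbind, gab_rows)
  rownames(gab) <- NULL

  win_table <- NULL
  range_sums <- NULL
  if (length(outcomes) >= 1) {
    win_table <- do.call(rbind, lapply(names(outcomes), function(pn) {
      w <- outcomes[[pn]]$wins
      data.frame(p = as.numeric(pn), method = names(w),
                 wins = as.integer(w), row.names = NULL,
                 stringsAsFactors = FALSE)
    }))
    span <- range(config$grid)
    ranges <- list(c(1, 30), c(31, 60), c(61, 80))
    ranges <- Filter(function(r) any(config$grid >= r[1] &
                                       config$grid <= r[2]), ranges)
    if (length(ranges) == 0) ranges <- list(span)
    range_sums <- sum_wins(outcomes, ranges)
  }

  results <- structure(
    list(reference = reference, bias_records = bias_records, gab = gab,
         outcomes = outcomes, win_table = win_table,
         range_sums = range_sums, config = config),
    class = "experiment_results"
  )
  if (!is.null(dir)) {
    utils::write.csv(bias_records, file.path(dir, "bias_records.csv"),
                     row.names = FALSE)
    utils::write.csv(gab, file.path(dir, "gab.csv"), row.names = FALSE)
    if (!is.null(win_table)) {
      utils::write.csv(win_table, file.path(dir, "wins.csv"),
                       row.names = FALSE)
    }
    if (!is.null(range_sums)) {
      utils::write.csv(range_sums, file.path(dir, "range_sums.csv"),
                       row.names = FALSE)
    }
  }
  results
}

#' @export
print.experiment_results <- function(x, ...) {
  cat("Benchmark results (", x$config$scale, " scale): ",
      length(x$config$grid), " proportions x ", x$config$n_replicates,
      " replicates x ", length(x$config$methods), " methods\n", sep = "")
  print(utils::head(x$gab, 12))
  invisible(x)
}

#' Plot benchmark results
#'
#' Writes two figures: the GAB-versus-missingness-proportion curve per
#' method (curves stop where the GAB is undefined) and the
#' per-proportion pairwise-win counts.
#'
#' @param results An `"experiment_results"` object.
#' @param dir Directory for the figure files.
#' @param methods Optional subset of methods to plot.
#' @return Invisibly, the paths of the two written files.
#' @export
plot_results <- function(results, dir = ".",
                         methods = results$config$methods) {
  stopifnot(inherits(results, "experiment_results"))
  if (length(methods) == 0) stop("no methods selected to plot")
  gab <- results$gab[results$gab$defined & results$gab$method %in% methods, ]
  if (nrow(gab) == 0) stop("no defined GAB values to plot")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- ggplot2::ggplot(gab, ggplot2::aes(x = p, y = gab,
                                          colour = method)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "missingness proportion (%)",
                  y = "grand mean of absolute biases (GAB)",
                  colour = "method") +
    ggplot2::theme_minimal()
  f1 <- file.path(dir, "gab_curves.png")
  ggplot2::ggsave(f1, p1, width = 7, height = 4.5, dpi = 150)

  f2 <- file.path(dir, "win_counts.png")
  if (!is.null(results$win_table)) {
    wt <- results$win_table[results$win_table$method %in% methods, ]
    wt$wins[is.na(wt$wins)] <- 0L
    p2 <- ggplot2::ggplot(wt, ggplot2::aes(x = factor(p), y = wins,
                                           fill = method)) +
      ggplot2::geom_col(position = "dodge") +
      ggplot2::labs(x = "missingness proportion (%)",
                    y = "pairwise comparisons won", fill = "method") +
      ggplot2::theme_minimal()
    ggplot2::ggsave(f2, p2, width = 7, height = 4.5, dpi = 150)
  } else {
    f2 <- NULL
  }
  invisible(c(f1, f2))
}
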