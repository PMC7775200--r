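#' The default missingness-proportion grid
#'
#' Percent proportions at which incomplete data sets are simulated:
#' 1% to 80% in steps of 1%.
#'
#' @return Integer vector `1:80`.
#' @export
default_grid <- function() {
  proportion_grid(1:80)
}

#' @rdname default_grid
#' @param proportions Strictly increasing percentages in (0, 100).
#' @export
proportion_grid <- function(proportions) {
  p <- as.numeric(proportions)
  if (length(p) == 0 || any(p <= 0 | p >= 100) || any(diff(p) <= 0)) {
    stop("proportions must be strictly increasing and inside (0, 100)")
  }
  p
}

# round-half-to-even cell count for proportion p over n eligible cells
mask_cell_count <- function(p, n_eligible) {
  as.integer(round(p / 100 * n_eligible))
}

#' Inject missing-completely-at-random cells into a complete panel
#'
#' Deletes `round(p/100 * n_eligible)` cells chosen uniformly without
#' replacement from the eligible cells — the eight measured variables
#' only (7072 cells for the default 884-row reference); identifier,
#' dummy and time columns are never masked.  The deletion is
#' independent of all data values (MCAR).
#'
#' @param reference Complete panel data frame.
#' @param p Missingness proportion in percent, strictly inside (0, 100).
#' @param seed Integer seed making the pattern reproducible.
#'
#' @return A list of class `"mcar_pattern"`: `incomplete` (the panel
#'   with masked cells set to `NA`), `mask` (data frame of `row`,
#'   `variable`), `p`, `seed`, `n_masked`.
#' @export
#' @examples
#' ref <- generate_reference(generator_config(seed = 1))
#' sim <- inject_mcar(ref$panel, p = 10, seed = 42)
#' sim$n_masked # 707
inject_mcar <- function(reference, p, seed) {
  vars <- measured_vars(reference)
  if (anyNA(reference[, vars])) {
    stop("reference panel must be complete")
  }
  if (p <= 0 || p >= 100) {
    stop("p must be strictly between 0 and 100")
  }
  n_rows <- nrow(reference)
  n_eligible <- n_rows * length(vars)
  n_mask <- mask_cell_count(p, n_eligible)
  set.seed(seed)
  cells <- sample.int(n_eligible, n_mask)
  rows <- ((cells - 1) %% n_rows) + 1
  cols <- ((cells - 1) %/% n_rows) + 1
  incomplete <- reference
  for (j in seq_along(vars)) {
    hit <- rows[cols == j]
    if (length(hit)) incomplete[hit, vars[j]] <- NA_real_
  }
  structure(
    list(incomplete = incomplete,
         mask = data.frame(row = rows, variable = vars[cols],
                           stringsAsFactors = FALSE),
         p = p, seed = as.integer(seed), n_masked = n_mask),
    class = "mcar_pattern"
  )
}

#' Generate a batch of simulated incomplete data sets
#'
#' Draws `n_replicates` independent MCAR patterns at proportion `p`,
#' with per-replicate seeds derived deterministically from
#' `(master_seed, p, s)` so that any single replicate can be
#' regenerated in isolation.
#'
#' @param reference Complete panel data frame.
#' @param p Missingness proportion in percent.
#' @param n_replicates Number of simulated data sets (200 at full
#'   study scale).
#' @param master_seed Integer master seed for the batch.
#'
#' @return List of `n_replicates` `"mcar_pattern"` objects.
#' @export
simulate_batch <- function(reference, p, n_replicates = 200L,
                           master_seed = 1L) {
  stopifnot(n_replicates >= 1)
  lapply(seq_len(n_replicates), function(s) {
    pat <- inject_mcar(reference, p, derive_seed(master_seed, p, s))
    pat$s <- s
    pat
  })
}

#' @export
print.mcar_pattern <- function(x, ...) {
  cat("MCAR pattern: p = ", x$p, "%, ", x$n_masked, " masked cells (seed ",
      x$seed, ")\n", sep = "")
  invisible(x)
}

#' Serialize a missingness mask
#'
#' @param pattern An `"mcar_pattern"`.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(pattern, path) {
  utils::write.csv(pattern$mask, path, row.names = FALSE)
  invisible(path)
}
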