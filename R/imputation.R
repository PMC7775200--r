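#' Handling results
#'
#' Every missing-data handler returns a `handling_result`: the list of
#' completed panels (one for deletion / single-imputation methods, `m`
#' for multiple imputation), plus method-specific diagnostics.
#' Observed cells are never altered; completed panels contain no
#' missing measured cells.
#'
#' @param method Method identifier.
#' @param completed List of complete panel data frames.
#' @param diagnostics Named list of method-specific diagnostics.
#' @return An object of class `"handling_result"`.
#' @keywords internal
handling_result <- function(method, completed, diagnostics = list()) {
  structure(list(method = method, completed = completed,
                 diagnostics = diagnostics),
            class = "handling_result")
}

#' @export
print.handling_result <- function(x, ...) {
  cat("<handling result> ", x$method, ": ", length(x$completed),
      " completed data set(s)\n", sep = "")
  invisible(x)
}

#' The six benchmark methods
#'
#' @return Character vector of method identifiers in canonical order.
#' @export
handling_methods <- function() {
  c("listwise", "mean", "knn", "lowrank", "em_mi", "pmm_mi")
}

# measured block as a numeric matrix
measured_matrix <- function(panel) {
  as.matrix(panel[, measured_vars(panel)])
}

#' Listwise deletion
#'
#' Complete-case analysis: retains only rows where all eight measured
#' variables are observed.  With no complete rows left (or too few for
#' any downstream estimation) the result is a typed method failure, the
#' situation that makes this method's grand bias undefined at high
#' missingness.
#'
#' @param incomplete Panel data frame with `NA` cells.
#' @return A `handling_result` with one reduced-row panel, or a
#'   [method_failure()].
#' @export
listwise_delete <- function(incomplete) {
  keep <- stats::complete.cases(incomplete[, measured_vars(incomplete)])
  if (!any(keep)) {
    return(method_failure("listwise", "no complete rows remain"))
  }
  out <- incomplete[keep, ]
  rownames(out) <- NULL
  handling_result("listwise", list(out),
                  list(n_retained = sum(keep), n_dropped = sum(!keep)))
}

#' Mean imputation
#'
#' Substitutes each missing cell with the mean of the observed values
#' of its variable.
#'
#' @inheritParams listwise_delete
#' @return A `handling_result` with one completed panel, or a
#'   [method_failure()] when some variable has no observed values.
#' @export
mean_impute <- function(incomplete) {
  vars <- measured_vars(incomplete)
  x <- measured_matrix(incomplete)
  mu <- colMeans(x, na.rm = TRUE)
  if (anyNA(mu) || any(!is.finite(mu))) {
    bad <- vars[!is.finite(mu)]
    return(method_failure("mean", paste0(
      "no observed values in column(s): ", paste(bad, collapse = ", "))))
  }
  out <- incomplete
  for (j in seq_along(vars)) {
    miss <- is.na(x[, j])
    if (any(miss)) out[miss, vars[j]] <- mu[j]
  }
  handling_result("mean", list(out), list(column_means = mu))
}

#' Neighborhood size for k-nearest-neighbor imputation
#'
#' The odd integer closest to the square root of the number of complete
#' observations; when the square root sits exactly between two odd
#' integers the smaller one is taken.
#'
#' @param n_complete Number of complete rows (>= 1).
#' @return An odd positive integer.
#' @export
#' @examples
#' choose_k(884) # 29
choose_k <- function(n_complete) {
  stopifnot(n_complete >= 1)
  r <- sqrt(n_complete)
  lo <- 2 * floor((r - 1) / 2) + 1 # largest odd <= r (or r itself)
  hi <- lo + 2
  if (r - lo <= hi - r) as.integer(lo) else as.integer(hi)
}

#' k-nearest-neighbor imputation
#'
#' For each incomplete row, Euclidean distances to every complete row
#' are computed over the coordinates observed in that row (scaled by
#' the number of coordinates used), and each missing cell is replaced
#' by the kernel-weighted average of the k nearest complete rows'
#' values.  `k` defaults to [choose_k()] of the complete-row count.
#'
#' @inheritParams listwise_delete
#' @param k Neighborhood size; default [choose_k()] on the number of
#'   complete rows.
#' @param weighting `"gaussian"` (weights `exp(-dist^2)`, the default)
#'   or `"uniform"`.
#' @return A `handling_result` with one completed panel, or a
#'   [method_failure()] when there are no complete donor rows, fewer
#'   complete rows than `k`, or a row with no observed coordinates to
#'   measure distance from.
#' @export
knn_impute <- function(incomplete, k = NULL,
                       weighting = c("gaussian", "uniform")) {
  weighting <- match.arg(weighting)
  vars <- measured_vars(incomplete)
  x <- measured_matrix(incomplete)
  complete <- stats::complete.cases(x)
  n_complete <- sum(complete)
  if (n_complete == 0) {
    return(method_failure("knn", "no complete rows to serve as neighbors"))
  }
  if (is.null(k)) k <- choose_k(n_complete)
  if (n_complete < k) {
    return(method_failure("knn", sprintf(
      "only %d complete rows but k = %d", n_complete, k)))
  }
  donors <- x[complete, , drop = FALSE]
  out <- incomplete
  for (i in which(!complete)) {
    obs <- !is.na(x[i, ])
    if (!any(obs)) {
      return(method_failure("knn", sprintf(
        "row %d has no observed values to compute distances from", i)))
    }
    diff <- sweep(donors[, obs, drop = FALSE], 2, x[i, obs])
    d <- sqrt(rowSums(diff^2) / sum(obs))
    nn <- order(d)[seq_len(k)]
    w <- if (weighting == "gaussian") exp(-d[nn]^2) else rep(1, k)
    if (sum(w) < .Machine$double.eps) w <- rep(1, k)
    fill <- colSums(donors[nn, !obs, drop = FALSE] * w) / sum(w)
    out[i, vars[!obs]] <- fill
  }
  handling_result("knn", list(out),
                  list(k = k, n_complete = n_complete, weighting = weighting))
}
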