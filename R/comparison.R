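#' Dunnett-modified Tukey-Kramer pairwise comparison of MAB samples
#'
#' For every unordered pair of methods \{A, B\} with defined bias
#' samples at one missingness proportion, builds the Dunnett C-type
#' confidence interval for `mean(MAB_A) - mean(MAB_B)`:
#' half-width `q(alpha, J, nu_AB) / sqrt(2) *
#' sqrt(s_A^2/n_A + s_B^2/n_B)`, where `q` is the studentized-range
#' quantile for the number of compared methods `J` and `nu_AB` the
#' Welch-Satterthwaite degrees of freedom of the pair.  Method A
#' scores a win over B when the interval lies entirely below zero
#' (statistically smaller mean absolute bias).  Methods whose GAB is
#' undefined are excluded from `J` and from all pairs.
#'
#' @param mab_samples Named list: per-method numeric vectors of MABs
#'   (each of length >= 2).  Entries that are `NULL` or contain `NA`
#'   are treated as unavailable.
#' @param alpha Familywise significance level (default 0.05).
#' @return A list of class `"comparison_outcome"`: `wins` (named
#'   integer vector), `superior_set` (methods attaining the maximum
#'   win count), `pairs` (data frame of per-pair intervals), `J`,
#'   `alpha`.
#' @export
#' @examples
#' set.seed(1)
#' out <- dtk_pairwise(list(a = rnorm(50, 0.01, 0.001),
#'                          b = rnorm(50, 0.10, 0.001)))
#' out$wins
dtk_pairwise <- function(mab_samples, alpha = 0.05) {
  avail <- vapply(mab_samples, function(v) {
    !is.null(v) && !anyNA(v) && length(v) >= 2
  }, logical(1))
  samples <- mab_samples[avail]
  j <- length(samples)
  if (j < 2) stop("need at least two methods with defined bias samples")
  methods <- names(samples)
  n <- vapply(samples, length, numeric(1))
  mean_i <- vapply(samples, mean, numeric(1))
  var_i <- vapply(samples, stats::var, numeric(1))
  wins <- stats::setNames(integer(j), methods)
  pairs <- list()
  for (a in seq_len(j - 1)) {
    for (b in (a + 1):j) {
      va <- var_i[a] / n[a]
      vb <- var_i[b] / n[b]
      df_den <- va^2 / (n[a] - 1) + vb^2 / (n[b] - 1)
      nu <- if (df_den > 0) (va + vb)^2 / df_den else Inf
      half <- stats::qtukey(1 - alpha, j, nu) / sqrt(2) * sqrt(va + vb)
      diff_ab <- mean_i[a] - mean_i[b]
      if (diff_ab + half < 0) wins[a] <- wins[a] + 1L
      if (diff_ab - half > 0) wins[b] <- wins[b] + 1L
      pairs[[length(pairs) + 1]] <- data.frame(
        method_a = methods[a], method_b = methods[b],
        diff = diff_ab, lower = diff_ab - half, upper = diff_ab + half,
        df = nu, stringsAsFactors = FALSE)
    }
  }
  wins_all <- stats::setNames(rep(NA_integer_, length(mab_samples)),
                              names(mab_samples))
  wins_all[methods] <- wins
  structure(
    list(wins = wins_all,
         superior_set = methods[wins == max(wins)],
         pairs = do.call(rbind, pairs), J = j, alpha = alpha),
    class = "comparison_outcome"
  )
}

#' @export
print.comparison_outcome <- function(x, ...) {
  cat("DTK pairwise comparison (J = ", x$J, ", alpha = ", x$alpha, ")\n",
      sep = "")
  print(x$wins)
  cat("superior set:", paste(x$superior_set, collapse = ", "), "\n")
  invisible(x)
}

#' Sum pairwise-comparison wins over a missingness-proportion range
#'
#' Aggregates per-proportion win counts into range totals (the
#' summary-table view); the default ranges are 1-30%, 31-60% and
#' 61-80%.  A method with an undefined outcome at some proportion
#' contributes zero wins there.
#'
#' @param outcomes Named list (or list with `$p` fields) of
#'   `"comparison_outcome"` objects; names or fields give the percent
#'   proportion of each outcome.
#' @param ranges List of length-2 numeric vectors (closed intervals in
#'   percent).
#' @return Data frame: one row per range, one column per method, plus
#'   `range`.
#' @export
sum_wins <- function(outcomes,
                     ranges = list(c(1, 30), c(31, 60), c(61, 80))) {
  stopifnot(length(outcomes) >= 1, length(ranges) >= 1)
  ps <- as.numeric(names(outcomes))
  if (anyNA(ps)) stop("outcomes must be named by their percent proportion")
  methods <- unique(unlist(lapply(outcomes, function(o) names(o$wins))))
  rows <- lapply(ranges, function(r) {
    stopifnot(length(r) == 2, r[1] <= r[2])
    sel <- which(ps >= r[1] & ps <= r[2])
    if (length(sel) == 0) stop("no outcomes inside range [",
                               r[1], ", ", r[2], "]")
    total <- stats::setNames(rep(0L, length(methods)), methods)
    for (i in sel) {
      w <- outcomes[[i]]$wins
      w[is.na(w)] <- 0L
      total[names(w)] <- total[names(w)] + w
    }
    cbind(data.frame(range = paste0(r[1], "-", r[2], "%")),
          as.data.frame(as.list(total)))
  })
  do.call(rbind, rows)
}
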