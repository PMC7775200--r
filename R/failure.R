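#' Method-failure results
#'
#' A missing-data handling method or a downstream model fit can be
#' infeasible for a given incomplete data set (for example, listwise
#' deletion leaving too few complete rows to estimate eight
#' coefficients).  Such outcomes are first-class result values, not
#' errors: the benchmark records them and reports the corresponding
#' grand absolute bias as undefined rather than aborting a sweep.
#'
#' @param method Identifier of the handling method or fit that failed.
#' @param reason Short human-readable explanation.
#' @param diagnostics Optional named list with method-specific context.
#'
#' @return An object of class `"method_failure"`.
#' @export
#' @examples
#' f <- method_failure("listwise", "no complete rows")
#' is_method_failure(f)
method_failure <- function(method, reason, diagnostics = list()) {
  structure(
    list(method = method, reason = reason, diagnostics = diagnostics),
    class = "method_failure"
  )
}

#' @rdname method_failure
#' @param x Object to test.
#' @export
is_method_failure <- function(x) inherits(x, "method_failure")

#' @export
print.method_failure <- function(x, ...) {
  cat("<method failure> ", x$method, ": ", x$reason, "\n", sep = "")
  invisible(x)
}

# Deterministic per-task seed from (master_seed, p, s): a small
# multiply-xor integer hash done in double precision (exact below 2^53)
# and reduced mod 2^31 - 1 so any (p, s) cell is reproducible in
# isolation without advancing a shared RNG stream.
derive_seed <- function(master_seed, p, s) {
  m <- 2147483647 # 2^31 - 1
  h <- (as.numeric(master_seed) %% m + 1)
  for (v in c(as.numeric(p), as.numeric(s))) {
    h <- (h * 48271) %% m
    h <- (h + (v + 1) * 69621) %% m
    h <- (h * 16807) %% m
  }
  as.integer(h %% 2147483562 + 1)
}
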