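# Internal validation helpers. Validation failures carry class
# "elderfit_validation_error" so the CLI can map them to exit code 2;
# numerical failures carry "elderfit_numeric_error" (exit code 3).

abort_validation <- function(...) {
  stop(errorCondition(paste0(...), class = c("elderfit_validation_error", "error")))
}

abort_numeric <- function(...) {
  stop(errorCondition(paste0(...), class = c("elderfit_numeric_error", "error")))
}

check_ages <- function(ages, where = "schedule") {
  if (length(ages) < 2L)
    abort_validation(where, ": need at least two age classes")
  if (ages[1] != 0L)
    abort_validation(where, ": ages must start at 0, got ", ages[1])
  d <- diff(ages)
  if (any(d != 1L)) {
    bad <- ages[which(d != 1L)[1] + 1L]
    abort_validation(where, ": ages must be contiguous one-year classes; gap before age ", bad)
  }
  if (any(!is.finite(ages)))
    abort_validation(where, ": non-finite age")
  invisible(TRUE)
}

check_finite <- function(x, name) {
  if (any(!is.finite(x)))
    abort_validation(name, ": non-finite value at age ",
                     (which(!is.finite(x))[1] - 1L))
  invisible(TRUE)
}

check_range <- function(x, name, lo = -Inf, hi = Inf) {
  check_finite(x, name)
  bad <- which(x < lo | x > hi)
  if (length(bad))
    abort_validation(name, ": value ", signif(x[bad[1]], 6), " at age ", bad[1] - 1L,
                     " outside [", lo, ", ", hi, "]")
  invisible(TRUE)
}
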