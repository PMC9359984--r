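stop_domain <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_nonneg <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_domain(field, "must be a single finite number")
  }
  if (x < 0) stop_domain(field, sprintf("must be >= 0 (got %g)", x))
  invisible(x)
}

check_positive <- function(x, field) {
  check_nonneg(x, field)
  if (x <= 0) stop_domain(field, sprintf("must be > 0 (got %g)", x))
  invisible(x)
}

rel_err <- function(x, ref) {
  abs(x - ref) / max(abs(ref), .Machine$double.eps)
}
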