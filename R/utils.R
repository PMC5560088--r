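## internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not <- function(cond, ..., call. = FALSE) {
  if (!isTRUE(cond)) stop(..., call. = call.)
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 1 && x == floor(x)
}

is_number <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x)

# stream seeds derived from one master seed; kept below 2^31 so they are valid
# arguments to set.seed() and exactly representable as doubles in the C++ layer
derive_stream_seed <- function(seed, idx) {
  s <- (as.numeric(seed) %% 2147483647) * 48271
  ((s + as.numeric(idx) * 16807) %% 2147483647) + 1
}

# round half away from zero (base round() rounds half to even)
round_half_up <- function(x) floor(x + 0.5)

ht_log <- function(...) message("[hemitopo] ", ...)

check_symmetric <- function(m, tol = 1e-10, what = "matrix") {
  stop_if_not(is.matrix(m) && nrow(m) == ncol(m), what, " must be square")
  stop_if_not(max(abs(m - t(m))) <= tol, what, " must be symmetric (tolerance ", tol, ")")
  invisible(TRUE)
}

default_roi_names <- function(n) sprintf("ROI%02d", seq_len(n))
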