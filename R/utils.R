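# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# classed error so callers can distinguish contract violations programmatically
abort <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(paste0("chemcov_", class), "chemcov_error")))
}

#' Round half away from zero
#'
#' Standard `round()` rounds half to even; printed percentages in published
#' tables almost always round half away from zero (32.45 -> 32.5), so all
#' user-facing percentage formatting goes through this.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @keywords internal
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# log-space binomial ratio choose(n, k) / choose(N, k), safe for N in the
# hundreds; returns 0 when k > n
lchoose_ratio <- function(n, k, N) {
  out <- numeric(length(n))
  ok <- n >= k
  out[ok] <- exp(lchoose(n[ok], k) - lchoose(N, k))
  out
}

stopifnot_scalar_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x != floor(x))
    abort(sprintf("`%s` must be a single non-negative integer", name), "bad-argument")
  as.integer(x)
}
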