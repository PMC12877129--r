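# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(...) stop(..., call. = FALSE)

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_(sprintf("'%s' must be a single finite number", name))
  }
  if (strict_lower && x <= lower) {
    stop_(sprintf("'%s' must be > %g (got %g)", name, lower, x))
  }
  if (!strict_lower && x < lower) {
    stop_(sprintf("'%s' must be >= %g (got %g)", name, lower, x))
  }
  if (x > upper) {
    stop_(sprintf("'%s' must be <= %g (got %g)", name, upper, x))
  }
  invisible(x)
}

check_count <- function(x, name, lower = 1L) {
  check_scalar_number(x, name, lower = lower)
  if (x != round(x)) stop_(sprintf("'%s' must be an integer (got %g)", name, x))
  invisible(as.integer(x))
}

#' Rescale values linearly onto [0, 1]
#'
#' Min-max scaling; applying it to a vector that already spans \[0, 1\]
#' is the identity.
#'
#' @param x numeric vector with at least two distinct finite values.
#' @return numeric vector on \[0, 1\].
#' @keywords internal
minmax01 <- function(x) {
  r <- range(x)
  if (!all(is.finite(r))) stop_("cannot rescale non-finite values")
  if (r[1] == r[2]) stop_("cannot rescale a constant vector")
  (x - r[1]) / (r[2] - r[1])
}

# Run code under a temporary RNG seed; NULL seed leaves the RNG stream alone.
with_seed_ <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), code)
}
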