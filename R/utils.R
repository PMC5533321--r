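#' Wrap phases to the interval (-pi, pi]
#'
#' @param x numeric vector of angles in radians.
#' @return numeric vector of the same length with every element in
#'   `(-pi, pi]`.
#' @export
wrap_phase <- function(x) {
  w <- x - 2 * pi * round(x / (2 * pi))
  w[w <= -pi] <- w[w <= -pi] + pi * 2
  w
}

#' Derive a child seed from a base seed and a counter
#'
#' Counter-based derivation used by all sweep drivers so that every
#' (parameter value, run) cell gets an independent, reproducible seed.
#' The result always fits in a 32-bit integer.
#'
#' @param base integer base seed.
#' @param index non-negative integer counter.
#' @return a single integer seed.
#' @export
derive_seed <- function(base, index) {
  m <- 2147483647
  s <- (abs(as.numeric(base)) %% m) * 48271 + as.numeric(index) * 7919 + 1
  as.integer(s %% m)
}

# internal: set the RNG only when a seed is supplied
seed_if_given <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}

# internal: scalar checks with informative messages
check_number <- function(x, name, lower = -Inf, upper = Inf,
                         integer = FALSE, strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number (got %s)",
                 name, deparse(x)), call. = FALSE)
  if (strict_lower) {
    if (x <= lower)
      stop(sprintf("'%s' must be > %g (got %g)", name, lower, x),
           call. = FALSE)
  } else if (x < lower) {
    stop(sprintf("'%s' must be >= %g (got %g)", name, lower, x),
         call. = FALSE)
  }
  if (x > upper)
    stop(sprintf("'%s' must be <= %g (got %g)", name, upper, x),
         call. = FALSE)
  if (integer && x != round(x))
    stop(sprintf("'%s' must be an integer (got %g)", name, x), call. = FALSE)
  x
}
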