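#' Natural-frequency distribution of the oscillator ensemble
#'
#' Describes the density g(omega) from which the oscillators' natural
#' frequencies are drawn.  The Gaussian family is the working default; the
#' Lorentzian (Cauchy) family is provided because it admits the closed-form
#' steady-state order parameter r = sqrt(1 - 2*gamma/K) for K > 2*gamma,
#' which serves as an analytic validation oracle.
#'
#' @param family `"gaussian"` or `"lorentzian"`.
#' @param location centre of the density (rad/time).
#' @param scale spread: standard deviation for the Gaussian family,
#'   half-width gamma for the Lorentzian.  Must be strictly positive.
#' @return an object of class `freq_dist`.
#' @export
#' @examples
#' freq_dist("gaussian", 0, 1)
freq_dist <- function(family = c("gaussian", "lorentzian"),
                      location = 0, scale = 1) {
  family <- match.arg(family)
  check_number(location, "location")
  check_number(scale, "scale", lower = 0, strict_lower = TRUE)
  structure(list(family = family, location = location, scale = scale),
            class = "freq_dist")
}

#' @export
print.freq_dist <- function(x, ...) {
  cat(sprintf("g(omega): %s(location = %g, scale = %g)\n",
              x$family, x$location, x$scale))
  invisible(x)
}

#' Sample natural frequencies from g(omega)
#'
#' @param dist a [freq_dist()] object.
#' @param n number of draws (>= 1).
#' @param seed optional integer seed; `NULL` uses the current RNG state.
#' @return numeric vector of `n` i.i.d. draws.
#' @export
sample_frequencies <- function(dist, n, seed = NULL) {
  stopifnot(inherits(dist, "freq_dist"))
  check_number(n, "n", lower = 1, integer = TRUE)
  seed_if_given(seed)
  switch(dist$family,
         gaussian   = rnorm(n, mean = dist$location, sd = dist$scale),
         lorentzian = rcauchy(n, location = dist$location, scale = dist$scale))
}
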