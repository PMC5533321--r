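#' Configuration of a mean-field Kuramoto simulation
#'
#' The ensemble obeys, per oscillator,
#'   d(theta_i) = (omega_i + K r sin(psi - theta_i)) dt + sigma dW_i,
#' i.e. the mean-field model with additive white frequency noise of
#' intensity `noise_sigma^2` integrated by the Euler--Maruyama scheme.
#' The order parameter r e^{i psi} is the mean unit phasor of the phases.
#'
#' @param n_oscillators ensemble size N.
#' @param coupling coupling constant K (>= 0).
#' @param noise_sigma noise amplitude sigma (>= 0, rad/sqrt(time)); the
#'   per-step phase kick has standard deviation `sigma * sqrt(dt)`.
#' @param dt integration step (> 0).
#' @param n_steps total number of integration steps.
#' @param transient_steps steps discarded as equilibration transient
#'   (default: half of `n_steps`).
#' @param thin record r every `thin` steps (default 50, i.e. every 0.5 time
#'   units at the default dt); successive recorded samples are then
#'   meaningfully decorrelated away from criticality.
#' @param freq_dist a [freq_dist()] describing g(omega).
#' @param seed integer seed controlling frequencies, initial phases and
#'   noise.
#' @return an object of class `kuramoto_config`.
#' @export
kuramoto_config <- function(n_oscillators = 2000, coupling = 1,
                            noise_sigma = 0, dt = 0.01, n_steps = 20000,
                            transient_steps = n_steps %/% 2, thin = 50,
                            freq_dist = ewdyn::freq_dist("gaussian", 0, 1),
                            seed = 1) {
  check_number(n_oscillators, "n_oscillators", lower = 1, integer = TRUE)
  check_number(coupling, "coupling", lower = 0)
  check_number(noise_sigma, "noise_sigma", lower = 0)
  check_number(dt, "dt", lower = 0, strict_lower = TRUE)
  check_number(n_steps, "n_steps", lower = 1, integer = TRUE)
  check_number(transient_steps, "transient_steps", lower = 0, integer = TRUE)
  check_number(thin, "thin", lower = 1, integer = TRUE)
  if (transient_steps >= n_steps)
    stop("'transient_steps' must be < 'n_steps'", call. = FALSE)
  stopifnot(inherits(freq_dist, "freq_dist"))
  structure(list(n_oscillators = as.integer(n_oscillators),
                 coupling = coupling, noise_sigma = noise_sigma, dt = dt,
                 n_steps = as.integer(n_steps),
                 transient_steps = as.integer(transient_steps),
                 thin = as.integer(thin), freq_dist = freq_dist,
                 seed = as.integer(seed)),
            class = "kuramoto_config")
}

#' @export
print.kuramoto_config <- function(x, ...) {
  cat(sprintf(
    "Kuramoto config: N = %d, K = %g, sigma = %g, dt = %g, steps = %d (transient %d, thin %d), seed = %d\n",
    x$n_oscillators, x$coupling, x$noise_sigma, x$dt, x$n_steps,
    x$transient_steps, x$thin, x$seed))
  print(x$freq_dist)
  invisible(x)
}

#' Instantaneous state of the oscillator ensemble
#'
#' @param phases numeric vector of phases theta_i (wrapped to `(-pi, pi]`).
#' @param nat_freqs numeric vector of natural frequencies omega_i, same
#'   length as `phases`.
#' @return an object of class `oscillator_ensemble`.
#' @export
oscillator_ensemble <- function(phases, nat_freqs) {
  if (length(phases) != length(nat_freqs))
    stop("'phases' and 'nat_freqs' must have equal length", call. = FALSE)
  if (length(phases) == 0L)
    stop("empty ensemble", call. = FALSE)
  if (!all(is.finite(phases)) || !all(is.finite(nat_freqs)))
    stop("phases and natural frequencies must be finite", call. = FALSE)
  structure(list(phases = wrap_phase(as.numeric(phases)),
                 nat_freqs = as.numeric(nat_freqs)),
            class = "oscillator_ensemble")
}

#' Kuramoto order parameter
#'
#' r e^{i psi} = (1/N) sum_j e^{i theta_j}: r measures overall
#' synchronization (0 incoherent, 1 fully locked) and psi is the collective
#' phase.
#'
#' @param phases non-empty numeric vector of phases (radians).
#' @return list with components `r` (in `[0, 1]`) and `psi` (in
#'   `(-pi, pi]`).
#' @export
#' @examples
#' order_parameter(c(0, pi / 2))  # r = sqrt(2)/2, psi = pi/4
order_parameter <- function(phases) {
  if (length(phases) == 0L)
    stop("'phases' must be non-empty", call. = FALSE)
  z <- mean(exp(1i * phases))
  list(r = min(Mod(z), 1), psi = Arg(z))
}

#' Advance the ensemble by one forward step
#'
#' One Euler--Maruyama update: the deterministic drift uses r and psi
#' computed from the pre-step phases; when `noise_sigma > 0` each
#' oscillator receives an independent Gaussian phase kick of standard
#' deviation `noise_sigma * sqrt(dt)` drawn from R's RNG in oscillator
#' order.  Phases are re-wrapped to `(-pi, pi]`.
#'
#' @param state an [oscillator_ensemble()].
#' @param config a [kuramoto_config()]; only `coupling`, `noise_sigma` and
#'   `dt` are used.
#' @return the updated `oscillator_ensemble`, with the pre-step order
#'   parameter attached as attributes `r` and `psi`.
#' @export
kuramoto_step <- function(state, config) {
  stopifnot(inherits(state, "oscillator_ensemble"),
            inherits(config, "kuramoto_config"))
  out <- kuramoto_step_core(state$phases, state$nat_freqs,
                            config$coupling, config$noise_sigma, config$dt)
  res <- oscillator_ensemble(out$phases, state$nat_freqs)
  attr(res, "r") <- out$r
  attr(res, "psi") <- out$psi
  res
}

#' Simulate the noisy mean-field Kuramoto model
#'
#' Initial phases are i.i.d. uniform on `(-pi, pi]` and natural frequencies
#' are drawn from `config$freq_dist`; the ensemble is then integrated for
#' `n_steps` steps.  r is recorded every `thin` steps and samples from the
#' first `transient_steps` steps are discarded.  The run is bit-reproducible
#' given `config$seed`.
#'
#' @param config a [kuramoto_config()].
#' @return an object of class `r_trace`: list with `times`, `r_values` and
#'   the generating `config`.
#' @export
simulate_kuramoto <- function(config) {
  stopifnot(inherits(config, "kuramoto_config"))
  set.seed(config$seed)
  N <- config$n_oscillators
  omega <- sample_frequencies(config$freq_dist, N)
  phases <- wrap_phase(runif(N, -pi, pi))
  r <- kuramoto_run_core(phases, omega, config$coupling, config$noise_sigma,
                         config$dt, config$n_steps, config$transient_steps,
                         config$thin)
  steps <- seq(config$thin, config$n_steps, by = config$thin)
  steps <- steps[steps > config$transient_steps]
  structure(list(times = steps * config$dt, r_values = r, config = config),
            class = "r_trace")
}

#' @export
print.r_trace <- function(x, ...) {
  cat(sprintf(
    "r(t) trace: %d samples over t = [%g, %g], <r> = %.4f (K = %g, sigma = %g, N = %d)\n",
    length(x$r_values), min(x$times), max(x$times), mean(x$r_values),
    x$config$coupling, x$config$noise_sigma, x$config$n_oscillators))
  invisible(x)
}

#' @export
as.data.frame.r_trace <- function(x, ...) {
  data.frame(time = x$times, r = x$r_values)
}

#' Sweep the coupling constant
#'
#' For each value of K, runs `n_runs` independent simulations whose seeds
#' are derived deterministically from `config$seed` with a running counter,
#' so the whole sweep is reproducible.
#'
#' @param config template [kuramoto_config()]; its `coupling` field is
#'   overridden per sweep value.
#' @param k_values non-empty vector of non-negative coupling values, used
#'   in input order.
#' @param n_runs independent runs per value (>= 1).
#' @return an object of class `coupling_sweep`: a named list (one element
#'   per K, in input order) of lists of `r_trace` objects.
#' @export
sweep_coupling <- function(config, k_values, n_runs = 1) {
  stopifnot(inherits(config, "kuramoto_config"))
  if (length(k_values) == 0L || any(!is.finite(k_values)) || any(k_values < 0))
    stop("'k_values' must be non-empty, finite and non-negative",
         call. = FALSE)
  check_number(n_runs, "n_runs", lower = 1, integer = TRUE)
  counter <- 0L
  out <- lapply(k_values, function(k) {
    lapply(seq_len(n_runs), function(j) {
      cfg <- config
      cfg$coupling <- k
      cfg$seed <- derive_seed(config$seed, counter)
      counter <<- counter + 1L
      simulate_kuramoto(cfg)
    })
  })
  names(out) <- format(k_values)
  structure(out, k_values = k_values, class = "coupling_sweep")
}
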