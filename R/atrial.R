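#' Configuration of the atrial-tissue cellular automaton
#'
#' A cylindrical L x L lattice of tissue blocks.  Horizontal neighbours are
#' always connected (no wraparound: the first and last columns connect in
#' one direction only); vertical neighbours are connected independently
#' with probability `nu`, cyclically in the vertical direction.  A fraction
#' `delta` of blocks is defective and fails to excite with probability
#' `epsilon` per opportunity.  Excited blocks enter a refractory period of
#' `refractory_steps` steps during which they cannot be re-excited; sparse
#' vertical connectivity plus conduction failure lets wavefronts re-enter
#' behind the refractory tail, the automaton's analogue of fibrillation.
#'
#' @param grid_size lattice side L (default 200, i.e. 20 cm^2 of tissue at
#'   five cells per block).
#' @param nu vertical-connection probability in `[0, 1]` (control
#'   parameter).
#' @param delta fraction of defective blocks (default 0.05).
#' @param epsilon per-opportunity conduction-failure probability of a
#'   defective block (default 0.05).
#' @param refractory_steps refractory length tau in steps (default 50).
#' @param ms_per_step physical duration of one step (default 0.06 ms, so
#'   the reference 13.2 ms pacing interval is exactly 220 steps).
#' @param n_steps number of recorded steps per run (default 20000).
#' @param warmup_steps steps simulated and discarded before recording
#'   starts (default 2000, about nine pacing cycles).
#' @param seed integer seed controlling the lattice draw, conduction
#'   failures and (through derived seeds) stochastic pacing.
#' @return an object of class `atrial_config`.
#' @export
atrial_config <- function(grid_size = 200, nu = 0.14, delta = 0.05,
                          epsilon = 0.05, refractory_steps = 50,
                          ms_per_step = 0.06, n_steps = 20000,
                          warmup_steps = 2000, seed = 1) {
  check_number(grid_size, "grid_size", lower = 1, integer = TRUE)
  check_number(nu, "nu", lower = 0, upper = 1)
  check_number(delta, "delta", lower = 0, upper = 1)
  check_number(epsilon, "epsilon", lower = 0, upper = 1)
  check_number(refractory_steps, "refractory_steps", lower = 1,
               integer = TRUE)
  check_number(ms_per_step, "ms_per_step", lower = 0, strict_lower = TRUE)
  check_number(n_steps, "n_steps", lower = 1, integer = TRUE)
  check_number(warmup_steps, "warmup_steps", lower = 0, integer = TRUE)
  structure(list(grid_size = as.integer(grid_size), nu = nu, delta = delta,
                 epsilon = epsilon,
                 refractory_steps = as.integer(refractory_steps),
                 ms_per_step = ms_per_step, n_steps = as.integer(n_steps),
                 warmup_steps = as.integer(warmup_steps),
                 seed = as.integer(seed)),
            class = "atrial_config")
}

#' @export
print.atrial_config <- function(x, ...) {
  cat(sprintf(
    "Atrial CA config: %dx%d, nu = %g, delta = %g, epsilon = %g, tau = %d steps, %g ms/step, %d steps (+%d warmup), seed = %d\n",
    x$grid_size, x$grid_size, x$nu, x$delta, x$epsilon, x$refractory_steps,
    x$ms_per_step, x$n_steps, x$warmup_steps, x$seed))
  invisible(x)
}

#' Rectangular signal-extraction region
#'
#' Ranges are 1-based and inclusive, in lattice coordinates.
#'
#' @param row_start,row_end first and last row of the region.
#' @param col_start,col_end first and last column of the region.
#' @return an object of class `signal_region`.
#' @export
signal_region <- function(row_start, row_end, col_start, col_end) {
  for (v in c(row_start, row_end, col_start, col_end))
    check_number(v, "region bound", lower = 1, integer = TRUE)
  if (row_end < row_start || col_end < col_start)
    stop("signal region must be non-empty", call. = FALSE)
  structure(list(row_start = as.integer(row_start),
                 row_end = as.integer(row_end),
                 col_start = as.integer(col_start),
                 col_end = as.integer(col_end)),
            class = "signal_region")
}

#' Default signal region: all rows x the central quarter of columns
#'
#' For the default 200 x 200 lattice this is the 200 x 50 band of columns
#' 76..125, spanning the full cylinder circumference in the middle of the
#' conduction path.
#'
#' @param config an [atrial_config()].
#' @return a [signal_region()].
#' @export
default_region <- function(config) {
  L <- config$grid_size
  w <- max(1L, L %/% 4L)
  c0 <- (L - w) %/% 2L + 1L
  signal_region(1L, L, c0, c0 + w - 1L)
}

#' Build the lattice for one run
#'
#' Seeds the RNG from `config$seed`, draws every downward vertical link
#' independently Bernoulli(nu) (cyclic: row L links to row 1) and marks
#' exactly `round(delta * L^2)` distinct blocks defective, chosen uniformly.
#' All blocks start at rest.
#'
#' @param config an [atrial_config()].
#' @return an object of class `atrial_grid`: list with the integer `state`
#'   matrix (0 rest, tau+1 excited, tau..1 refractory countdown), logical
#'   `vlink` and `defective` matrices, and the `config`.
#' @export
build_grid <- function(config) {
  stopifnot(inherits(config, "atrial_config"))
  set.seed(config$seed)
  L <- config$grid_size
  vlink <- matrix(runif(L * L) < config$nu, L, L)
  defective <- matrix(FALSE, L, L)
  ndef <- round(config$delta * L * L)
  if (ndef > 0)
    defective[sample.int(L * L, ndef)] <- TRUE
  structure(list(state = matrix(0L, L, L), vlink = vlink,
                 defective = defective, config = config),
            class = "atrial_grid")
}

#' Inject a pacemaker pulse
#'
#' Every first-column block currently at rest becomes excited; refractory
#' blocks are left alone (the refractory rule has precedence).
#'
#' @param grid an [build_grid()] lattice.
#' @return the updated `atrial_grid`.
#' @export
inject_pulse <- function(grid) {
  stopifnot(inherits(grid, "atrial_grid"))
  exc <- grid$config$refractory_steps + 1L
  col1 <- grid$state[, 1L]
  col1[col1 == 0L] <- exc
  grid$state[, 1L] <- col1
  grid
}

#' One synchronous automaton step
#'
#' From the pre-step state: excited blocks enter refractoriness with
#' counter tau; refractory counters decrement (1 -> rest); a resting block
#' with at least one excited connected neighbour becomes excited, unless it
#' is defective and an independent Bernoulli(epsilon) conduction failure
#' fires, in which case it stays at rest this step.  Failure uniforms are
#' consumed in column-major block order.
#'
#' @param grid an `atrial_grid`.
#' @return the updated `atrial_grid`.
#' @export
step_ca <- function(grid) {
  stopifnot(inherits(grid, "atrial_grid"))
  grid$state <- ca_step_core(grid$state, grid$vlink, grid$defective,
                             grid$config$refractory_steps,
                             grid$config$epsilon)
  grid
}

#' Region-averaged excitation intensity
#'
#' Intensity map: excited -> 1, refractory counter c -> c/tau, rest -> 0;
#' the value is the mean over the region's blocks, in `[0, 1]`.
#'
#' @param grid an `atrial_grid`.
#' @param region a [signal_region()]; default [default_region()].
#' @return a single number in `[0, 1]`.
#' @export
extract_intensity <- function(grid, region = default_region(grid$config)) {
  stopifnot(inherits(grid, "atrial_grid"), inherits(region, "signal_region"))
  L <- grid$config$grid_size
  if (region$row_end > L || region$col_end > L)
    stop("signal region exceeds grid bounds", call. = FALSE)
  tau <- grid$config$refractory_steps
  m <- grid$state[region$row_start:region$row_end,
                  region$col_start:region$col_end, drop = FALSE]
  mean(ifelse(m == tau + 1L, 1, m / tau))
}

# internal: 0-based pulse step indices for a schedule, recycled as needed
pulse_step_indices <- function(schedule, ms_per_step, total_steps) {
  iv <- schedule$intervals_ms
  steps <- pmax(1L, as.integer(round(iv / ms_per_step)))
  pulses <- integer(0)
  t <- 0L
  k <- 1L
  n <- length(steps)
  while (t < total_steps) {
    pulses <- c(pulses, t)
    t <- t + steps[k]
    k <- if (k == n) 1L else k + 1L   # recycle the schedule
  }
  pulses
}

#' Run one pacing-driven automaton simulation
#'
#' Builds the lattice, injects a pulse at each scheduled time (the first at
#' step 0; each interval is converted to a step count by rounding to the
#' nearest step, minimum 1; the schedule is recycled if exhausted), and
#' records the region-averaged intensity at every step after the warm-up.
#' Deterministic given `config$seed`.
#'
#' @param config an [atrial_config()].
#' @param schedule a [pacing_schedule()].
#' @param region a [signal_region()]; default [default_region()].
#' @return an object of class `intensity_trace`: list with `values` (length
#'   `config$n_steps`, in `[0, 1]`), `ms_per_step`, the `config` and the
#'   schedule `kind`.
#' @export
run_simulation <- function(config, schedule,
                           region = default_region(config)) {
  stopifnot(inherits(config, "atrial_config"),
            inherits(schedule, "pacing_schedule"),
            inherits(region, "signal_region"))
  L <- config$grid_size
  if (region$row_end > L || region$col_end > L)
    stop("signal region exceeds grid bounds", call. = FALSE)
  grid <- build_grid(config)   # seeds the RNG; failure draws continue it
  total <- config$warmup_steps + config$n_steps
  pulses <- pulse_step_indices(schedule, config$ms_per_step, total)
  values <- ca_run_core(grid$vlink, grid$defective,
                        config$refractory_steps, config$epsilon,
                        pulses, total, config$warmup_steps,
                        region$row_start - 1L, region$row_end,
                        region$col_start - 1L, region$col_end)
  structure(list(values = values, ms_per_step = config$ms_per_step,
                 config = config, schedule_kind = schedule$kind),
            class = "intensity_trace")
}

#' @export
print.intensity_trace <- function(x, ...) {
  cat(sprintf(
    "intensity trace: %d steps (%.1f ms), mean = %.4f (nu = %g, pacing = %s)\n",
    length(x$values), length(x$values) * x$ms_per_step, mean(x$values),
    x$config$nu, x$schedule_kind))
  invisible(x)
}

#' @export
as.data.frame.intensity_trace <- function(x, ...) {
  data.frame(step = seq_along(x$values) - 1L,
             time_ms = (seq_along(x$values) - 1L) * x$ms_per_step,
             intensity = x$values)
}

#' Sweep the vertical-connection fraction
#'
#' For each value of nu runs `n_runs` independent simulations, each with a
#' fresh lattice draw (new connections and defects) and, when `schedule` is
#' a factory function, fresh pacing noise.  Per-run seeds are derived
#' deterministically from `config$seed`.
#'
#' @param nu_values vector of values in `[0, 1]`, used in input order.
#' @param n_runs independent runs per value (>= 1).
#' @param config template [atrial_config()]; `nu` and `seed` are overridden
#'   per run.
#' @param schedule either a fixed [pacing_schedule()] used for every run,
#'   or a function `function(seed)` returning a schedule (stochastic pacing
#'   regimes).
#' @param region a [signal_region()] or `NULL` for the default.
#' @return an object of class `nu_sweep`: a named list (one element per nu)
#'   of lists of `intensity_trace` objects.
#' @export
sweep_nu <- function(nu_values, n_runs, config, schedule, region = NULL) {
  stopifnot(inherits(config, "atrial_config"))
  if (length(nu_values) == 0L || any(!is.finite(nu_values)) ||
      any(nu_values < 0) || any(nu_values > 1))
    stop("'nu_values' must be probabilities in [0, 1]", call. = FALSE)
  check_number(n_runs, "n_runs", lower = 1, integer = TRUE)
  if (is.null(region)) region <- default_region(config)
  counter <- 0L
  out <- lapply(nu_values, function(nu) {
    lapply(seq_len(n_runs), function(j) {
      cfg <- config
      cfg$nu <- nu
      cfg$seed <- derive_seed(config$seed, 2L * counter)
      sched <- if (is.function(schedule))
        schedule(derive_seed(config$seed, 2L * counter + 1L))
      else schedule
      counter <<- counter + 1L
      run_simulation(cfg, sched, region)
    })
  })
  names(out) <- format(nu_values)
  structure(out, nu_values = nu_values, class = "nu_sweep")
}
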