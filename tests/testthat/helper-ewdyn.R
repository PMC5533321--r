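# Shared fixtures and slow-sweep caches.  The acceptance-level sweeps are
# computed once per test run and reused by every test that needs them.

.sweep_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .sweep_cache))
    assign(key, force(expr), envir = .sweep_cache)
  get(key, envir = .sweep_cache)
}

# Unperturbed desk-scale coupling sweep: N = 2000, K = 0..3.5 step 0.1,
# 10 runs per K, 40000 steps (30000 retained), r recorded every 0.5 time
# units.  Used for the variance-peak CP, the lag-1 peak and the PSD
# curvature ordering.
sigma0_k_sweep <- function() {
  cached("sigma0", {
    cfg <- kuramoto_config(n_oscillators = 2000, coupling = 0,
                           noise_sigma = 0, n_steps = 40000L,
                           transient_steps = 10000L, thin = 50, seed = 11)
    sweep_coupling(cfg, seq(0, 3.5, by = 0.1), 10)
  })
}

sigma0_k_summary <- function() {
  cached("sigma0_summary",
         summarize_sweep(sigma0_k_sweep(), cp_method = "max_variance"))
}

# Reduced-size sweeps at three noise amplitudes for the CP-shift and
# enhancement properties: N = 1000, K = 1.2..2.7 step 0.05, 5 runs per K.
noisy_k_summaries <- function() {
  cached("noisy", {
    ks <- seq(1.2, 2.7, by = 0.05)
    lapply(c(0, 0.5, 1), function(sig) {
      cfg <- kuramoto_config(n_oscillators = 1000, coupling = 0,
                             noise_sigma = sig, n_steps = 16000L,
                             transient_steps = 8000L, thin = 50,
                             seed = 101)
      summarize_sweep(sweep_coupling(cfg, ks, 5),
                      cp_method = "max_variance")
    })
  })
}

# Desk-scale atrial nu sweep at the reference conditions: 200 x 200 grid,
# nu = 0.02..0.25 step 0.01, 20 runs per nu, fixed 13.2 ms pacing.
atrial_nu_summary <- function() {
  cached("atrial", {
    cfg <- atrial_config(nu = 0.14, seed = 501)
    sw <- sweep_nu(seq(0.02, 0.25, by = 0.01), 20, cfg, fixed_schedule(4))
    summarize_sweep(sw, cp_method = "max_abs_mean_slope")
  })
}

# Reentry fixture reproducing the blocked-wave mechanism: two rows coupled
# by vertical links at columns 3 and 11, with one defective block at
# (6, 9) between them.  With the frozen seed the defective block fails on
# the forward pass (blocking the lower row), so the upper wave descends at
# the right link, travels backwards through the recovered lower row,
# re-ascends at the left link and closes a self-sustaining circuit of
# length 2*8 + 2 = 18 steps > tau + 1 = 5.  With epsilon = 0 the same
# geometry conducts everywhere and the single pulse dies out.
reentry_grid <- function(epsilon) {
  cfg <- atrial_config(grid_size = 12, nu = 0, delta = 0, epsilon = epsilon,
                       refractory_steps = 4, n_steps = 200,
                       warmup_steps = 0, seed = 50)
  g <- build_grid(cfg)
  g$vlink[, ] <- FALSE
  g$vlink[5, 3] <- TRUE     # rows 5-6 coupled at columns 3 and 11
  g$vlink[5, 11] <- TRUE
  g$defective[, ] <- FALSE
  g$defective[6, 9] <- TRUE # stochastically failing block between them
  g
}

# Total number of non-rest blocks
grid_activity <- function(grid) sum(grid$state > 0L)
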