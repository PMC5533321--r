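test_that("order parameter matches analytic phasor sums", {
  op <- order_parameter(rep(0.7, 5))
  expect_equal(op$r, 1)
  expect_equal(op$psi, 0.7)

  op3 <- order_parameter(c(0, 2 * pi / 3, 4 * pi / 3))  # three-fold symmetry
  expect_lt(op3$r, 1e-14)

  op2 <- order_parameter(c(0, pi / 2))
  expect_equal(op2$r, sqrt(2) / 2)
  expect_equal(op2$psi, pi / 4)

  expect_error(order_parameter(numeric(0)), "non-empty")
})

test_that("a single oscillator advances at its natural frequency exactly", {
  cfg <- kuramoto_config(n_oscillators = 1, coupling = 2.5, noise_sigma = 0,
                         dt = 0.01, n_steps = 10)
  st <- oscillator_ensemble(0.3, 0.7)
  for (m in 1:50) st <- kuramoto_step(st, cfg)
  # r = 1 makes the coupling term vanish: theta = theta0 + m dt omega
  expect_equal(st$phases, wrap_phase(0.3 + 50 * 0.01 * 0.7))
})

test_that("decoupled noiseless oscillators advance by dt*omega per step", {
  cfg <- kuramoto_config(n_oscillators = 4, coupling = 0, noise_sigma = 0,
                         dt = 0.02, n_steps = 10)
  om <- c(-1.2, 0.4, 0.9, 2.0)
  th0 <- c(0.1, -2, 1.5, 3)
  st <- oscillator_ensemble(th0, om)
  for (m in 1:25) st <- kuramoto_step(st, cfg)
  expect_equal(st$phases, wrap_phase(th0 + 25 * 0.02 * om))
})

test_that("three identical coupled oscillators synchronize monotonically", {
  # independent brute-force Euler oracle for the 3-oscillator system
  oracle <- function(th, K, dt, n) {
    r <- numeric(n)
    for (s in seq_len(n)) {
      z <- mean(exp(1i * th))
      th <- th + dt * K * Mod(z) * sin(Arg(z) - th)
      r[s] <- Mod(mean(exp(1i * th)))
    }
    list(th = th, r = r)
  }
  th0 <- c(0.1, 0.2, 0.3)
  res <- oracle(th0, K = 1, dt = 0.01, n = 1e4)
  expect_true(all(diff(res$r) > -1e-12))   # non-decreasing toward 1
  expect_gt(res$r[1e4], 0.9999)

  # package step agrees with the oracle trajectory
  cfg <- kuramoto_config(n_oscillators = 3, coupling = 1, noise_sigma = 0,
                         dt = 0.01, n_steps = 10)
  st <- oscillator_ensemble(th0, rep(0, 3))
  for (s in 1:200) st <- kuramoto_step(st, cfg)
  expect_equal(st$phases, wrap_phase(oracle(th0, 1, 0.01, 200)$th),
               tolerance = 1e-10)
})

test_that("non-finite phases raise an instability error", {
  cfg <- kuramoto_config(n_oscillators = 2, coupling = 0, noise_sigma = 0,
                         dt = 10, n_steps = 10)  # dt*omega overflows
  st <- oscillator_ensemble(c(0, 1), c(1e308, 0))
  expect_error(kuramoto_step(st, cfg), "non-finite phase")
})

test_that("simulate is reproducible, bounded and honours the transient", {
  cfg <- kuramoto_config(n_oscillators = 100, coupling = 1, noise_sigma = 0.5,
                         n_steps = 500, transient_steps = 100, thin = 5,
                         seed = 9)
  tr1 <- simulate_kuramoto(cfg)
  tr2 <- simulate_kuramoto(cfg)
  expect_identical(tr1$r_values, tr2$r_values)   # bit-identical rerun
  expect_true(all(tr1$r_values >= 0 & tr1$r_values <= 1))
  expect_length(tr1$r_values, (500 - 100) / 5)
  expect_true(all(diff(tr1$times) > 0))

  # boundary case: keep exactly one sample
  cfg1 <- kuramoto_config(n_oscillators = 10, coupling = 1, noise_sigma = 0,
                          n_steps = 50, transient_steps = 49, thin = 1,
                          seed = 1)
  expect_length(simulate_kuramoto(cfg1)$r_values, 1)
})

test_that("finite-size incoherence at K = 0 scales as N^(-1/2)", {
  cfg <- kuramoto_config(n_oscillators = 2000, coupling = 0, noise_sigma = 0,
                         seed = 4)
  expect_lt(mean(simulate_kuramoto(cfg)$r_values), 0.05)
})

test_that("coupling sweeps are deterministic and reduce to simulate", {
  cfg <- kuramoto_config(n_oscillators = 50, coupling = 0, noise_sigma = 0.3,
                         n_steps = 400, transient_steps = 200, thin = 4,
                         seed = 21)
  sw <- sweep_coupling(cfg, 0, n_runs = 1)
  expect_length(sw, 1)
  direct <- local({
    c2 <- cfg
    c2$seed <- derive_seed(21, 0)
    simulate_kuramoto(c2)
  })
  expect_identical(sw[[1]][[1]]$r_values, direct$r_values)

  sw2 <- sweep_coupling(cfg, c(0, 1), n_runs = 2)
  sw3 <- sweep_coupling(cfg, c(0, 1), n_runs = 2)
  expect_identical(lapply(sw2, lapply, `[[`, "r_values"),
                   lapply(sw3, lapply, `[[`, "r_values"))
})

test_that("mean synchronization increases with coupling", {
  cfg <- kuramoto_config(n_oscillators = 500, coupling = 0, noise_sigma = 0,
                         n_steps = 10000, transient_steps = 5000, thin = 50,
                         seed = 33)
  ks <- seq(0, 3.5, by = 0.25)
  sw <- sweep_coupling(cfg, ks, 1)
  rbar <- vapply(sw, function(l) mean(l[[1]]$r_values), numeric(1))
  expect_gt(cor(ks, rbar, method = "spearman"), 0.95)
})
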