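test_that("lattice construction obeys nu, delta and the seed", {
  cfg1 <- atrial_config(grid_size = 30, nu = 1, seed = 5)
  expect_true(all(build_grid(cfg1)$vlink))
  cfg0 <- atrial_config(grid_size = 30, nu = 0, seed = 5)
  expect_false(any(build_grid(cfg0)$vlink))

  cfg <- atrial_config(grid_size = 200, nu = 0.5, delta = 0.05, seed = 8)
  g <- build_grid(cfg)
  # binomial concentration: 20000 +/- 3*sqrt(40000*0.25)
  expect_lt(abs(sum(g$vlink) - 20000), 300)
  expect_identical(sum(g$defective), as.integer(round(0.05 * 200^2)))
  expect_true(all(g$state == 0L))

  g2 <- build_grid(cfg)
  expect_identical(g$vlink, g2$vlink)
  expect_identical(g$defective, g2$defective)
})

test_that("pacemaker pulses excite only resting first-column blocks", {
  cfg <- atrial_config(grid_size = 6, nu = 0.5, delta = 0,
                       refractory_steps = 3, seed = 1)
  g <- build_grid(cfg)
  exc <- 4L  # tau + 1

  g1 <- inject_pulse(g)
  expect_true(all(g1$state[, 1] == exc))
  expect_true(all(g1$state[, -1] == 0L))

  gr <- g
  gr$state[, 1] <- 2L           # refractory: rule 2 has precedence
  expect_identical(inject_pulse(gr)$state, gr$state)

  expect_identical(inject_pulse(g1)$state, g1$state)  # idempotent
})

test_that("one step propagates excitation and starts refractoriness", {
  # a lone excited block surrounded by connected resting blocks
  cfg <- atrial_config(grid_size = 5, nu = 1, delta = 0,
                       refractory_steps = 3, seed = 1)
  g <- build_grid(cfg)
  g$state[3, 3] <- 4L
  g1 <- step_ca(g)
  expect_identical(g1$state[3, 3], 3L)              # source now refractory
  expect_identical(g1$state[c(2, 4), 3], c(4L, 4L)) # vertical neighbours
  expect_identical(g1$state[3, c(2, 4)], c(4L, 4L)) # horizontal neighbours
  expect_identical(sum(g1$state > 0), 5L)
})

test_that("certain conduction failure keeps a defective block at rest", {
  cfg <- atrial_config(grid_size = 4, nu = 0, delta = 0, epsilon = 1,
                       refractory_steps = 2, seed = 2)
  g <- build_grid(cfg)
  g$defective[2, 2] <- TRUE
  g$state[2, 1] <- 3L
  for (s in 1:5) {
    g <- step_ca(g)
    expect_identical(g$state[2, 2], 0L)
  }
})

test_that("refractory blocks count down and cannot be re-excited", {
  cfg <- atrial_config(grid_size = 3, nu = 0, delta = 0,
                       refractory_steps = 4, seed = 2)
  g <- build_grid(cfg)
  g$state[2, 2] <- 3L   # mid-refractory
  g$state[2, 1] <- 5L   # excited neighbour
  seen <- integer(0)
  for (s in 1:3) {
    g <- step_ca(g)
    seen <- c(seen, g$state[2, 2])
  }
  expect_identical(seen, c(2L, 1L, 0L))  # counts down despite the neighbour
  g$state[2, 1] <- 5L   # fresh excitation next door, block now at rest
  expect_identical(step_ca(g)$state[2, 2], 5L)
})

test_that("horizontal edges do not wrap while vertical edges do", {
  cfg <- atrial_config(grid_size = 4, nu = 1, delta = 0,
                       refractory_steps = 2, seed = 3)
  g <- build_grid(cfg)
  g$state[2, 4] <- 3L            # last column
  g1 <- step_ca(g)
  expect_identical(g1$state[2, 1], 0L)   # no horizontal wraparound

  g <- build_grid(cfg)
  g$state[4, 2] <- 3L            # last row; vlink(4, 2) connects to row 1
  g1 <- step_ca(g)
  expect_identical(g1$state[1, 2], 3L)   # cyclic vertical topology
})

test_that("state sequences follow rest -> excited -> refractory chain", {
  cfg <- atrial_config(grid_size = 10, nu = 0.5, delta = 0.3, epsilon = 0.5,
                       refractory_steps = 4, seed = 17)
  g <- inject_pulse(build_grid(cfg))
  exc <- 5L
  for (s in 1:60) {
    if (s %% 25 == 0) g <- inject_pulse(g)
    prev <- g$state
    g <- step_ca(g)
    now <- g$state
    legal <- (prev == 0L & (now == 0L | now == exc)) |
      (prev == exc & now == exc - 1L) |
      (prev > 0L & prev < exc & now == prev - 1L)
    expect_true(all(legal))
    prev <- now
  }
})

test_that("region intensity is the mean of the linear grey-scale map", {
  cfg <- atrial_config(grid_size = 4, nu = 0, delta = 0,
                       refractory_steps = 4, seed = 1)
  g <- build_grid(cfg)
  expect_identical(extract_intensity(g), 0)
  g$state[, ] <- 5L
  expect_identical(extract_intensity(g), 1)
  g$state[, ] <- 0L
  g$state[1, 1] <- 5L
  expect_equal(extract_intensity(g, signal_region(1, 1, 1, 2)), 0.5)
  g$state[1, 2] <- 2L   # refractory counter 2 of tau = 4
  expect_equal(extract_intensity(g, signal_region(1, 1, 1, 2)),
               (1 + 0.5) / 2)
  expect_error(extract_intensity(g, signal_region(1, 9, 1, 2)), "bounds")
})

test_that("a single pulse on homogeneous tissue is a plane wave", {
  L <- 20
  tau <- 5
  cfg <- atrial_config(grid_size = L, nu = 1, delta = 0, epsilon = 0,
                       refractory_steps = tau, ms_per_step = 0.06,
                       n_steps = 40, warmup_steps = 0, seed = 6)
  # 13.2 ms = 220 steps > n_steps: exactly one pulse at step 0
  tr <- run_simulation(cfg, fixed_schedule(2), signal_region(1, L, 1, L))
  expect_true(all(tr$values >= 0 & tr$values <= 1))
  # wavefront moves one column per step: column 5 lights up at step 4
  tr5 <- run_simulation(cfg, fixed_schedule(2), signal_region(1, L, 5, 5))
  expect_true(all(tr5$values[1:4] == 0))
  expect_equal(tr5$values[5], 1)   # first excited at step 4 (0-based)
  # activity is gone by step (L-1) + tau + 1
  expect_true(all(tr$values[((L - 1) + tau + 2):40] == 0))
})

test_that("the fast run kernel matches stepwise composition exactly", {
  L <- 15
  cfg <- atrial_config(grid_size = L, nu = 0.4, delta = 0.2, epsilon = 0.3,
                       refractory_steps = 4, ms_per_step = 1,
                       n_steps = 60, warmup_steps = 0, seed = 29)
  region <- signal_region(1, L, 4, 12)
  sched <- fixed_schedule(3, base_ms = 10)   # a pulse every 10 steps
  tr <- run_simulation(cfg, sched, region)

  g <- build_grid(cfg)   # same seed: same lattice, same failure stream
  ref <- numeric(60)
  for (t in 0:59) {
    if (t %% 10 == 0) g <- inject_pulse(g)
    ref[t + 1] <- extract_intensity(g, region)
    g <- step_ca(g)
  }
  expect_equal(tr$values, ref, tolerance = 1e-9)
})

test_that("without conduction failure activity always dies out", {
  for (nu in c(0.1, 0.6)) {
    cfg <- atrial_config(grid_size = 30, nu = nu, delta = 0.05, epsilon = 0,
                         refractory_steps = 5, ms_per_step = 1,
                         n_steps = 150, warmup_steps = 0, seed = 31)
    tr <- run_simulation(cfg, fixed_schedule(2, base_ms = 50),
                         signal_region(1, 30, 1, 30))
    # wave + refractory tail of the first pulse are over well before the
    # next pulse at step 50
    expect_true(all(tr$values[41:50] == 0))
  }
})

test_that("a blocked wave with two vertical links forms sustained reentry", {
  g <- inject_pulse(reentry_grid(epsilon = 0.05))
  active <- logical(200)
  for (t in 1:200) {
    g <- step_ca(g)
    active[t] <- grid_activity(g) > 0
  }
  expect_true(all(active))   # the circuit re-excites itself indefinitely

  # same geometry, no conduction failure: the single pulse dies out
  g0 <- inject_pulse(reentry_grid(epsilon = 0))
  for (t in 1:40) g0 <- step_ca(g0)
  expect_identical(grid_activity(g0), 0L)
})

test_that("nu sweeps are deterministic and reduce to single runs", {
  cfg <- atrial_config(grid_size = 25, nu = 0.1, delta = 0.1, epsilon = 0.2,
                       refractory_steps = 4, ms_per_step = 1,
                       n_steps = 80, warmup_steps = 0, seed = 77)
  sched <- fixed_schedule(2, base_ms = 20)
  sw <- sweep_nu(0.3, 1, cfg, sched)
  direct <- local({
    c2 <- cfg
    c2$nu <- 0.3
    c2$seed <- derive_seed(77, 0)
    run_simulation(c2, sched)
  })
  expect_identical(sw[[1]][[1]]$values, direct$values)

  sw2 <- sweep_nu(c(0.1, 0.3), 2, cfg, sched)
  sw3 <- sweep_nu(c(0.1, 0.3), 2, cfg, sched)
  expect_identical(lapply(sw2, lapply, `[[`, "values"),
                   lapply(sw3, lapply, `[[`, "values"))
})

test_that("sparse vertical connectivity sustains more activity than dense", {
  cfg <- atrial_config(nu = 0.1, n_steps = 6000, warmup_steps = 1000,
                       seed = 91)
  sw <- sweep_nu(c(0.04, 0.22), 4, cfg, fixed_schedule(2))
  m <- vapply(sw, function(l) mean(vapply(l, function(tr) mean(tr$values),
                                          numeric(1))), numeric(1))
  expect_gt(m[[1]], m[[2]])
})
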