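test_that("chimera-like ring initial condition has the stated structure", {
  ph <- init_ring_phases(4, seed = 1)
  expect_length(ph, 4)
  expect_equal(ph[1], ph[2])  # floor(4/2) = 2 share one phase
  expect_equal(length(unique(round(ph, 12))), 3)

  # order parameter restricted to the common-phase half is exactly 1
  ph <- init_ring_phases(100, seed = 3)
  z <- exp(1i * ph[1:50])
  expect_equal(Mod(mean(z)), 1)

  # the incoherent half is uniform on [common - spread, common + spread]:
  # Kolmogorov-Smirnov test against that uniform CDF for two seeds
  for (s in c(11, 12)) {
    ph <- init_ring_phases(500, seed = s, spread = 1.5)
    common <- ph[1]
    ks <- suppressWarnings(
      stats::ks.test(ph[251:500], "punif", common - 1.5, common + 1.5))
    expect_gt(ks$p.value, 0.01)
  }
  # and distinct across seeds
  expect_false(isTRUE(all.equal(init_ring_phases(10, seed = 1),
                                init_ring_phases(10, seed = 2))))

  expect_error(init_ring_phases(1), class = "phasechimera_config_error")
})

test_that("one Euler step of the ring matches a literal double-loop evaluation", {
  set.seed(7)
  for (N in c(4, 6, 10)) {
    phi <- runif(N, 0, 2 * pi)
    cfg <- ring_config(N = N, A = 0.95, beta = 0.2, rho = 1.8)
    tr <- simulate_ring(cfg, duration = cfg$dt, burn_in = 0,
                        record_stride = 1, init = phi)
    expect_lt(max(abs(tr$phases[2, ] -
                        ring_euler_oracle(phi, 0.95, 0.2, 1.8, cfg$dt))),
              1e-12)
  }
})

test_that("vectorized ring coupling equals the double loop along a short trajectory", {
  set.seed(8)
  N <- 8
  phi <- runif(N, 0, 2 * pi)
  cfg <- ring_config(N = N, rho = 1.2, dt = 1e-3)
  tr <- simulate_ring(cfg, duration = 0.05, burn_in = 0, record_stride = 1,
                      init = phi)
  ph <- phi
  for (k in 1:50) {
    ph <- ring_euler_oracle(ph, cfg$A, cfg$beta, cfg$rho, cfg$dt)
    expect_lt(max(abs(tr$phases[k + 1, ] - ph)), 1e-10)
  }
})

test_that("uniform phases drift at exactly rho - cos(beta)", {
  cfg <- ring_config(N = 50, A = 0.5, beta = 0.3, rho = 2, dt = 1e-3)
  tr <- simulate_ring(cfg, duration = 1, burn_in = 0, record_stride = 10,
                      init = rep(1.3, 50))
  drift <- (tr$phases[nrow(tr$phases), ] - tr$phases[1, ]) / max(tr$times)
  expect_lt(max(abs(drift - (2 - cos(0.3)))), 10 * cfg$dt)
})

test_that("ring trajectories are rotation-symmetric and seed-deterministic", {
  cfg <- ring_config(N = 30, rho = 1.5)
  set.seed(5)
  phi <- runif(30, 0, 2 * pi)
  t1 <- simulate_ring(cfg, duration = 2, burn_in = 0, init = phi,
                      record_stride = 100)
  t2 <- simulate_ring(cfg, duration = 2, burn_in = 0, init = phi + 0.7,
                      record_stride = 100)
  expect_lt(max(abs(t2$phases - (t1$phases + 0.7))), 1e-9)

  a <- simulate_ring(ring_config(N = 20, rho = 1, seed = 42), duration = 2,
                     burn_in = 0.5)
  b <- simulate_ring(ring_config(N = 20, rho = 1, seed = 42), duration = 2,
                     burn_in = 0.5)
  expect_identical(a$phases, b$phases)
})

test_that("noisy ring runs are reproducible and stay finite", {
  cfg <- ring_config(N = 40, rho = 1, noise_D = 1e-4, seed = 9)
  expect_equal(cfg$noise_sigma, sqrt(2e-4))
  a <- simulate_ring(cfg, duration = 2, burn_in = 0)
  b <- simulate_ring(cfg, duration = 2, burn_in = 0)
  expect_identical(a$phases, b$phases)
  expect_true(all(is.finite(a$phases)))
  # and differs from the deterministic path
  d <- simulate_ring(ring_config(N = 40, rho = 1, seed = 9), duration = 2,
                     burn_in = 0)
  expect_gt(max(abs(a$phases - d$phases)), 0)
})

test_that("invalid ring configurations are rejected", {
  expect_error(ring_config(N = 1), class = "phasechimera_config_error")
  expect_error(ring_config(A = 1.2), class = "phasechimera_config_error")
  expect_error(ring_config(dt = 0), class = "phasechimera_config_error")
  expect_error(ring_config(noise_D = -1), class = "phasechimera_config_error")
  expect_error(simulate_ring(ring_config(), duration = 1e-9),
               class = "phasechimera_config_error")
})
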