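test_that("mean phase velocity counts complete rotations exactly", {
  tr <- const_rate_trajectory(2 * pi, duration = 3, dt = 0.001)
  prof <- mean_phase_velocity(tr, window = 3)
  expect_equal(prof$M, 3L)
  expect_equal(prof$omega, 2 * pi, tolerance = 1e-9)

  # stationary phase
  tr0 <- phase_trajectory(seq(0, 3, 0.1), matrix(1, 31, 2))
  p0 <- mean_phase_velocity(tr0, window = 3)
  expect_equal(p0$M, c(0L, 0L))
  expect_equal(p0$omega, c(0, 0))

  # omega is the exact rational 2*pi*M / delta_t
  tr2 <- const_rate_trajectory(c(1.7, 2.9), duration = 10, dt = 0.01)
  p2 <- mean_phase_velocity(tr2, window = 10)
  expect_identical(p2$omega, 2 * pi * p2$M / attr(p2, "delta_t"))

  expect_error(mean_phase_velocity(tr, window = 100),
               class = "phasechimera_argument_error")
})

test_that("domain classification uses the minimum rule and flags collapse", {
  tr <- const_rate_trajectory(rep(3, 5), duration = 10)
  prof <- classify_sync_domain(mean_phase_velocity(tr, window = 10))
  expect_true(all(prof$domain == "sync"))
  expect_true(attr(prof, "collapse"))
  vr <- velocity_ratio(prof)
  expect_equal(vr$ratio, 1)
  expect_equal(vr$spread, 0)
  expect_true(vr$collapse)

  # two groups: slower group labeled sync
  tr2 <- const_rate_trajectory(c(2, 2, 3, 3.5), duration = 40)
  p2 <- classify_sync_domain(mean_phase_velocity(tr2, window = 40))
  expect_equal(p2$domain, c("sync", "sync", "unsync", "unsync"))
})

test_that("a synthetic two-frequency ensemble recovers its ratio exactly", {
  # units at fixed Omega_a < Omega_b; window chosen so counts are exact
  omega_a <- 2 * pi * 4 / 10   # 4 rotations in 10
  omega_b <- 2 * pi * 10 / 10  # 10 rotations in 10
  tr <- const_rate_trajectory(c(rep(omega_a, 3), rep(omega_b, 5)),
                              duration = 10, dt = 0.01)
  prof <- classify_sync_domain(mean_phase_velocity(tr, window = 10))
  vr <- velocity_ratio(prof)
  expect_equal(vr$ratio, omega_a / omega_b, tolerance = 1e-9)
  expect_equal(vr$spread, 0)
  expect_equal(vr$n_sync, 3L)
})

test_that("two-population profiles label whole populations and have zero spread", {
  cfg <- twopop_config(rho = 5, seed = 2)
  tr <- simulate_twopop(cfg, duration = 1000, burn_in = 200,
                        record_stride = 2000)
  prof <- classify_sync_domain(mean_phase_velocity(tr, window = 1000))
  expect_true(all(prof$domain[prof$population == "gamma"] ==
                    prof$domain[prof$population == "gamma"][1]))
  vr <- velocity_ratio(prof)
  expect_equal(vr$spread, 0)
  expect_lte(vr$ratio, 1)
  # the synchronized population is the slower one
  sync_pop <- unique(prof$population[prof$domain == "sync"])
  mean_om <- tapply(prof$omega, prof$population, mean)
  expect_equal(sync_pop, names(mean_om)[which.min(mean_om)])
})

test_that("the uncoupled velocity is rho and a simulated uncoupled oscillator matches", {
  expect_equal(uncoupled_velocity(2.8), 2.8)
  # A = 0 removes the kernel modulation but not the coupling; an uncoupled
  # oscillator is a 1-unit synthetic trajectory with slope rho
  rho <- 2.8
  tr <- const_rate_trajectory(rho, duration = 100, dt = 0.01)
  prof <- mean_phase_velocity(tr, window = 100)
  expect_equal(prof$omega, rho, tolerance = 2 * pi / 100)
})

test_that("a single-point frequency sweep equals the direct pipeline", {
  cfg <- ring_config(N = 40, rho = 1.5)
  sw <- frequency_sweep(cfg, rho = 1.5, seeds = 7L, window = 30, burn_in = 10)
  cfg2 <- ring_config(N = 40, rho = 1.5, seed = 7)
  tr <- sweep_run_direct <- simulate_ring(cfg2, duration = 30, burn_in = 10,
                                          record_stride = 1500)
  vr <- velocity_ratio(classify_sync_domain(mean_phase_velocity(tr, window = 30)))
  expect_equal(sw$ratio, vr$ratio, tolerance = 1e-12)
  expect_equal(sw$omega_min, min(mean_phase_velocity(tr, window = 30)$omega))
  expect_error(frequency_sweep(cfg, rho = numeric(0)),
               class = "phasechimera_argument_error")
})

test_that("calibration finds the rho that gives the target theta count", {
  cal <- calibrate_rho(twopop_config(seed = 1), target_cycles = 8,
                       window = 1000, burn_in = 200)
  expect_equal(unname(cal$cycles["sync"]), 8, tolerance = 0.02)
  expect_equal(cal$config$rho, cal$rho)
  expect_gt(cal$cycles["unsync"], cal$cycles["sync"])
})
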