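test_that("the supervisor has paired unit-norm channels and decodes back", {
  cfg <- twopop_config(rho = 5, seed = 1)
  tr <- simulate_twopop(cfg, duration = 200, burn_in = 100, record_stride = 10)
  sup <- build_supervisor(tr, dt = 0.04)
  expect_equal(nrow(sup$x), 12)  # m = 4n with n = 3
  n <- sup$n
  # channel layout (cos phi, sin phi, cos gamma, sin gamma): each (cos, sin)
  # pair satisfies cos^2 + sin^2 = 1 at every sample
  for (i in seq_len(n)) {
    expect_lt(max(abs(sup$x[i, ]^2 + sup$x[n + i, ]^2 - 1)), 1e-12)
    expect_lt(max(abs(sup$x[2 * n + i, ]^2 + sup$x[3 * n + i, ]^2 - 1)), 1e-12)
  }
  # round trip: decoded phases equal the trajectory's wrapped phases
  # (compare as circular distances)
  dec <- decode_phases(sup)
  ref <- vapply(seq_len(6), function(j)
    approx(tr$times, tr$phases[, j], xout = dec$times + min(tr$times))$y,
    numeric(length(dec$times)))
  dphi <- abs(wrap_phase(dec$phases) - wrap_phase(ref))
  dphi <- pmin(dphi, 2 * pi - dphi)
  expect_lt(max(dphi), 1e-6)

  expect_error(build_supervisor(tr, duration = 1e5),
               class = "phasechimera_argument_error")
})

test_that("network initialization has the stated sparsity, signs, and zero decoder", {
  net <- force_network(N = 1000, p = 0.1, m = 12, dale = TRUE, seed = 3)
  frac <- length(net$omega0@x) / (1000 * 1000)
  expect_equal(frac, 0.1, tolerance = 0.01)
  # Dale: excitatory columns non-negative, inhibitory non-positive
  W <- as.matrix(net$omega0)
  expect_true(all(W[, 1:500] >= 0))
  expect_true(all(W[, 501:1000] <= 0))
  expect_true(all(net$d == 0))
  expect_true(all(net$eta_fb >= 0))
  expect_equal(unname(net$P[1, 1]), 1 / net$lambda)

  # zero decoder means zero output before learning
  tr <- run_spiking(net, duration = 5, dt = 0.04, seed = 1)
  expect_true(all(tr$xhat == 0))

  expect_error(force_network(N = 1), class = "phasechimera_config_error")
  expect_error(force_network(p = 1.5), class = "phasechimera_config_error")
})

test_that("single-neuron firing onset brackets the rheobase", {
  # min_v of k(v-v_r)(v-v_t) is -1000 pA at v = -40: I_bias = 1000 is the
  # saddle-node; check firing above, silence below, robust to a finer step
  quiet_state <- list(v = rep(-60, 2), u = rep(0, 2), r = rep(0, 2),
                      h = rep(0, 2))
  for (dt in c(0.04, 0.004)) {
    n_hi <- run_spiking(
      force_network(N = 2, p = 0.5, G = 0, Q = 0, m = 2, dale = FALSE,
                    params = izh_params(I_bias = 1100), seed = 1),
      duration = 400, dt = dt, state = quiet_state)
    n_lo <- run_spiking(
      force_network(N = 2, p = 0.5, G = 0, Q = 0, m = 2, dale = FALSE,
                    params = izh_params(I_bias = 900), seed = 1),
      duration = 400, dt = dt, state = quiet_state)
    expect_gt(nrow(n_hi$spikes), 3)
    expect_equal(nrow(n_lo$spikes), 0)
  }
})

test_that("synaptic filter follows the closed-form double exponential", {
  net <- force_network(N = 2, p = 1, G = 0, Q = 0, m = 2, dale = FALSE,
                       params = izh_params(I_bias = 1500), seed = 1)
  tr <- run_spiking(net, duration = 300, dt = 0.04, probe_units = 1L,
                    record_spikes = TRUE, seed = 5)
  sp1 <- tr$spikes$time[tr$spikes$unit == 1]
  expect_gt(length(sp1), 2)
  r_theory <- vapply(tr$times, function(t) {
    dtv <- t - sp1[sp1 <= t]
    sum((exp(-dtv / 20) - exp(-dtv / 2)) / (20 - 2))
  }, 0)
  expect_lt(max(abs(tr$r_probe[1, ] - r_theory)), 1e-12)
  expect_true(all(tr$r_probe >= 0))
})

test_that("spike reset contract: v to v_reset and u incremented by d_u", {
  net <- force_network(N = 2, p = 1, G = 0, Q = 0, m = 2, dale = FALSE,
                       params = izh_params(I_bias = 1500), seed = 1)
  tr <- run_spiking(net, duration = 100, dt = 0.04, probe_units = 1L,
                    record_stride = 1, record_spikes = TRUE, seed = 2)
  sp1 <- tr$spikes$time[tr$spikes$unit == 1]
  idx <- round(sp1 / 0.04)  # sample just after each spike (stride 1)
  idx <- idx[idx < ncol(tr$v_probe) - 1]
  expect_true(all(abs(tr$v_probe[1, idx + 1] - (-65)) < 20))
  # u jumps by ~200 across the spike
  jumps <- tr$u_probe[1, idx + 1] - tr$u_probe[1, idx]
  expect_true(all(jumps > 150))
})

test_that("streaming RLS equals ridge-regularized batch least squares", {
  set.seed(99)
  N <- 20; m <- 3; T_ <- 200; lambda <- 1
  R <- matrix(rnorm(T_ * N), T_, N)
  Y <- matrix(rnorm(T_ * m), T_, m)
  d <- matrix(0, N, m)
  P <- diag(N) / lambda
  for (t in seq_len(T_)) {
    r <- R[t, ]
    e <- drop(crossprod(d, r)) - Y[t, ]
    up <- rls_update(d, P, r, e)
    d <- up$d; P <- up$P
  }
  d_batch <- solve(crossprod(R) + lambda * diag(N), crossprod(R, Y))
  expect_lt(max(abs(d - d_batch)), 1e-8)

  # e = 0 leaves d unchanged; r = 0 leaves P unchanged
  up0 <- rls_update(d, P, rnorm(N), rep(0, m))
  expect_equal(up0$d, d)
  upr <- rls_update(d, P, rep(0, N), rnorm(m))
  expect_equal(upr$P, P)
})

test_that("a short FORCE run reduces the learning error and respects Dale signs", {
  cfg <- twopop_config(rho = 5.02, seed = 1)
  traj <- simulate_twopop(cfg, duration = 9500, burn_in = 500,
                          record_stride = 40)
  sup <- build_supervisor(traj)
  net <- force_network(N = 400, G = 6000, Q = 1400, dale = TRUE, seed = 10)
  fit <- train_force(net, sup, pre = 400, learn = 8000, post = 1000,
                     seed = 11)
  expect_lt(fit$learn_mse_end, fit$learn_mse_start)
  expect_true(fit$dale_ok)
  # every neuron's outgoing effective weights share one sign, at the end of
  # training (the projection enforces this at every update)
  W <- effective_weights(fit$network)
  n_exc <- 200
  expect_true(all(W[, seq_len(n_exc)] >= 0))
  expect_true(all(W[, n_exc + seq_len(200)] <= 0))
  # frozen decoder: post-learning trace leaves d untouched
  expect_identical(fit$traces$post$network$d, fit$traces$learn$network$d)
})

test_that("decode_phases recovers a two-group velocity structure from a clean supervisor", {
  cfg <- twopop_config(rho = 5, seed = 2)
  tr <- simulate_twopop(cfg, duration = 2000, burn_in = 200, record_stride = 10)
  sup <- build_supervisor(tr, dt = 0.1)
  dec <- decode_phases(sup)
  prof <- classify_sync_domain(mean_phase_velocity(dec, window = 2000))
  vr <- velocity_ratio(prof)
  expect_false(vr$collapse)
  expect_lt(vr$ratio, 1)
  # degenerate channels trigger a warning
  bad <- matrix(0.01 * rnorm(8 * 50), 8, 50)
  expect_warning(decode_phases(bad), "degenerate")
})
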