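test_that("spike phases are linearly interpolated from the reference", {
  ref <- tibble::tibble(time = c(0, 1, 2), phase = c(0.2, 0.4, 0.8))
  raster <- structure(tibble::tibble(unit = c(1L, 1L), time = c(1, 0.5)),
                      class = c("spike_raster", "tbl_df", "tbl", "data.frame"))
  sp <- assign_spike_phases(raster, ref)
  expect_equal(sp$phase[1], 0.4)   # at a node
  expect_equal(sp$phase[2], 0.3)   # linear midpoint
  expect_equal(sp$cycle, c(0L, 0L))

  bad <- structure(tibble::tibble(unit = 2L, time = 5),
                   class = class(raster))
  expect_error(assign_spike_phases(bad, ref),
               class = "phasechimera_argument_error")
})

test_that("cycle indices come from the unwrapped reference", {
  ref <- tibble::tibble(time = seq(0, 10, 0.01), phase = 2 * pi * seq(0, 10, 0.01))
  raster <- const_rate_raster(1.25, duration = 10)  # spikes every 0.8
  sp <- assign_spike_phases(raster, ref)
  expect_equal(sp$cycle, as.integer(floor(sp$time)))
  expect_true(all(sp$phase >= 0 & sp$phase < 2 * pi))
})

test_that("the circular-linear slope is exact on noiseless linear data", {
  for (delta in c(0.05, 0.3, 0.785)) {
    cycles <- 0:19
    phases <- wrap_phase(1.0 - delta * cycles)
    sp <- tibble::tibble(unit = 1L, time = cycles, cycle = cycles,
                         phase = phases)
    rep <- precession_report(sp)
    expect_equal(rep$slope, -delta, tolerance = 1e-6)
    expect_equal(rep$rlen_fit, 1, tolerance = 1e-9)
    # slopes shallower than the threshold are not called precessing
    expect_equal(rep$classification,
                 if (delta >= 0.1) "precessing" else "locked")
  }

  # constant phases: slope 0, classified locked
  sp0 <- tibble::tibble(unit = 1L, time = 0:10, cycle = 0:10,
                        phase = rep(2.5, 11))
  r0 <- precession_report(sp0)
  expect_equal(r0$slope, 0)
  expect_equal(r0$classification, "locked")

  # classification invariant under a constant circular shift
  sp1 <- tibble::tibble(unit = 1L, time = 0:19, cycle = 0:19,
                        phase = wrap_phase(0.3 - 0.3 * (0:19)))
  sp2 <- dplyr::mutate(sp1, phase = wrap_phase(phase + 1.9))
  expect_equal(precession_report(sp1)$slope, precession_report(sp2)$slope,
               tolerance = 1e-6)
})

test_that("insufficient spikes yield a result, not an error", {
  sp <- tibble::tibble(unit = 1L, time = c(0, 1), cycle = c(0L, 1L),
                       phase = c(1, 2))
  rep <- precession_report(sp)
  expect_equal(rep$classification, "insufficient-data")
  expect_true(is.na(rep$slope))
})

test_that("two constant-rate trains give the theoretical precession slope", {
  # reference at f_s, unit at f_u > f_s: slope ~ -2*pi*(f_u/f_s - 1)
  f_s <- 8 / 1000; f_u <- 9 / 1000
  dur <- 5000
  ref <- tibble::tibble(time = seq(0, dur, 1),
                        phase = 2 * pi * f_s * seq(0, dur, 1))
  raster <- const_rate_raster(f_u, duration = dur)
  sp <- assign_spike_phases(raster, ref)
  rep <- precession_report(sp)
  expected <- -2 * pi * (f_u / f_s - 1)

  # brute-force phase bookkeeping oracle: phases decrease by
  # 2*pi*(1 - f_s/f_u) per spike; per unit cycle that is `expected`
  spike_times <- raster$time
  phases_direct <- wrap_phase(2 * pi * f_s * spike_times)
  fit_direct <- stats::lm(unwrap_phase(phases_direct) - 2 * pi *
                            floor(f_s * spike_times) ~ 0)  # sanity anchor
  expect_equal(rep$slope, expected, tolerance = 0.02)
  expect_equal(rep$classification, "precessing")
})

test_that("theta sequence score is 1 for identical orders and ~0 for shuffled ones", {
  n_units <- 20; n_cycles <- 50
  base <- tibble::tibble(
    unit = rep(1:n_units, n_cycles),
    cycle = rep(0:(n_cycles - 1), each = n_units))
  ident <- dplyr::mutate(base, time = cycle + unit / (n_units + 1),
                         phase = 2 * pi * unit / (n_units + 1))
  expect_equal(theta_sequence_score(ident)$score, 1)

  set.seed(1)
  shuffled <- dplyr::group_by(ident, cycle)
  shuffled <- dplyr::mutate(shuffled, time = cycle + sample(unit) / (n_units + 1))
  shuffled <- dplyr::ungroup(shuffled)
  sc <- theta_sequence_score(shuffled)
  expect_lt(abs(sc$score), 0.1)
  expect_equal(sc$n_pairs, n_cycles - 1L)

  # insufficient data
  tiny <- tibble::tibble(unit = 1L, cycle = 0L, time = 0.1, phase = 0.3)
  expect_true(is.na(theta_sequence_score(tiny)$score))
})

test_that("ring chimera theta sequences beat their within-cycle shuffle null", {
  # the chimera needs the full-size ring; sequences are carried by the
  # slower (partially coherent) side of the unsynchronized arc
  cfg <- ring_config(N = 500, rho = 1.8, seed = 5)
  tr <- simulate_ring(cfg, duration = 120, burn_in = 60, record_stride = 20)
  prof <- classify_sync_domain(mean_phase_velocity(tr, window = 120))
  sync <- prof$unit[prof$domain == "sync"]
  uns <- prof[prof$domain == "unsync", ]
  expect_gt(nrow(uns), 20)
  units <- uns$unit[order(uns$omega)][1:15]
  raster <- phases_to_spikes(tr, units = units)
  sp <- assign_spike_phases(raster, reference_phase(tr, sync[1]))
  obs <- theta_sequence_score(sp)$score

  set.seed(11)
  null <- replicate(39, {
    shuf <- dplyr::group_by(sp, cycle)
    shuf <- dplyr::mutate(shuf, time = sample(time))
    theta_sequence_score(dplyr::ungroup(shuf))$score
  })
  expect_gt(obs, stats::quantile(null, 0.95, na.rm = TRUE))
})

test_that("a synchronized oscillator's own spikes map to near-constant phase", {
  cfg <- twopop_config(rho = 5, seed = 1)
  tr <- simulate_twopop(cfg, duration = 600, burn_in = 200, record_stride = 20)
  prof <- classify_sync_domain(mean_phase_velocity(tr, window = 600))
  sync <- prof$unit[prof$domain == "sync"]
  raster <- phases_to_spikes(tr, units = sync[2])
  sp <- assign_spike_phases(raster, reference_phase(tr, sync[1]))
  rlen <- sqrt(mean(cos(sp$phase))^2 + mean(sin(sp$phase))^2)
  expect_gt(rlen, 0.99)
})
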