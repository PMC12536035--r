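#' Mean phase velocity profile
#'
#' For each oscillator, counts the number `M_i` of complete rotations around
#' the origin (crossings of multiples of `2*pi` by the unwrapped phase)
#' inside a measurement window of length `window`, and reports
#' `Omega_i = 2*pi*M_i / window` — an exact rational in the integer count.
#' This matches the per-unit spike counts of [phases_to_spikes()] over the
#' same window.
#'
#' @param trajectory A [phase_trajectory()].
#' @param window Window length `Delta t` in time units (default 1000, the
#'   conventional measurement interval for chimera velocity profiles).
#' @param start Window start time (default: first recorded sample). The
#'   nearest recorded samples to `start` and `start + window` are used.
#' @return A `velocity_profile`: tibble with columns `unit`, `population`
#'   (if the trajectory has populations), `M` and `omega`, plus attributes
#'   `delta_t` and `window`.
#' @export
#' @examples
#' tr <- phase_trajectory(seq(0, 3, 0.01), cbind(2 * pi * seq(0, 3, 0.01)))
#' mean_phase_velocity(tr, window = 3)
mean_phase_velocity <- function(trajectory, window = 1000, start = NULL) {
  stopifnot(inherits(trajectory, "phase_trajectory"))
  check_scalar(window, "window")
  tt <- trajectory$times
  start <- start %||% tt[1]
  if (start < tt[1] - 1e-9 || start + window > tt[length(tt)] + 1e-9)
    abort("measurement window extends beyond the trajectory",
          class = "phasechimera_argument_error")
  i0 <- which.min(abs(tt - start))
  i1 <- which.min(abs(tt - (start + window)))
  dt_actual <- tt[i1] - tt[i0]
  if (dt_actual <= 0)
    abort("measurement window is empty", class = "phasechimera_argument_error")
  M <- floor(trajectory$phases[i1, ] / (2 * pi)) -
    floor(trajectory$phases[i0, ] / (2 * pi))
  out <- tibble(unit = seq_len(n_units(trajectory)),
                M = as.integer(M),
                omega = 2 * pi * M / dt_actual)
  if (!is.null(trajectory$populations))
    out <- tibble(unit = out$unit, population = trajectory$populations,
                  M = out$M, omega = out$omega)
  structure(out, class = c("velocity_profile", class(out)),
            delta_t = dt_actual, window = c(tt[i0], tt[i1]),
            model = trajectory$model)
}

#' Label synchronized and unsynchronized domains
#'
#' The synchronized domain oscillates slower than the unsynchronized one, so
#' it is identified from the minimum of the velocity profile: units whose
#' `omega` lies within relative tolerance `tol` of `min(omega)` are labeled
#' `sync`, the rest `unsync`. For two-population trajectories whole
#' populations are labeled by their common (mean) velocity. If every unit
#' falls within tolerance the profile has collapsed to full synchrony; the
#' degenerate all-sync labeling is returned with the `collapse` attribute
#' set.
#'
#' @param profile A `velocity_profile` from [mean_phase_velocity()].
#' @param tol Relative tolerance around the minimum (default 0.01).
#' @return The profile with a `domain` column (`"sync"` / `"unsync"`) and
#'   attributes `omega_s` (the synchronized velocity, `min(omega)`),
#'   `collapse`, and `tol`.
#' @export
classify_sync_domain <- function(profile, tol = 0.01) {
  stopifnot(inherits(profile, "velocity_profile"))
  check_scalar(tol, "tol", positive = FALSE)
  omega_s <- min(profile$omega)
  if ("population" %in% names(profile)) {
    pop_om <- tapply(profile$omega, profile$population, mean)
    sync_pop <- names(pop_om)[which.min(pop_om)]
    collapse <- diff(range(pop_om)) <= tol * max(abs(pop_om))
    domain <- if (collapse) rep("sync", nrow(profile))
              else ifelse(profile$population == sync_pop, "sync", "unsync")
    omega_s <- min(pop_om)
  } else {
    domain <- ifelse(profile$omega <= omega_s * (1 + tol) + 1e-12,
                     "sync", "unsync")
    collapse <- all(domain == "sync")
  }
  out <- profile
  out$domain <- domain
  structure(out, class = class(profile),
            delta_t = attr(profile, "delta_t"),
            window = attr(profile, "window"),
            model = attr(profile, "model"),
            omega_s = omega_s, collapse = collapse, tol = tol)
}

#' Mean phase velocity ratio between domains
#'
#' For a ring profile, the ratio is the mean of `Omega_s / Omega_j^u` over
#' the `m` unsynchronized oscillators, with its population standard
#' deviation as the spread; `Omega_s` is the minimum of the profile. For
#' two-population profiles both domains have a single common velocity, so
#' the ratio is the scalar `Omega_s / Omega_u` with zero spread. A collapsed
#' (all-synchronized) profile returns ratio 1, spread 0 and the collapse
#' flag.
#'
#' @param profile A `velocity_profile`, classified or not (an unclassified
#'   profile is first passed through [classify_sync_domain()] with `tol`).
#' @param tol Tolerance forwarded to [classify_sync_domain()] when needed.
#' @return A one-row tibble: `ratio`, `spread`, `n_sync`, `n_unsync`,
#'   `collapse`, `omega_s`.
#' @export
velocity_ratio <- function(profile, tol = 0.01) {
  stopifnot(inherits(profile, "velocity_profile"))
  if (!"domain" %in% names(profile))
    profile <- classify_sync_domain(profile, tol = tol)
  collapse <- isTRUE(attr(profile, "collapse"))
  omega_s <- attr(profile, "omega_s")
  n_sync <- sum(profile$domain == "sync")
  n_unsync <- sum(profile$domain == "unsync")
  if (collapse || n_unsync == 0) {
    return(tibble(ratio = 1, spread = 0, n_sync = n_sync, n_unsync = 0L,
                  collapse = TRUE, omega_s = omega_s))
  }
  if ("population" %in% names(profile)) {
    omega_u <- mean(profile$omega[profile$domain == "unsync"])
    ratio <- omega_s / omega_u
    spread <- 0
  } else {
    rr <- omega_s / profile$omega[profile$domain == "unsync"]
    ratio <- mean(rr)
    spread <- sqrt(mean((rr - ratio)^2))
  }
  tibble(ratio = ratio, spread = spread, n_sync = n_sync,
         n_unsync = n_unsync, collapse = collapse, omega_s = omega_s)
}

#' Mean phase velocity of an uncoupled oscillator
#'
#' An uncoupled oscillator obeys `d phi/dt = rho`, completing
#' `rho * Delta t / (2*pi)` rotations in a window, so its mean phase
#' velocity is `rho` itself. (The alternative normalization `2*pi*rho`
#' sometimes quoted for this quantity is inconsistent with the rotation-count
#' definition and with the magnitudes of coupled profiles, which sit just
#' below `rho`; this function deliberately returns `rho`.) Coupled chimera
#' profiles satisfy `max(omega) < rho`: the net effect of the coupling is
#' inhibitory.
#'
#' @param rho Intrinsic frequency (> 0).
#' @return `rho`, in radians per time unit.
#' @export
#' @examples
#' uncoupled_velocity(2.8)
uncoupled_velocity <- function(rho) {
  check_scalar(rho, "rho")
  rho
}

#' Sweep the intrinsic frequency
#'
#' Runs the full pipeline (simulate, burn-in, velocity profile, domain
#' classification, velocity ratio) for every value of `rho` on a grid,
#' optionally replicated over seeds with independent chimera-like initial
#' conditions. Works for both topologies: pass a [ring_config()] or a
#' [twopop_config()] as the base configuration; its `rho` and `seed` are
#' overridden per run.
#'
#' @param config Base [ring_config()] or [twopop_config()].
#' @param rho Numeric vector of intrinsic frequencies.
#' @param seeds Integer vector of seeds (one run per `rho` x seed).
#' @param window Velocity measurement window (default 1000).
#' @param burn_in Discarded transient per run (default 100).
#' @param tol Sync-classification tolerance (default 0.01).
#' @return A tibble with one row per run: `rho`, `seed`, `ratio`, `spread`,
#'   `collapse`, `omega_min`, `omega_max`, `n_sync`, `n_unsync`.
#' @export
frequency_sweep <- function(config, rho, seeds = 1L, window = 1000,
                            burn_in = 100, tol = 0.01) {
  if (!length(rho))
    abort("`rho` grid must be non-empty", class = "phasechimera_argument_error")
  grid <- expand.grid(rho = rho, seed = seeds)
  rows <- purrr::pmap(grid, function(rho, seed) {
    cfg <- config
    cfg$rho <- rho
    cfg$seed <- seed
    traj <- tryCatch(
      sweep_run(cfg, window = window, burn_in = burn_in),
      error = function(e) abort(
        sprintf("simulation failed at rho = %g: %s", rho, conditionMessage(e)),
        class = "phasechimera_sweep_error"))
    prof <- classify_sync_domain(mean_phase_velocity(traj, window = window),
                                 tol = tol)
    vr <- velocity_ratio(prof)
    tibble(rho = rho, seed = seed, ratio = vr$ratio, spread = vr$spread,
           collapse = vr$collapse, omega_min = min(prof$omega),
           omega_max = max(prof$omega), n_sync = vr$n_sync,
           n_unsync = vr$n_unsync)
  })
  dplyr::bind_rows(rows)
}

# internal: simulate with a coarse recording stride (velocity metrics only
# need window endpoints, so a sweep does not keep dense samples)
sweep_run <- function(cfg, window, burn_in, record_stride = NULL) {
  record_stride <- record_stride %||%
    max(1L, as.integer(round(window / cfg$dt / 20)))
  if (inherits(cfg, "ring_config"))
    simulate_ring(cfg, duration = window, burn_in = burn_in,
                  record_stride = record_stride)
  else
    simulate_twopop(cfg, duration = window, burn_in = burn_in,
                    record_stride = record_stride)
}

#' Calibrate the intrinsic frequency to a target theta count
#'
#' Finds `rho` such that the synchronized population completes a target
#' number of cycles per measurement window (by default 8 cycles per 1000
#' time units — the 8 Hz theta reference once one time unit is read as one
#' millisecond). The continuous cycle gain of the slower (synchronized)
#' domain is a smooth, monotone function of `rho`, so a root bracket is
#' solved with [uniroot()]. The same seed (hence the same initial condition)
#' is used for every evaluation.
#'
#' @param config Base [twopop_config()] or [ring_config()]; its `rho` is
#'   replaced by the calibrated value in the returned config.
#' @param target_cycles Cycles the synchronized domain should complete per
#'   window (default 8).
#' @param window Measurement window (default 1000 time units).
#' @param burn_in Discarded transient per evaluation (default 200).
#' @param bracket Initial search interval for `rho` (extended automatically
#'   if the root lies outside).
#' @param tol Convergence tolerance on `rho`.
#' @return A list: `rho` (calibrated value), `config` (updated), and
#'   `cycles` — the continuous per-domain cycle gains at the calibrated
#'   `rho` (names `sync`, `unsync`).
#' @export
calibrate_rho <- function(config, target_cycles = 8, window = 1000,
                          burn_in = 200, bracket = c(1, 12), tol = 1e-4) {
  gains <- function(rho) {
    cfg <- config
    cfg$rho <- rho
    traj <- sweep_run(cfg, window = window, burn_in = burn_in)
    i1 <- length(traj$times)
    g <- (traj$phases[i1, ] - traj$phases[1, ]) / (2 * pi) *
      (window / (traj$times[i1] - traj$times[1]))
    if (!is.null(traj$populations)) {
      pg <- tapply(g, traj$populations, mean)
      return(c(sync = unname(min(pg)), unsync = unname(max(pg))))
    }
    c(sync = min(g), unsync = max(g))
  }
  f <- function(rho) gains(rho)[["sync"]] - target_cycles
  root <- uniroot(f, interval = bracket, extendInt = "upX", tol = tol)
  cfg <- config
  cfg$rho <- root$root
  list(rho = root$root, config = cfg, cycles = gains(root$root))
}

#' Velocity profile plot
#'
#' @param object A `velocity_profile`.
#' @param ... Unused.
#' @return A ggplot of `omega` against oscillator index, colored by domain
#'   when classified.
#' @export
autoplot.velocity_profile <- function(object, ...) {
  p <- ggplot(object, aes(x = .data$unit, y = .data$omega)) +
    labs(x = "oscillator", y = expression(Omega[i] ~ "(rad / time unit)"))
  if ("domain" %in% names(object))
    p + geom_point(aes(colour = .data$domain), size = 0.8)
  else
    p + geom_point(size = 0.8)
}
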