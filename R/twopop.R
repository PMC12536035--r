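#' Configuration for the two-population chimera
#'
#' Two populations of `n` identical Kuramoto oscillators each (phases
#' `gamma` and `phi`), strongly coupled within a population (`mu`) and weakly
#' between populations (`nu`):
#' \deqn{\tau\, d\gamma_i/dt = \rho - \mu\sum_j \cos(\gamma_i-\gamma_j-\beta)
#'   - \nu\sum_j \cos(\gamma_i-\phi_j-\beta)}
#' and symmetrically for `phi`. The couplings are derived from the asymmetry
#' `A`: `mu = (1 + A) / (2n)`, `nu = (1 - A) / (2n)` (so `nu < mu`). The
#' within-group sums include the self-term `j = i`, a constant common drift,
#' exactly as the model is written. `tau` slows the dynamics down; at
#' `tau = 1/0.012` and a suitably calibrated `rho` (see [calibrate_rho()])
#' the synchronized population completes 8 cycles per 1000 time units, which
#' rescales (1 time unit = 1 ms) to an 8 Hz theta oscillation.
#'
#' @param n Oscillators per population (>= 2).
#' @param A Coupling asymmetry, in `[0, 1]`.
#' @param beta Phase lag (radians).
#' @param rho Intrinsic frequency (radians per time unit).
#' @param tau Time-scaling constant (> 0).
#' @param dt Euler integration step (time units).
#' @param seed Integer RNG seed, or `NULL`.
#' @return A `twopop_config` object (list) with derived `mu`, `nu`.
#' @export
#' @examples
#' cfg <- twopop_config(rho = 5, seed = 1)
#' c(cfg$mu, cfg$nu)
twopop_config <- function(n = 3, A = 0.1, beta = 0.025, rho = 1,
                          tau = 1 / 0.012, dt = 1e-3, seed = NULL) {
  check_scalar(n, "n", integer = TRUE)
  if (n < 2) abort("`n` must be at least 2", class = "phasechimera_config_error")
  check_scalar(A, "A", positive = FALSE)
  if (A < 0 || A > 1) abort("`A` must lie in [0, 1]", class = "phasechimera_config_error")
  check_scalar(beta, "beta", positive = FALSE)
  check_scalar(rho, "rho", positive = FALSE)
  check_scalar(tau, "tau")
  check_scalar(dt, "dt")
  mu <- (1 + A) / (2 * n)
  nu <- (1 - A) / (2 * n)
  structure(
    list(n = as.integer(n), A = A, beta = beta, rho = rho, tau = tau,
         dt = dt, mu = mu, nu = nu, seed = seed),
    class = "twopop_config")
}

#' @export
print.twopop_config <- function(x, ...) {
  cat(sprintf("<twopop_config: n=%d, A=%g, beta=%g, rho=%g, tau=%g, mu=%.4g, nu=%.4g>\n",
              x$n, x$A, x$beta, x$rho, x$tau, x$mu, x$nu))
  invisible(x)
}

#' Chimera-like initial phases for the two-population model
#'
#' One population starts with identical phases (drawn once, uniformly from
#' `[0, 2*pi)`); the other starts incoherent. Which population is coherent
#' selects which one ends up synchronized: the identity of the synchronized
#' population depends on the initial conditions.
#'
#' Three incoherent profiles are provided, because at the default coupling
#' (`A = 0.1`, `beta = 0.025`, small `n`) the fully synchronized state is a
#' strong competing attractor:
#' * `"spread"` (default) — i.i.d. uniform within `spread` radians of the
#'   common phase. This lands in the basin of the long-lived breathing
#'   chimera (one population coherent, the other's order parameter
#'   fluctuating well below 1), which persists for at least tens of
#'   thousands of time units.
#' * `"splay"` — phases exactly evenly spaced (a rotating-wave
#'   configuration, order parameter 0). Its within-population coupling
#'   cancels, so the incoherent population drifts fastest; the configuration
#'   is dynamically unstable and collapses to full synchrony after several
#'   hundred time units, so use it only with short measurement windows.
#' * `"uniform"` — i.i.d. uniform on the full `[0, 2*pi)`. This overshoots
#'   the chimera's partially coherent incoherent population and typically
#'   collapses to full synchrony within a few thousand time units.
#'
#' @param n Oscillators per population (>= 2).
#' @param sync Which population starts coherent: `"gamma"` (default) or
#'   `"phi"`.
#' @param seed Integer RNG seed, or `NULL`.
#' @param incoherent Profile of the incoherent population: `"spread"`,
#'   `"splay"`, or `"uniform"`.
#' @param spread Half-width (radians) for the `"spread"` profile.
#' @return A list with numeric vectors `gamma` and `phi` (length `n` each).
#' @export
#' @examples
#' init_twopop_phases(3, seed = 1)
init_twopop_phases <- function(n, sync = c("gamma", "phi"), seed = NULL,
                               incoherent = c("spread", "splay", "uniform"),
                               spread = 1) {
  check_scalar(n, "n", integer = TRUE)
  if (n < 2) abort("`n` must be at least 2", class = "phasechimera_config_error")
  sync <- match.arg(sync)
  incoherent <- match.arg(incoherent)
  check_scalar(spread, "spread")
  with_seed(seed, {
    th <- runif(1, 0, 2 * pi)
    common <- rep(th, n)
    inc <- switch(incoherent,
                  spread = th + runif(n, -spread, spread),
                  splay = th + 2 * pi * (seq_len(n) - 1) / n,
                  uniform = runif(n, 0, 2 * pi))
    if (sync == "gamma") list(gamma = common, phi = inc)
    else list(gamma = inc, phi = common)
  })
}

#' Simulate the two-population chimera
#'
#' Forward-Euler integration of the two weakly coupled populations (see
#' [twopop_config()]). Oscillators 1..n are the `gamma` population,
#' n+1..2n the `phi` population. An optional perturbation applies an
#' independent uniform phase kick in `[-magnitude, +magnitude]` to every
#' oscillator at `perturb_at` (recorded time), after which integration
#' continues unchanged; a sufficiently large kick makes the synchronized and
#' unsynchronized populations swap roles.
#'
#' @param config A [twopop_config()].
#' @param duration Recorded duration (time units).
#' @param burn_in Discarded transient before recording (default 100).
#' @param record_stride Record every `record_stride`-th Euler step
#'   (default 100).
#' @param init Optional initial phases, a list as returned by
#'   [init_twopop_phases()].
#' @param perturb_at Optional recorded time at which to kick all phases.
#' @param perturb_magnitude Half-width of the uniform kick (radians,
#'   default `pi`).
#' @return A [phase_trajectory()] with `populations` labels and, when
#'   perturbed, an event log entry.
#' @export
#' @examples
#' cfg <- twopop_config(rho = 5, seed = 2)
#' traj <- simulate_twopop(cfg, duration = 50, burn_in = 50)
#' traj
simulate_twopop <- function(config, duration, burn_in = 100,
                            record_stride = 100, init = NULL,
                            perturb_at = NULL, perturb_magnitude = pi) {
  stopifnot(inherits(config, "twopop_config"))
  check_scalar(duration, "duration")
  if (duration < config$dt)
    abort("`duration` must be at least one integration step",
          class = "phasechimera_config_error")
  check_scalar(burn_in, "burn_in", positive = FALSE)
  if (!is.null(perturb_at)) {
    check_scalar(perturb_at, "perturb_at", positive = FALSE)
    check_scalar(perturb_magnitude, "perturb_magnitude", positive = FALSE)
    if (perturb_magnitude < 0)
      abort("`perturb_magnitude` must be >= 0", class = "phasechimera_argument_error")
    if (perturb_at < 0 || perturb_at >= duration)
      abort("`perturb_at` must lie within the recorded window",
            class = "phasechimera_argument_error")
  }

  with_seed(config$seed, {
    init <- init %||% init_twopop_phases(config$n)
    if (!is.list(init) || length(init$gamma) != config$n ||
        length(init$phi) != config$n)
      abort("`init` must be a list with `gamma` and `phi`, length n each",
            class = "phasechimera_config_error")
    g0 <- init$gamma
    p0 <- init$phi
    if (burn_in > 0) {
      nb <- round(burn_in / config$dt)
      fin <- sim_twopop_cpp(g0, p0, config$mu, config$nu, config$beta,
                            config$rho, config$tau, config$dt, nb, nb)$final
      g0 <- fin[seq_len(config$n)]
      p0 <- fin[config$n + seq_len(config$n)]
    }

    run_chunk <- function(g0, p0, n_steps) {
      n_steps <- record_stride * max(1L, n_steps %/% record_stride)
      sim_twopop_cpp(g0, p0, config$mu, config$nu, config$beta, config$rho,
                     config$tau, config$dt, n_steps, record_stride)
    }

    events <- list()
    if (is.null(perturb_at)) {
      res <- run_chunk(g0, p0, round(duration / config$dt))
      phases <- res$phases
    } else {
      res1 <- run_chunk(g0, p0, round(perturb_at / config$dt))
      st <- res1$final
      kick <- runif(2 * config$n, -perturb_magnitude, perturb_magnitude)
      st <- st + kick
      res2 <- run_chunk(st[seq_len(config$n)],
                        st[config$n + seq_len(config$n)],
                        round((duration - perturb_at) / config$dt))
      # drop the duplicated junction sample from the second chunk
      phases <- rbind(res1$phases, res2$phases[-1, , drop = FALSE])
      t_kick <- (nrow(res1$phases) - 1) * config$dt * record_stride
      events <- list(list(label = sprintf("perturbation at t=%g", t_kick),
                          time = t_kick, magnitude = perturb_magnitude,
                          kick = kick))
    }
    times <- seq(0, by = config$dt * record_stride, length.out = nrow(phases))
    phase_trajectory(times, phases, model = "twopop", config = config,
                     populations = rep(c("gamma", "phi"), each = config$n),
                     seed = config$seed, events = events)
  })
}

#' Perturb a finished two-population run and continue it
#'
#' Takes an already-simulated two-population trajectory, applies an
#' independent uniform phase kick in `[-magnitude, +magnitude]` to every
#' oscillator at the recorded sample nearest `t_perturb`, and re-integrates
#' from that kicked state to the trajectory's original end time. The portion
#' before the kick is kept as-is (a recorded sample is the complete state of
#' a phase-only model, so the continuation is exact).
#'
#' @param trajectory A two-population [phase_trajectory()].
#' @param t_perturb Time of the kick; must lie strictly inside the recorded
#'   window.
#' @param magnitude Half-width of the uniform kick (radians); `0` reproduces
#'   the unperturbed trajectory.
#' @param seed Integer RNG seed for the kick, or `NULL`.
#' @return A [phase_trajectory()] with the perturbation logged in `events`.
#' @export
perturb_twopop <- function(trajectory, t_perturb, magnitude = pi, seed = NULL) {
  stopifnot(inherits(trajectory, "phase_trajectory"))
  if (trajectory$model != "twopop" || is.null(trajectory$config))
    abort("`trajectory` must come from simulate_twopop()",
          class = "phasechimera_argument_error")
  tt <- trajectory$times
  if (t_perturb < min(tt) || t_perturb >= max(tt))
    abort("`t_perturb` must lie within the recorded window",
          class = "phasechimera_argument_error")
  check_scalar(magnitude, "magnitude", positive = FALSE)
  if (magnitude < 0)
    abort("`magnitude` must be >= 0", class = "phasechimera_argument_error")
  cfg <- trajectory$config
  i0 <- which.min(abs(tt - t_perturb))
  stride <- round((tt[2] - tt[1]) / cfg$dt)

  with_seed(seed, {
    st <- trajectory$phases[i0, ]
    kick <- runif(2 * cfg$n, -magnitude, magnitude)
    st <- st + kick
    n_steps <- round((max(tt) - tt[i0]) / cfg$dt)
    res <- sim_twopop_cpp(st[seq_len(cfg$n)], st[cfg$n + seq_len(cfg$n)],
                          cfg$mu, cfg$nu, cfg$beta, cfg$rho, cfg$tau,
                          cfg$dt, stride * max(1L, n_steps %/% stride), stride)
    phases <- rbind(trajectory$phases[seq_len(i0 - 1), , drop = FALSE],
                    res$phases)
    times <- tt[seq_len(i0 - 1 + nrow(res$phases))]
    ev <- c(trajectory$events,
            list(list(label = sprintf("perturbation at t=%g", tt[i0]),
                      time = tt[i0], magnitude = magnitude, kick = kick)))
    phase_trajectory(times, phases, model = "twopop", config = cfg,
                     populations = trajectory$populations,
                     seed = trajectory$seed, events = ev)
  })
}
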