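#' Izhikevich neuron parameters
#'
#' Parameters of the adaptive quadratic integrate-and-fire (Izhikevich)
#' model used in the spiking network, in the standard bookkeeping
#' (millivolts, milliseconds, picoamperes, capacitance scaled so the voltage
#' equation is dimensionally consistent as written):
#' \deqn{C\,dv/dt = k (v - v_r)(v - v_t) - u + I_{bias} + s}
#' \deqn{du/dt = a (b (v - v_r) - u)}
#' with a hard reset `v -> v_reset`, `u -> u + d_u` when `v` reaches
#' `v_peak`. The defaults are the standard theta-burst regime for this model.
#'
#' @param C Membrane capacitance.
#' @param v_r,v_t Resting and threshold potentials (mV).
#' @param v_peak,v_reset Spike peak and reset potentials (mV).
#' @param a Adaptation rate (1/ms).
#' @param b Adaptation coupling (nS).
#' @param k Action-potential half-width parameter (nS/mV).
#' @param d_u Post-spike adaptation increment.
#' @param I_bias Constant bias current (pA).
#' @param tau_r,tau_d Synaptic rise and decay times (ms), `tau_r < tau_d`.
#' @return An `izh_params` list.
#' @export
#' @examples
#' izh_params()
izh_params <- function(C = 250, v_r = -60, v_t = -20, v_peak = 30,
                       v_reset = -65, a = 0.01, b = -2, k = 2.5, d_u = 200,
                       I_bias = 1000, tau_r = 2, tau_d = 20) {
  if (!(v_reset < v_r && v_r < v_t && v_t < v_peak))
    abort("require v_reset < v_r < v_t < v_peak",
          class = "phasechimera_config_error")
  if (!(tau_r > 0 && tau_d > tau_r))
    abort("require 0 < tau_r < tau_d", class = "phasechimera_config_error")
  for (nm in c("C", "a", "k"))
    check_scalar(get(nm), nm)
  structure(list(C = C, v_r = v_r, v_t = v_t, v_peak = v_peak,
                 v_reset = v_reset, a = a, b = b, k = k, d_u = d_u,
                 I_bias = I_bias, tau_r = tau_r, tau_d = tau_d),
            class = "izh_params")
}

#' Build the chimera supervisor from a two-population trajectory
#'
#' The supervisor is the `m = 4n`-dimensional signal
#' `x = (cos phi_1..n, sin phi_1..n, cos gamma_1..n, sin gamma_1..n)` built
#' from the two-population chimera, resampled to the network integration
#' step by linear interpolation of the unwrapped phases (one trajectory time
#' unit is read as one millisecond).
#'
#' @param trajectory A two-population [phase_trajectory()].
#' @param dt Network integration step in ms (default 0.04); must be no
#'   coarser than the trajectory's sampling.
#' @param duration Optional supervisor duration in ms (default: the full
#'   trajectory).
#' @return A `chimera_supervisor`: list with `x` (an `m x T` matrix, one
#'   column per step), `times`, `dt`, and `n`.
#' @export
build_supervisor <- function(trajectory, dt = 0.04, duration = NULL) {
  stopifnot(inherits(trajectory, "phase_trajectory"))
  if (is.null(trajectory$populations))
    abort("`trajectory` must be a two-population run",
          class = "phasechimera_argument_error")
  stride <- trajectory$times[2] - trajectory$times[1]
  if (stride > dt + 1e-12)
    abort("trajectory must be sampled at least as finely as the network dt",
          class = "phasechimera_argument_error")
  total <- max(trajectory$times) - min(trajectory$times)
  duration <- duration %||% total
  if (duration > total + 1e-9)
    abort("`duration` exceeds the trajectory length",
          class = "phasechimera_argument_error")
  n <- sum(trajectory$populations == "gamma")
  grid <- seq(min(trajectory$times), min(trajectory$times) + duration, by = dt)
  ph <- vapply(seq_len(n_units(trajectory)), function(j)
    approx(trajectory$times, trajectory$phases[, j], xout = grid)$y,
    numeric(length(grid)))
  gamma <- ph[, trajectory$populations == "gamma", drop = FALSE]
  phi <- ph[, trajectory$populations == "phi", drop = FALSE]
  x <- t(cbind(cos(phi), sin(phi), cos(gamma), sin(gamma)))
  structure(list(x = x, times = grid - grid[1], dt = dt, n = n),
            class = "chimera_supervisor")
}

#' @export
print.chimera_supervisor <- function(x, ...) {
  cat(sprintf("<chimera_supervisor: m=%d channels, %d samples, dt=%g ms>\n",
              nrow(x$x), ncol(x$x), x$dt))
  invisible(x)
}

#' Initialize a FORCE-trainable spiking network
#'
#' Builds the static random connectivity and the FORCE state: a sparse
#' static weight matrix `omega0` (each entry present with probability `p`,
#' values Normal with mean 0 and variance `1/(N p^2)`), encoders `eta` drawn
#' uniformly from `[-1, 1]^m`, decoders `d = 0`, and the RLS
#' inverse-correlation matrix `P = I/lambda`. Effective recurrent weights
#' during training are `G * omega0 + Q * eta_fb %*% t(d)`.
#'
#' With `dale = TRUE` the network obeys Dale's law: the first half of the
#' neurons is excitatory, the second half inhibitory; `omega0` entries take
#' their column's (presynaptic neuron's) sign; the feedback encoder uses
#' `eta_fb = |eta|` and decoder rows are projected onto their neuron's sign
#' after every RLS update, so every neuron's outgoing effective weights
#' share one sign at every training step.
#'
#' @param N Neuron count (>= 2).
#' @param p Connection density in `(0, 1]` (default 0.1, i.e. 90% sparse).
#' @param G Static-weight gain. The literature for this network quotes both
#'   1.5e3 and 1.5e4; neither is usable at the scaled-down default `N`
#'   (the first leaves the network nearly silent, the second is unstable).
#'   `G` is a free parameter; the reference configuration uses 6000, the
#'   middle of the regime where the network is chaotic but stable.
#' @param Q Feedback gain (default 1400).
#' @param m Supervisor dimensionality (default 12).
#' @param dale Enforce Dale's law (default `TRUE`).
#' @param dale_mode How the decoder respects the sign constraint during
#'   learning: `"lazy"` (default; an unconstrained shadow decoder is updated
#'   by RLS and the network uses its sign projection — stable over long
#'   training) or `"project"` (the decoder itself is hard-projected after
#'   every update).
#' @param lambda RLS regularizer (default 1).
#' @param params An [izh_params()] set.
#' @param seed Integer RNG seed, or `NULL`.
#' @return A `force_network` object.
#' @export
force_network <- function(N = 1000, p = 0.1, G = 6000, Q = 1400, m = 12,
                          dale = TRUE, dale_mode = c("lazy", "project"),
                          lambda = 1, params = izh_params(), seed = NULL) {
  dale_mode <- match.arg(dale_mode)
  check_scalar(N, "N", integer = TRUE)
  if (N < 2) abort("`N` must be at least 2", class = "phasechimera_config_error")
  check_scalar(p, "p")
  if (p > 1) abort("`p` must lie in (0, 1]", class = "phasechimera_config_error")
  check_scalar(m, "m", integer = TRUE)
  check_scalar(lambda, "lambda")
  stopifnot(inherits(params, "izh_params"))

  with_seed(seed, {
    n_exc <- ceiling(N / 2)
    neuron_sign <- rep(c(1L, -1L), c(n_exc, N - n_exc))
    idx <- which(runif(N * N) < p)
    vals <- rnorm(length(idx), 0, 1 / (sqrt(N) * p))
    ii <- ((idx - 1) %% N) + 1
    jj <- ((idx - 1) %/% N) + 1
    if (dale) vals <- abs(vals) * neuron_sign[jj]
    omega0 <- Matrix::sparseMatrix(i = ii, j = jj, x = vals, dims = c(N, N))
    eta <- matrix(runif(N * m, -1, 1), N, m)
    structure(
      list(N = as.integer(N), p = p, G = G, Q = Q, m = as.integer(m),
           lambda = lambda, dale = dale, params = params, omega0 = omega0,
           eta = eta, eta_fb = if (dale) abs(eta) else eta,
           d = matrix(0, N, m), d_free = matrix(0, N, m),
           P = diag(N) / lambda, dale_mode = dale_mode,
           neuron_sign = neuron_sign, seed = seed, trained = FALSE),
      class = "force_network")
  })
}

#' @export
print.force_network <- function(x, ...) {
  cat(sprintf("<force_network: N=%d, p=%g, G=%g, Q=%g, m=%d, dale=%s%s>\n",
              x$N, x$p, x$G, x$Q, x$m, x$dale,
              if (x$trained) ", trained" else ""))
  invisible(x)
}

#' Effective recurrent weight matrix
#'
#' `G * omega0 + Q * eta_fb %*% t(d)` — useful for checking the Dale sign
#' structure (every column belongs to one presynaptic neuron and must be
#' sign-definite when Dale's law is enforced).
#'
#' @param network A [force_network()].
#' @return A dense `N x N` matrix.
#' @export
effective_weights <- function(network) {
  stopifnot(inherits(network, "force_network"))
  as.matrix(network$G * network$omega0) +
    network$Q * network$eta_fb %*% t(network$d)
}

#' One recursive-least-squares step
#'
#' The streaming decoder update used during FORCE learning, written exactly
#' as implemented in the training loop:
#' `P <- P - (P r)(P r)^T / (1 + r^T P r)` followed by
#' `d <- d - (P_new r) e^T`, where `e = d^T r - x` is the decoding error.
#' Iterated from `d = 0`, `P = I/lambda` over a stream of `(r, x)` pairs it
#' converges to the ridge-regularized batch least-squares solution.
#'
#' @param d Current decoder (`N x m`).
#' @param P Current inverse-correlation matrix (`N x N`).
#' @param r Rate vector (length `N`).
#' @param e Error vector `d^T r - x` (length `m`).
#' @return A list with updated `d` and `P`.
#' @export
rls_update <- function(d, P, r, e) {
  Pr <- P %*% r
  denom <- 1 + drop(crossprod(r, Pr))
  P <- P - tcrossprod(Pr) / denom
  d <- d - (Pr / denom) %*% t(e)
  list(d = d, P = P)
}

#' Run the spiking network for one phase
#'
#' Integrates the Izhikevich network with forward Euler (exact exponential
#' updates for the double-exponential synapses), optionally updating the
#' decoder online with RLS against a supervisor. Initial membrane state is
#' drawn uniformly between `v_r` and `v_peak` unless continued from a
#' previous phase via `state`.
#'
#' @param network A [force_network()].
#' @param duration Phase duration in ms.
#' @param dt Integration step in ms (default 0.04).
#' @param supervisor A `chimera_supervisor` (required when `rls = TRUE`).
#' @param supervisor_offset Time offset (ms) into the supervisor at which
#'   this phase starts.
#' @param rls Run RLS decoder updates (default `FALSE`).
#' @param rls_every Steps between RLS updates (default 20).
#' @param record_stride Steps between recorded samples of the decoded
#'   output (default 25, i.e. 1 ms at `dt = 0.04`).
#' @param probe_units Units whose `v`, `u`, `r` are recorded (default none).
#' @param record_spikes Keep the spike raster (default `TRUE`).
#' @param state Optional list `(v, u, r, h)` to continue from.
#' @param t0 Time origin for recorded times (ms).
#' @param seed Integer RNG seed for the initial state, or `NULL`.
#' @return A `net_trace`: list with `times`, `xhat` (`m x samples`),
#'   `spikes` (a `spike_raster` tibble), probe matrices, `rls_error`,
#'   final `state`, and the (possibly updated) `network`.
#' @export
run_spiking <- function(network, duration, dt = 0.04, supervisor = NULL,
                        supervisor_offset = 0, rls = FALSE, rls_every = 20,
                        record_stride = 25, probe_units = integer(0),
                        record_spikes = TRUE, state = NULL, t0 = 0,
                        seed = NULL) {
  stopifnot(inherits(network, "force_network"))
  check_scalar(duration, "duration")
  check_scalar(dt, "dt")
  n_steps <- as.integer(round(duration / dt))
  prm <- network$params

  sup_mat <- matrix(0, 0, 0)
  if (!is.null(supervisor)) {
    stopifnot(inherits(supervisor, "chimera_supervisor"))
    if (abs(supervisor$dt - dt) > 1e-12)
      abort("supervisor dt must equal the network dt",
            class = "phasechimera_argument_error")
    i0 <- as.integer(round(supervisor_offset / dt))
    if (i0 + n_steps > ncol(supervisor$x))
      abort("supervisor too short for the requested phase",
            class = "phasechimera_argument_error")
    sup_mat <- supervisor$x[, i0 + seq_len(n_steps), drop = FALSE]
  } else if (rls) {
    abort("RLS requires a supervisor", class = "phasechimera_argument_error")
  }

  with_seed(seed, {
    if (is.null(state)) {
      state <- list(
        v = prm$v_r + (prm$v_peak - prm$v_r) * runif(network$N),
        u = rep(0, network$N), r = rep(0, network$N), h = rep(0, network$N))
    }
    res <- izh_force_cpp(
      W0 = network$omega0, eta_fb = network$eta_fb, d = network$d,
      P = network$P, supervisor = sup_mat, prm = unclass(prm),
      G = network$G, Q = network$Q, dt = dt, n_steps = n_steps, rls = rls,
      rls_every = as.integer(rls_every), neuron_sign = network$neuron_sign,
      dale_mode = if (!isTRUE(network$dale)) 0L
                  else if (identical(network$dale_mode, "project")) 1L else 2L,
      fb_offset = if (isTRUE(network$dale)) 0.5 else 0,
      record_stride = as.integer(record_stride),
      probe_units = as.integer(probe_units - 1L), record_spikes = record_spikes,
      t0 = t0, v0 = state$v, u0 = state$u, r0 = state$r, h0 = state$h,
      d_free = network$d_free %||% network$d)

    if (rls) {
      network$d <- res$d
      network$P <- res$P
      network$d_free <- res$d_free
    }
    spikes <- tibble(unit = as.integer(res$spike_unit),
                     time = as.numeric(res$spike_time))
    spikes <- dplyr::arrange(spikes, .data$unit, .data$time)
    spikes <- structure(spikes, class = c("spike_raster", class(spikes)),
                        window = c(t0, t0 + duration), model = "izhikevich")
    structure(
      list(times = as.numeric(res$times), xhat = res$xhat, spikes = spikes,
           probe_units = probe_units, v_probe = res$v_probe,
           u_probe = res$u_probe, r_probe = res$r_probe,
           rls_error = as.numeric(res$rls_error),
           dale_ok = isTRUE(res$dale_ok) || !network$dale,
           state = list(v = res$v, u = res$u, r = res$r, h = res$h),
           network = network, dt = dt),
      class = "net_trace")
  })
}

#' @export
print.net_trace <- function(x, ...) {
  cat(sprintf("<net_trace: %d samples, %d spikes, t in [%g, %g] ms>\n",
              length(x$times), nrow(x$spikes),
              min(x$times), max(x$times)))
  invisible(x)
}

#' FORCE-train the spiking network on the chimera supervisor
#'
#' Runs the three FORCE phases back to back: pre-learning (static weights,
#' chaotic regime), learning (RLS decoder updates every `rls_every` steps),
#' and post-learning (decoder frozen). Training succeeds when, over the
#' post-learning phase, every supervisor channel is reproduced with
#' correlation at least `success_cor`.
#'
#' @param network A [force_network()].
#' @param supervisor A `chimera_supervisor` covering at least
#'   `pre + learn + post` ms.
#' @param pre,learn,post Phase durations in ms (defaults 1000, 30000, 5000).
#' @param rls_every Steps between RLS updates (default 20).
#' @param record_stride Steps between recorded output samples (default 25).
#' @param probe_units Units recorded in detail (default: none).
#' @param success_cor Per-channel correlation required for success
#'   (default 0.9).
#' @param success_window Window (ms) at the start of the post-learning phase
#'   over which the per-channel correlation is judged (default 1000). The
#'   incoherent population's channels are weakly chaotic, so even a
#'   perfectly trained autonomous network de-phases from the supervisor on
#'   a multi-second horizon; agreement is therefore judged over a finite
#'   window. Correlations over the whole post phase are also reported.
#' @param record_spikes_phases Which phases keep full spike rasters
#'   (default `"post"`; any of `"pre"`, `"learn"`, `"post"`).
#' @param seed Integer RNG seed for the initial membrane state.
#' @return A `force_fit`: list with the trained `network`, per-phase
#'   `traces`, `channel_cor`, per-phase RMSE, `rls_error` trace, and
#'   `success`.
#' @export
train_force <- function(network, supervisor, pre = 1000, learn = 30000,
                        post = 5000, rls_every = 20, record_stride = 25,
                        probe_units = integer(0), success_cor = 0.9,
                        success_window = 1000,
                        record_spikes_phases = "post", seed = NULL) {
  stopifnot(inherits(network, "force_network"),
            inherits(supervisor, "chimera_supervisor"))
  dt <- supervisor$dt
  if ((pre + learn + post) > ncol(supervisor$x) * dt + 1e-9)
    abort("supervisor shorter than pre + learn + post",
          class = "phasechimera_argument_error")

  with_seed(seed, {
    phases <- list(pre = pre, learn = learn, post = post)
    offsets <- cumsum(c(0, pre, learn))
    names(offsets) <- names(phases)
    traces <- list()
    state <- NULL
    net <- network
    for (ph in names(phases)) {
      tr <- run_spiking(
        net, duration = phases[[ph]], dt = dt, supervisor = supervisor,
        supervisor_offset = offsets[[ph]], rls = (ph == "learn"),
        rls_every = rls_every, record_stride = record_stride,
        probe_units = probe_units,
        record_spikes = ph %in% record_spikes_phases,
        state = state, t0 = offsets[[ph]])
      state <- tr$state
      net <- tr$network
      traces[[ph]] <- tr
    }
    net$trained <- TRUE

    sup_at <- function(tr) {
      idx <- as.integer(round(tr$times / dt)) + 1L
      supervisor$x[, idx, drop = FALSE]
    }
    rmse <- vapply(traces, function(tr)
      sqrt(mean((tr$xhat - sup_at(tr))^2)), 0)
    sup_post <- sup_at(traces$post)
    cor_over <- function(idx) vapply(seq_len(nrow(sup_post)), function(i) {
      if (sd(traces$post$xhat[i, idx]) == 0) return(0)
      cor(traces$post$xhat[i, idx], sup_post[i, idx])
    }, 0)
    in_window <- traces$post$times - min(traces$post$times) <= success_window
    channel_cor <- cor_over(which(in_window))
    channel_cor_full <- cor_over(seq_len(ncol(sup_post)))
    err <- traces$learn$rls_error
    n5 <- max(1L, length(err) %/% 20)
    structure(
      list(network = net, traces = traces, supervisor_n = supervisor$n,
           supervisor_post = sup_post,
           dt = dt, rmse = rmse, channel_cor = channel_cor,
           channel_cor_full = channel_cor_full,
           success_window = success_window,
           rls_error = err,
           learn_mse_start = mean(err[seq_len(n5)]^2),
           learn_mse_end = mean(err[length(err) - seq_len(n5) + 1]^2),
           dale_ok = all(vapply(traces, function(tr) tr$dale_ok, TRUE)),
           success = all(channel_cor >= success_cor),
           success_cor = success_cor),
      class = "force_fit")
  })
}

#' @export
print.force_fit <- function(x, ...) {
  cat(sprintf(
    "<force_fit: N=%d, G=%g, Q=%g | post-learning channel correlation %.3f-%.3f | %s>\n",
    x$network$N, x$network$G, x$network$Q, min(x$channel_cor),
    max(x$channel_cor), if (x$success) "success" else "NOT successful"))
  invisible(x)
}

#' @describeIn train_force Per-channel post-learning agreement.
#' @param x A `force_fit`.
#' @param ... Unused.
#' @export
tidy.force_fit <- function(x, ...) {
  n <- x$supervisor_n
  tibble(channel = seq_along(x$channel_cor),
         label = c(paste0("cos_phi_", 1:n), paste0("sin_phi_", 1:n),
                   paste0("cos_gamma_", 1:n), paste0("sin_gamma_", 1:n)),
         correlation = x$channel_cor,
         correlation_full_post = x$channel_cor_full)
}

#' @describeIn train_force One-row training summary.
#' @export
glance.force_fit <- function(x, ...) {
  tibble(N = x$network$N, G = x$network$G, Q = x$network$Q,
         dale = x$network$dale, min_channel_cor = min(x$channel_cor),
         rmse_post = unname(x$rmse["post"]),
         learn_mse_start = x$learn_mse_start,
         learn_mse_end = x$learn_mse_end,
         dale_ok = x$dale_ok, success = x$success)
}

#' Decode oscillator phases from paired cosine/sine channels
#'
#' Recovers wrapped phases from the decoded network output (or any matrix in
#' supervisor channel layout) as the two-argument arctangent of each
#' (sine, cosine) channel pair, then unwraps them so that velocity metrics
#' and spike generation apply. Channel layout is the supervisor's:
#' `(cos phi_1..n, sin phi_1..n, cos gamma_1..n, sin gamma_1..n)`. The
#' returned trajectory uses the two-population layout (gamma units first).
#'
#' @param x A `net_trace`, a `chimera_supervisor`, or an `m x T` matrix with
#'   `m = 4n` rows.
#' @param times Sample times; taken from the object when available.
#' @return A [phase_trajectory()] (`model = "decoded"`) with population
#'   labels. Warns when a channel pair's amplitude is degenerate
#'   (`sqrt(cos^2 + sin^2) < 0.2`) for more than 5% of samples.
#' @export
decode_phases <- function(x, times = NULL) {
  if (inherits(x, "net_trace")) {
    times <- times %||% x$times
    x <- x$xhat
  } else if (inherits(x, "chimera_supervisor")) {
    times <- times %||% x$times
    x <- x$x
  }
  stopifnot(is.matrix(x))
  m <- nrow(x)
  if (m %% 4 != 0)
    abort("channel count must be a multiple of 4 (paired cos/sin, two populations)",
          class = "phasechimera_argument_error")
  n <- m %/% 4
  times <- times %||% (seq_len(ncol(x)) - 1)
  cos_rows <- c(seq_len(n), 2 * n + seq_len(n))
  sin_rows <- c(n + seq_len(n), 3 * n + seq_len(n))
  amp <- sqrt(x[cos_rows, , drop = FALSE]^2 + x[sin_rows, , drop = FALSE]^2)
  if (mean(amp < 0.2) > 0.05)
    warn("degenerate decoding: cos/sin amplitude < 0.2 for > 5% of samples")
  ang <- function(ci, si) {
    th <- atan2(x[si, , drop = FALSE], x[ci, , drop = FALSE])
    t(wrap_phase(th))
  }
  phi <- ang(seq_len(n), n + seq_len(n))
  gamma <- ang(2 * n + seq_len(n), 3 * n + seq_len(n))
  phases <- unwrap_phase(cbind(gamma, phi))
  phase_trajectory(times, phases, model = "decoded",
                   populations = rep(c("gamma", "phi"), each = n))
}

#' Decoded output vs. supervisor plot
#'
#' @param object A `force_fit`.
#' @param channels Channels to display (default: first 4).
#' @param ... Unused.
#' @return A ggplot overlaying decoded output and supervisor channels.
#' @export
autoplot.force_fit <- function(object, channels = 1:4, ...) {
  tr <- object$traces$post
  dfs <- purrr::map(channels, function(ch) {
    tibble(time = rep(tr$times, 2), channel = ch,
           series = rep(c("decoded", "supervisor"), each = length(tr$times)),
           value = c(tr$xhat[ch, ], object$supervisor_post[ch, ]))
  })
  ggplot(dplyr::bind_rows(dfs),
         aes(x = .data$time, y = .data$value, colour = .data$series)) +
    geom_line(linewidth = 0.3) +
    facet_wrap(~channel, ncol = 1) +
    labs(x = "time (ms)", y = "output")
}
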