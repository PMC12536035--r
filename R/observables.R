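#' Convert phase trajectories into spikes (Poincare map)
#'
#' Emits one spike each time an oscillator's unwrapped phase crosses a
#' multiple of `2*pi` from below, i.e. each time the wrapped phase passes
#' through 0 in the direction of increasing phase (backward crossings, which
#' can occur transiently, are ignored). The crossing time is located by
#' linear interpolation between the bracketing recorded samples, so the
#' per-unit spike count over a window equals the rotation count `M_i` that
#' [mean_phase_velocity()] uses over the same window.
#'
#' @param trajectory A [phase_trajectory()].
#' @param units Optional integer vector of oscillators to convert
#'   (default: all).
#' @return A `spike_raster`: a tibble with columns `unit` and `time`
#'   (strictly increasing per unit), with the source window and model kept
#'   as attributes. An empty raster (no crossings) is allowed.
#' @export
#' @examples
#' tr <- phase_trajectory(seq(0, 3, 0.01), cbind(2 * pi * seq(0, 3, 0.01)))
#' phases_to_spikes(tr)
phases_to_spikes <- function(trajectory, units = NULL) {
  stopifnot(inherits(trajectory, "phase_trajectory"))
  units <- units %||% seq_len(n_units(trajectory))
  tt <- trajectory$times
  two_pi <- 2 * pi

  one_unit <- function(j) {
    p <- trajectory$phases[, j]
    k1 <- floor(p[-length(p)] / two_pi)
    k2 <- floor(p[-1] / two_pi)
    idx <- which(k2 > k1)
    if (!length(idx)) return(numeric(0))
    # one entry per crossed level (handles >1 crossing per interval)
    reps <- k2[idx] - k1[idx]
    i_rep <- rep(idx, reps)
    lev <- two_pi * (sequence(reps) + rep(k1[idx], reps))
    p1 <- p[i_rep]; p2 <- p[i_rep + 1]
    t1 <- tt[i_rep]; t2 <- tt[i_rep + 1]
    sort(t1 + (lev - p1) / (p2 - p1) * (t2 - t1))
  }

  sp <- lapply(units, one_unit)
  out <- tibble(unit = rep(units, lengths(sp)), time = unlist(sp) %||% numeric(0))
  structure(out,
            class = c("spike_raster", class(out)),
            window = range(tt), model = trajectory$model,
            populations = trajectory$populations)
}

#' Phenomenological LFP trace from a phase trajectory
#'
#' The local field potential stand-in is the pointwise mean of `cos(phase)`
#' over a set of oscillators: either the synchronized population
#' (`"synchronized-mean"`, requires `sync_units`) or all oscillators
#' (`"global-mean"`). Both give qualitatively similar theta-band traces.
#'
#' @param trajectory A [phase_trajectory()].
#' @param mode `"global-mean"` (default) or `"synchronized-mean"`.
#' @param sync_units Oscillator indices of the synchronized set, required for
#'   `"synchronized-mean"`.
#' @return A tibble with columns `time` and `amplitude` (in `[-1, 1]`), with
#'   the mode kept as an attribute.
#' @export
compute_lfp <- function(trajectory,
                        mode = c("global-mean", "synchronized-mean"),
                        sync_units = NULL) {
  stopifnot(inherits(trajectory, "phase_trajectory"))
  mode <- match.arg(mode)
  units <- if (mode == "synchronized-mean") {
    if (is.null(sync_units) || !length(sync_units))
      abort("`sync_units` must be a non-empty unit set for synchronized-mean mode",
            class = "phasechimera_argument_error")
    sync_units
  } else {
    seq_len(n_units(trajectory))
  }
  amp <- rowMeans(cos(trajectory$phases[, units, drop = FALSE]))
  out <- tibble(time = trajectory$times, amplitude = amp)
  attr(out, "mode") <- mode
  out
}

#' Kuramoto order parameter over time
#'
#' Computes `R(t) = |mean(exp(i * theta_j(t)))|` over the selected
#' oscillators: 1 for full synchrony, near 0 for incoherence.
#'
#' @param trajectory A [phase_trajectory()].
#' @param units Oscillator indices (default: all). Must be non-empty.
#' @return A tibble with columns `time` and `R` (each in `[0, 1]`).
#' @export
#' @examples
#' tr <- phase_trajectory(0:2, matrix(1, 3, 4))
#' order_parameter(tr)$R
order_parameter <- function(trajectory, units = NULL) {
  stopifnot(inherits(trajectory, "phase_trajectory"))
  units <- units %||% seq_len(n_units(trajectory))
  if (!length(units))
    abort("`units` must be non-empty", class = "phasechimera_argument_error")
  ph <- trajectory$phases[, units, drop = FALSE]
  R <- sqrt(rowMeans(cos(ph))^2 + rowMeans(sin(ph))^2)
  tibble(time = trajectory$times, R = pmin(R, 1))
}

#' Spike raster plot
#'
#' @param object A `spike_raster` from [phases_to_spikes()] or a trained
#'   network trace.
#' @param ... Unused.
#' @return A ggplot object with one tick row per unit.
#' @export
autoplot.spike_raster <- function(object, ...) {
  ggplot(object, aes(x = .data$time, y = .data$unit)) +
    geom_point(shape = "|", size = 1.5) +
    labs(x = "time", y = "unit")
}
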