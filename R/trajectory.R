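#' Phase trajectory container
#'
#' Holds the sampled phase series of a simulated oscillator network. Phases
#' are stored unwrapped (cumulative), which is what rotation counting, spike
#' generation and velocity metrics need; the wrapped view onto `[0, 2*pi)` is
#' computed on demand with [wrapped_phases()] or [tidy()].
#'
#' @param times Strictly increasing sample times (dimensionless time units).
#' @param phases Numeric matrix, `length(times)` rows, one column per
#'   oscillator, unwrapped phases in radians.
#' @param model Character tag: `"ring"`, `"twopop"`, `"decoded"`, or
#'   `"synthetic"`.
#' @param config The configuration object the trajectory came from (may be
#'   `NULL` for synthetic fixtures).
#' @param populations Optional character vector, one label per oscillator
#'   (e.g. `"gamma"` / `"phi"` for the two-population model).
#' @param seed Integer seed used to produce the trajectory, or `NULL`.
#' @param events Optional list of logged events (e.g. perturbations).
#' @return An object of class `phase_trajectory`.
#' @export
phase_trajectory <- function(times, phases, model = "synthetic", config = NULL,
                             populations = NULL, seed = NULL, events = list()) {
  phases <- as.matrix(phases)
  if (length(times) != nrow(phases))
    abort("`times` must have one entry per row of `phases`",
          class = "phasechimera_config_error")
  if (any(diff(times) <= 0))
    abort("`times` must be strictly increasing",
          class = "phasechimera_config_error")
  if (!is.null(populations) && length(populations) != ncol(phases))
    abort("`populations` must have one label per oscillator",
          class = "phasechimera_config_error")
  structure(
    list(times = as.numeric(times), phases = phases, model = model,
         config = config, populations = populations, seed = seed,
         events = events),
    class = "phase_trajectory")
}

#' @export
print.phase_trajectory <- function(x, ...) {
  cat(sprintf("<phase_trajectory: %s, %d oscillators, %d samples, t in [%g, %g]>\n",
              x$model, ncol(x$phases), length(x$times),
              min(x$times), max(x$times)))
  if (length(x$events))
    cat(sprintf("  events: %s\n",
                paste(vapply(x$events, function(e) e$label, ""), collapse = ", ")))
  invisible(x)
}

#' Number of oscillators in a trajectory
#' @param trajectory A [phase_trajectory()].
#' @return Integer count.
#' @export
n_units <- function(trajectory) ncol(trajectory$phases)

#' Wrapped view of a trajectory's phases
#'
#' @param trajectory A [phase_trajectory()].
#' @return Matrix of phases wrapped onto `[0, 2*pi)`, same shape as the
#'   stored unwrapped matrix.
#' @export
wrapped_phases <- function(trajectory) wrap_phase(trajectory$phases)

#' Tidy a phase trajectory into a long tibble
#'
#' @param x A [phase_trajectory()].
#' @param wrap If `TRUE` (default) add a `phase` column wrapped to
#'   `[0, 2*pi)` alongside the unwrapped one.
#' @param ... Unused.
#' @return A tibble with columns `time`, `unit`, `population` (if any),
#'   `phase_unwrapped` and `phase`.
#' @export
tidy.phase_trajectory <- function(x, wrap = TRUE, ...) {
  n <- n_units(x)
  out <- tibble(
    time = rep(x$times, times = n),
    unit = rep(seq_len(n), each = length(x$times)),
    phase_unwrapped = as.vector(x$phases))
  if (!is.null(x$populations))
    out$population <- x$populations[out$unit]
  if (wrap) out$phase <- wrap_phase(out$phase_unwrapped)
  out
}

#' Extract one unit's phase series as a reference trace
#'
#' Convenience for building the theta reference used by
#' [assign_spike_phases()]: the unwrapped phase of a single (typically
#' synchronized) oscillator.
#'
#' @param trajectory A [phase_trajectory()].
#' @param unit Column index of the oscillator to extract.
#' @return A tibble with columns `time` and `phase` (unwrapped).
#' @export
reference_phase <- function(trajectory, unit) {
  if (unit < 1 || unit > n_units(trajectory))
    abort("`unit` out of range", class = "phasechimera_argument_error")
  tibble(time = trajectory$times, phase = trajectory$phases[, unit])
}

#' Snapshot plot of a phase trajectory
#'
#' Plots the wrapped phase of every oscillator at one sampled time, the usual
#' way a chimera's coexisting coherent and incoherent domains are displayed.
#'
#' @param object A [phase_trajectory()].
#' @param at Time of the snapshot (nearest sample is used); defaults to the
#'   last sample.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.phase_trajectory <- function(object, at = NULL, ...) {
  at <- at %||% max(object$times)
  i <- which.min(abs(object$times - at))
  df <- tibble(unit = seq_len(n_units(object)),
               phase = wrap_phase(object$phases[i, ]))
  if (!is.null(object$populations)) df$population <- object$populations
  p <- ggplot(df, aes(x = .data$unit, y = .data$phase)) +
    geom_point(if (!is.null(object$populations))
      aes(colour = .data$population) else NULL, size = 0.8) +
    labs(x = "oscillator", y = "phase (rad)",
         title = sprintf("phase snapshot at t = %.4g", object$times[i])) +
    ylim(0, 2 * pi)
  p
}
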