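#' Assign theta phases to spikes
#'
#' Each spike time is mapped to the phase of a reference theta trace (the
#' unwrapped phase of a synchronized oscillator, or a decoded synchronized
#' component) by linear interpolation of the reference's unwrapped phase at
#' the spike time. The theta cycle index is the integer part of the
#' unwrapped phase divided by `2*pi`; the spike phase is the remainder,
#' wrapped onto `[0, 2*pi)`.
#'
#' @param raster A `spike_raster` (tibble with `unit`, `time`).
#' @param reference A tibble with columns `time` and `phase` (unwrapped
#'   reference phase), e.g. from [reference_phase()]; it must cover every
#'   spike time.
#' @return A `spike_phases` tibble: `unit`, `time`, `cycle`, `phase`.
#' @export
assign_spike_phases <- function(raster, reference) {
  stopifnot(is.data.frame(raster), is.data.frame(reference))
  if (!all(c("time", "phase") %in% names(reference)))
    abort("`reference` needs `time` and `phase` columns",
          class = "phasechimera_argument_error")
  if (nrow(raster)) {
    bad <- raster$time < min(reference$time) - 1e-9 |
      raster$time > max(reference$time) + 1e-9
    if (any(bad))
      abort(sprintf("spikes of unit(s) %s fall outside the reference window",
                    paste(unique(raster$unit[bad]), collapse = ", ")),
            class = "phasechimera_argument_error")
  }
  u <- if (nrow(raster))
    approx(reference$time, reference$phase, xout = raster$time,
           rule = 1)$y else numeric(0)
  out <- tibble(unit = raster$unit, time = raster$time,
                cycle = as.integer(floor(u / (2 * pi))),
                phase = wrap_phase(u))
  structure(out, class = c("spike_phases", class(out)))
}

# internal: circular-linear slope by maximizing the mean resultant length of
# (phase - slope * cycle); coarse grid then local refinement. Slopes are only
# identifiable modulo 2*pi per cycle, hence the bounded search range.
circlin_slope <- function(phase, cycle, slope_range = c(-pi, pi),
                          n_grid = 721) {
  rlen_at <- function(s) {
    z <- phase - s * cycle
    sqrt(mean(cos(z))^2 + mean(sin(z))^2)
  }
  grid <- seq(slope_range[1], slope_range[2], length.out = n_grid)
  r <- vapply(grid, rlen_at, 0)
  i <- which.max(r)
  lo <- grid[max(1, i - 1)]
  hi <- grid[min(n_grid, i + 1)]
  opt <- optimize(rlen_at, interval = c(lo, hi), maximum = TRUE,
                  tol = 1e-10)
  # prefer slope 0 when it explains the data equally well (breaks the tie
  # for perfectly constant phases in favor of "locked")
  if (rlen_at(0) >= opt$objective - 1e-12)
    list(slope = 0, rlen_fit = rlen_at(0))
  else
    list(slope = opt$maximum, rlen_fit = opt$objective)
}

#' Per-unit phase-precession slopes and classification
#'
#' For every unit with at least `min_spikes` spikes, fits a circular-linear
#' regression of spike phase against theta-cycle index (the slope that
#' maximizes the mean resultant length of `phase - slope * cycle`), and
#' classifies the unit:
#' * `precessing` — slope at or below `-slope_threshold` (phases arrive
#'   earlier on successive cycles);
#' * `locked` — `|slope| < slope_threshold` and the raw mean resultant
#'   length of the spike phases is at least `rlen_threshold`;
#' * `other` — anything else;
#' * `insufficient-data` — fewer than `min_spikes` spikes (no fit).
#'
#' The classification is a pure function of the slope and the resultant
#' length, and is invariant under adding a constant to all phases.
#'
#' @param spike_phases A `spike_phases` tibble from [assign_spike_phases()].
#' @param slope_threshold Slope magnitude (radians per theta cycle) below
#'   which a unit is not considered precessing (default 0.1).
#' @param rlen_threshold Minimum raw mean resultant length for `locked`
#'   (default 0.8).
#' @param min_spikes Minimum spikes per unit for a fit (default 3).
#' @param slope_range Bounded slope search interval (radians per cycle;
#'   default `c(-pi, pi)`, the identifiable range for integer cycles).
#' @return A `precession_report` tibble: `unit`, `n_spikes`, `slope`,
#'   `rlen` (raw mean resultant length), `rlen_fit` (at the fitted slope)
#'   and `classification`.
#' @export
precession_report <- function(spike_phases, slope_threshold = 0.1,
                              rlen_threshold = 0.8, min_spikes = 3,
                              slope_range = c(-pi, pi)) {
  stopifnot(is.data.frame(spike_phases))
  by_unit <- split(spike_phases, spike_phases$unit)
  rows <- purrr::map(by_unit, function(df) {
    n <- nrow(df)
    if (n < min_spikes) {
      return(tibble(unit = df$unit[1], n_spikes = n, slope = NA_real_,
                    rlen = NA_real_, rlen_fit = NA_real_,
                    classification = "insufficient-data"))
    }
    rlen_raw <- sqrt(mean(cos(df$phase))^2 + mean(sin(df$phase))^2)
    fit <- circlin_slope(df$phase, df$cycle, slope_range = slope_range)
    cls <- if (fit$slope <= -slope_threshold) "precessing"
    else if (abs(fit$slope) < slope_threshold && rlen_raw >= rlen_threshold)
      "locked"
    else "other"
    tibble(unit = df$unit[1], n_spikes = n, slope = fit$slope,
           rlen = rlen_raw, rlen_fit = fit$rlen_fit, classification = cls)
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("precession_report", class(out)))
}

#' Theta-sequence consistency score
#'
#' Measures whether units fire in a repeatable order within theta cycles:
#' within each cycle units are ranked by their first spike time, and the
#' score is the mean Spearman rank correlation of those orders between
#' consecutive cycle pairs (computed over the units present in both cycles).
#' 1 means an identical order every cycle; values near 0 mean unrelated
#' orders.
#'
#' @param spike_phases A `spike_phases` tibble ([assign_spike_phases()]),
#'   typically restricted to unsynchronized units.
#' @param cycles Optional integer vector restricting which theta cycles are
#'   considered.
#' @param min_units Minimum units a cycle pair must share to contribute
#'   (default 2).
#' @return A one-row tibble: `score` (in `[-1, 1]`, `NA` when no cycle pair
#'   qualifies — the insufficient-data result) and `n_pairs`.
#' @export
theta_sequence_score <- function(spike_phases, cycles = NULL, min_units = 2) {
  stopifnot(is.data.frame(spike_phases))
  df <- spike_phases
  if (!is.null(cycles)) df <- df[df$cycle %in% cycles, ]
  if (!nrow(df)) return(tibble(score = NA_real_, n_pairs = 0L))
  first <- dplyr::summarise(dplyr::group_by(df, .data$cycle, .data$unit),
                            t0 = min(.data$time), .groups = "drop")
  cyc <- sort(unique(first$cycle))
  cors <- c()
  for (i in seq_len(length(cyc) - 1)) {
    a <- first[first$cycle == cyc[i], ]
    b <- first[first$cycle == cyc[i + 1], ]
    common <- intersect(a$unit, b$unit)
    if (length(common) < min_units) next
    ra <- rank(a$t0[match(common, a$unit)])
    rb <- rank(b$t0[match(common, b$unit)])
    if (sd(ra) == 0 || sd(rb) == 0) next
    cors <- c(cors, cor(ra, rb, method = "spearman"))
  }
  if (!length(cors)) return(tibble(score = NA_real_, n_pairs = 0L))
  tibble(score = mean(cors), n_pairs = length(cors))
}

#' Spike phase vs. theta cycle plot
#'
#' @param object A `spike_phases` tibble.
#' @param units Optional unit subset to display.
#' @param ... Unused.
#' @return A ggplot of spike phase against cycle index, faceted by unit.
#' @export
autoplot.spike_phases <- function(object, units = NULL, ...) {
  df <- if (is.null(units)) object else object[object$unit %in% units, ]
  ggplot(df, aes(x = .data$cycle, y = .data$phase)) +
    geom_point(size = 0.7) +
    facet_wrap(~unit) +
    labs(x = "theta cycle", y = "spike phase (rad)") +
    ylim(0, 2 * pi)
}
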