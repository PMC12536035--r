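#' Wrap phases onto [0, 2*pi)
#'
#' @param x Numeric vector or matrix of phases (radians).
#' @return `x` reduced modulo `2*pi`, in `[0, 2*pi)`.
#' @export
#' @examples
#' wrap_phase(c(-pi, 7))
wrap_phase <- function(x) {
  x %% (2 * pi)
}

#' Unwrap a wrapped phase series
#'
#' Reconstructs a cumulative (unwrapped) phase series from one wrapped onto
#' `[0, 2*pi)` by removing jumps larger than `pi` between consecutive samples.
#' Columns of a matrix are unwrapped independently.
#'
#' @param x Numeric vector, or matrix with one column per oscillator.
#' @return Unwrapped phases, same shape as `x`.
#' @export
#' @examples
#' th <- wrap_phase(seq(0, 20, by = 0.1))
#' max(abs(unwrap_phase(th) - seq(0, 20, by = 0.1)))
unwrap_phase <- function(x) {
  unwrap1 <- function(p) {
    dp <- diff(p)
    dp <- dp - 2 * pi * round(dp / (2 * pi))
    c(p[1], p[1] + cumsum(dp))
  }
  if (is.matrix(x)) apply(x, 2, unwrap1) else unwrap1(x)
}

# internal: validate a single positive scalar
check_scalar <- function(x, name, positive = TRUE, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x))
    abort(sprintf("`%s` must be a finite numeric scalar", name),
          class = "phasechimera_config_error")
  if (positive && x <= 0)
    abort(sprintf("`%s` must be positive", name),
          class = "phasechimera_config_error")
  if (integer && x != round(x))
    abort(sprintf("`%s` must be a whole number", name),
          class = "phasechimera_config_error")
  invisible(x)
}

# internal: seed handling; NULL leaves the RNG stream alone
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    check_scalar(seed, "seed", positive = FALSE, integer = TRUE)
    set.seed(seed)
  }
  expr
}
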