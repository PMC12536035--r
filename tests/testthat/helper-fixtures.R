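# Fixtures built in code: small trajectories and rasters with known structure.

# trajectory of independent constant-rate oscillators: phase_j(t) = phi0_j + omega_j * t
const_rate_trajectory <- function(omega, duration = 3, dt = 0.01, phi0 = NULL) {
  phi0 <- phi0 %||% rep(0, length(omega))
  times <- seq(0, duration, by = dt)
  phases <- outer(times, omega) + matrix(phi0, length(times), length(omega),
                                         byrow = TRUE)
  phase_trajectory(times, phases, model = "synthetic")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# spike raster of constant-rate trains: unit j spikes every 1/f_j
const_rate_raster <- function(freqs, duration = 10, t0 = 0) {
  sp <- lapply(seq_along(freqs), function(j) {
    s <- seq(t0 + 1 / freqs[j], duration, by = 1 / freqs[j])
    tibble::tibble(unit = j, time = s)
  })
  out <- dplyr::bind_rows(sp)
  structure(out, class = c("spike_raster", class(out)),
            window = c(t0, duration), model = "synthetic")
}

# literal double-loop Euler step of the ring model (oracle)
ring_euler_oracle <- function(phi, A, beta, rho, dt) {
  N <- length(phi)
  d <- numeric(N)
  for (i in 1:N) {
    s <- 0
    for (j in 1:N)
      s <- s + (1 + A * cos(2 * pi * abs(i - j) / N)) *
        cos(phi[i] - phi[j] - beta)
    d[i] <- rho - s / N
  }
  phi + dt * d
}

# literal double-loop Euler step of the two-population model (oracle)
twopop_euler_oracle <- function(gamma, phi, mu, nu, beta, rho, tau, dt) {
  n <- length(gamma)
  dg <- numeric(n); dp <- numeric(n)
  for (i in 1:n) {
    s1 <- sum(cos(gamma[i] - gamma - beta))
    s2 <- sum(cos(gamma[i] - phi - beta))
    dg[i] <- (rho - mu * s1 - nu * s2) / tau
    s3 <- sum(cos(phi[i] - phi - beta))
    s4 <- sum(cos(phi[i] - gamma - beta))
    dp[i] <- (rho - mu * s3 - nu * s4) / tau
  }
  list(gamma = gamma + dt * dg, phi = phi + dt * dp)
}
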