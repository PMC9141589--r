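#' Lorenz system right-hand side
#'
#' The classic chaotic benchmark with the standard parameters
#' `sigma = 10`, `rho = 28`, `beta = 8/3`:
#' `dx/dt = 10(-x + y)`, `dy/dt = 28x - y - xz`, `dz/dt = xy - (8/3)z`.
#'
#' @param state Numeric vector `c(x, y, z)`.
#' @return Numeric vector of derivatives `c(dx, dy, dz)`.
#' @export
lorenz_rhs <- function(state) {
  x <- state[1]; y <- state[2]; z <- state[3]
  c(10 * (-x + y),
    28 * x - y - x * z,
    x * y - (8 / 3) * z)
}

#' Classical fourth-order Runge-Kutta integration
#'
#' Fixed-step RK4. Returns `n_samples` states including the initial state
#' first, at times `t_k = k * dt`, `k = 0 .. n_samples - 1`.
#'
#' @param initial Numeric initial state vector.
#' @param dt Positive step size.
#' @param n_samples Number of samples to return (>= 1).
#' @param rhs Derivative function of the state (default [lorenz_rhs()]).
#' @return A matrix with `n_samples` rows, one column per state component.
#' @export
rk4_integrate <- function(initial, dt, n_samples, rhs = lorenz_rhs) {
  stopifnot(dt > 0, n_samples >= 1)
  d <- length(initial)
  out <- matrix(NA_real_, nrow = n_samples, ncol = d)
  s <- as.numeric(initial)
  out[1, ] <- s
  if (n_samples > 1) {
    for (k in 2:n_samples) {
      k1 <- rhs(s)
      k2 <- rhs(s + dt / 2 * k1)
      k3 <- rhs(s + dt / 2 * k2)
      k4 <- rhs(s + dt * k3)
      s <- s + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      if (any(!is.finite(s))) {
        stop(sprintf("integration blew up (non-finite state) at step %d", k - 1L))
      }
      out[k, ] <- s
    }
  }
  out
}

#' Simulate the Lorenz x-component for the deletion benchmark
#'
#' The benchmark couples step size and simulation length to the number of
#' interpolation points `n_interp`: `dt = 0.1 / (n_interp + 1)` and
#' `L = 200 * (n_interp + 1)` samples, so the total simulated time is always
#' 20 and the retained points of the deletion protocol sit at times
#' `0, 0.1, 0.2, ...` for every `n_interp`. Initial condition
#' `(x, y, z) = (-8, 8, 27)`.
#'
#' @param n_interp Number of interpolation points per gap (>= 1).
#' @return A time series `data.frame` of the x-component with
#'   `t_k = k * dt`.
#' @export
simulate_lorenz_x <- function(n_interp) {
  stopifnot(n_interp >= 1)
  dt <- 0.1 / (n_interp + 1)
  n_samples <- 200L * (as.integer(n_interp) + 1L)
  states <- rk4_integrate(c(-8, 8, 27), dt, n_samples)
  time_series((seq_len(n_samples) - 1) * dt, states[, 1])
}
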