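#' Covariance of fractional Brownian motion
#'
#' The covariance of fBm with Hurst exponent `h` is
#' `C(t, t') = (t^{2H} + t'^{2H} - |t - t'|^{2H}) / 2`. For `h = 0.5` this
#' collapses to `min(t, t')`, the Brownian case.
#'
#' @param t,t_prime Non-negative times (vectorized, recycled).
#' @param h Hurst exponent, strictly inside (0, 1).
#' @return Numeric covariance value(s).
#' @export
fbm_covariance <- function(t, t_prime, h) {
  check_hurst(h)
  if (any(t < 0) || any(t_prime < 0)) stop("times must be non-negative")
  0.5 * (t^(2 * h) + t_prime^(2 * h) - abs(t - t_prime)^(2 * h))
}

check_hurst <- function(h) {
  if (!is.numeric(h) || length(h) != 1 || is.na(h) || h <= 0 || h >= 1) {
    stop("Hurst exponent must be a single number strictly inside (0, 1)")
  }
  invisible(h)
}

check_grid <- function(times) {
  if (any(times < 0)) stop("grid times must be non-negative")
  if (length(times) > 1 && any(diff(times) <= 0)) {
    stop("grid times must be strictly increasing")
  }
  invisible(times)
}

# Full covariance matrix of fBm over a vector of (positive) times.
fbm_cov_matrix <- function(times, h) {
  p <- times^(2 * h)
  0.5 * (outer(p, p, "+") - abs(outer(times, times, "-"))^(2 * h))
}

# Cholesky factor (upper triangular) of the fBm covariance over positive
# times. If factorization fails, a jitter of 1e-12 * max diagonal is added
# once; a second failure is reported as a numerical error (no silent
# regularization beyond the documented jitter).
fbm_chol <- function(times, h) {
  C <- fbm_cov_matrix(times, h)
  out <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(out)) {
    jitter <- 1e-12 * max(diag(C))
    out <- tryCatch(chol(C + diag(jitter, nrow(C))), error = function(e) NULL)
  }
  if (is.null(out)) {
    stop(sprintf(
      "fBm covariance matrix is numerically not positive definite (H = %g, %d grid points)",
      h, length(times)))
  }
  out
}

# Draw `n` fBm paths over `grid` using the current RNG state. Returns a
# matrix with length(grid) rows and n columns; the row at t = 0 (if present)
# is exactly 0.
fbm_draw <- function(grid, h, n = 1) {
  has_origin <- grid[1] == 0
  times <- if (has_origin) grid[-1] else grid
  out <- matrix(0, nrow = length(grid), ncol = n)
  if (length(times) > 0) {
    L <- fbm_chol(times, h)
    z <- matrix(stats::rnorm(length(times) * n), nrow = length(times))
    x <- crossprod(L, z)
    if (has_origin) out[-1, ] <- x else out[, ] <- x
  }
  out
}

#' Sample a fractional Brownian motion path
#'
#' Exact sampling by Cholesky factorization of the full-grid covariance
#' matrix. The process is pinned to 0 at `t = 0` when the grid contains 0.
#'
#' @param grid Strictly increasing, non-negative sampling times.
#' @param h Hurst exponent in (0, 1).
#' @param seed Integer seed; identical `(seed, grid, h)` yields an identical
#'   path.
#' @return An object of class `gaussian_path`: a list with elements `times`,
#'   `values` and `hurst`.
#' @export
sample_fbm <- function(grid, h, seed) {
  check_hurst(h)
  check_grid(grid)
  values <- with_seed(seed, fbm_draw(grid, h, n = 1))[, 1]
  structure(list(times = grid, values = values, hurst = h),
            class = "gaussian_path")
}

#' Condition a Gaussian path on prescribed points
#'
#' Turns an fBm realization `X(t)` into a multi-point bridge
#' `X_B(t) = X(t) - (X(t_i) - X_i) [sigma^{-1}]_{ij} C(t, t_j)` (summation
#' over repeated indices), where `sigma_ij = C(t_i, t_j)` is the covariance
#' between constraint times. The bridge takes the value `X_k` at every
#' constraint time `t_k` exactly (to float round-off); the operation is
#' affine in the input path, so a path already satisfying the constraints is
#' returned unchanged.
#'
#' @param path A `gaussian_path` from [sample_fbm()].
#' @param constraints A data frame with columns `t` (strictly increasing,
#'   all > 0, each a member of the path's grid) and `value`.
#' @return An object of class `bridge_path`: list with `times`, `values`,
#'   `hurst` and `constraints`.
#' @export
condition_on_points <- function(path, constraints) {
  stopifnot(inherits(path, "gaussian_path") || is.list(path))
  ct <- as.numeric(constraints$t)
  cv <- as.numeric(constraints$value)
  if (length(ct) < 1) stop("at least one constraint point is required")
  if (any(duplicated(ct))) {
    stop(sprintf("duplicate constraint time t = %g makes sigma singular", ct[duplicated(ct)][1]))
  }
  if (any(ct <= 0)) {
    stop(sprintf("constraint at t = %g: constraints must have t > 0 (t = 0 is the pinned origin)",
                 ct[ct <= 0][1]))
  }
  idx <- match(ct, path$times)
  if (anyNA(idx)) {
    stop(sprintf("constraint time t = %g is not a member of the path's grid", ct[is.na(idx)][1]))
  }
  h <- path$hurst
  sigma <- fbm_cov_matrix(ct, h)
  ctc <- cross_cov(path$times, ct, h)
  resid <- path$values[idx] - cv
  corr <- ctc %*% solve(sigma, resid)
  values <- path$values - as.numeric(corr)
  structure(list(times = path$times, values = values, hurst = h,
                 constraints = data.frame(t = ct, value = cv)),
            class = "bridge_path")
}

# C(t, t_j) between all grid times and the constraint times.
cross_cov <- function(times, ct, h) {
  0.5 * (outer(times^(2 * h), ct^(2 * h), "+") -
           abs(outer(times, ct, "-"))^(2 * h))
}

# Core bridge interpolation using the current RNG state.
#
# Coordinates: the fBm lives on the refined *index* grid 0..M-1 (the gap
# between consecutive observed points spans points_per_gap + 1 index units);
# output times are placed uniformly inside each observed gap. The first
# observed value is subtracted from all constraints so the bridge starts
# from the pinned origin; it is added back afterwards.
bridge_interpolate <- function(observed_t, observed_v, points_per_gap, h, scale = 1) {
  n <- length(observed_t)
  K <- points_per_gap
  M <- n + (n - 1L) * K
  grid_idx <- 0:(M - 1)
  anchor_idx <- seq(0L, M - 1L, by = K + 1L)          # index positions of observed points
  offset <- observed_v[1]

  ct <- as.numeric(anchor_idx[-1])                    # constraints (origin handled by offset)
  cv <- observed_v[-1] - offset

  times <- as.numeric(grid_idx[-1])                   # positive grid times
  sigma <- fbm_cov_matrix(ct, h)
  ctc <- cross_cov(times, ct, h)
  w <- solve(sigma, t(ctc))                           # sigma^{-1} C(t_j, t) , n-1 x M-1

  x <- fbm_draw(as.numeric(grid_idx), h, n = 1)[, 1]  # consumes current RNG
  xc <- x[match(ct, grid_idx)]
  cond_mean <- as.numeric(crossprod(w, cv))
  fluct <- x[-1] - as.numeric(crossprod(w, xc))
  values <- c(0, cond_mean + scale * fluct) + offset

  # refined output times: uniform placement inside each observed gap
  t_out <- refined_times(observed_t, K)
  values[anchor_idx + 1L] <- observed_v              # anchors exact by construction
  time_series(t_out, values)
}

refined_times <- function(observed_t, K) {
  n <- length(observed_t)
  parts <- vector("list", n - 1)
  for (g in seq_len(n - 1)) {
    seg <- seq(observed_t[g], observed_t[g + 1], length.out = K + 2)
    parts[[g]] <- seg[-(K + 2)]
  }
  c(unlist(parts), observed_t[n])
}

#' Fill the gaps of an observed series with one stochastic bridge
#'
#' Refines the observed series with `points_per_gap` new samples placed
#' uniformly inside every gap, with values drawn from a single multi-point
#' fractional Brownian bridge with Hurst exponent `h` constrained on all
#' observed points. Observed values appear unchanged in the output. Gaps may
#' be non-equidistant; the fBm time coordinate is the refined sample index.
#'
#' @param observed A time series `data.frame` with at least 2 points.
#' @param points_per_gap Number of new samples per gap (>= 1).
#' @param h Hurst exponent in (0, 1).
#' @param seed Integer seed; a fixed seed gives byte-identical output.
#' @param scale Amplitude multiplier applied to the sampled fBm fluctuation
#'   before conditioning (default 1).
#' @return A refined time series `data.frame`.
#' @export
interpolate_gaps <- function(observed, points_per_gap, h, seed, scale = 1) {
  check_hurst(h)
  if (!is.numeric(points_per_gap) || points_per_gap < 1) {
    stop("`points_per_gap` must be a positive integer (>= 1)")
  }
  if (nrow(observed) < 2) stop("need at least 2 observed points")
  if (scale <= 0) stop("`scale` must be positive")
  with_seed(seed, bridge_interpolate(observed$t, observed$value,
                                     as.integer(points_per_gap), h, scale))
}
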