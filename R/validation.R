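#' Deletion split of a series
#'
#' Keeps indices `1, n_interp + 2, 2(n_interp + 1) + 1, ...` (1-based;
#' consecutive kept indices differ by `n_interp + 1`) and truncates the
#' series at the last kept index so every gap has both anchors. Every gap
#' interior holds exactly `n_interp` deleted samples.
#'
#' @param series A time series `data.frame`.
#' @param n_interp Number of deleted samples per gap (>= 1).
#' @return A list with `kept`, `missing` (integer index vectors over the
#'   truncated series) and `n` (truncated length).
#' @export
subsample <- function(series, n_interp) {
  n_total <- nrow(series)
  stopifnot(n_interp >= 1)
  if (n_total < n_interp + 2) stop("series too short for this split")
  kept <- seq(1L, n_total, by = as.integer(n_interp) + 1L)
  n <- kept[length(kept)]
  missing <- setdiff(seq_len(n), kept)
  list(kept = kept, missing = missing, n = n)
}

#' Root mean squared error
#'
#' `sqrt(mean((estimate - truth)^2))` over equal-length vectors.
#'
#' @param truth,estimate Numeric vectors of equal, positive length.
#' @return A single non-negative number.
#' @export
rmse <- function(truth, estimate) {
  if (length(truth) != length(estimate)) stop("length mismatch")
  if (length(truth) == 0) stop("empty input")
  sqrt(mean((estimate - truth)^2))
}

#' Linear baseline reconstruction
#'
#' Reconstructs the deleted samples by straight segments between the kept
#' points, against the time coordinate.
#'
#' @param split A split from [subsample()].
#' @param series The original time series `data.frame`.
#' @return Numeric vector of reconstructed values at the missing times.
#' @export
linear_baseline <- function(split, series) {
  if (length(split$kept) < 2) stop("need at least 2 kept points")
  stats::approx(series$t[split$kept], series$value[split$kept],
                xout = series$t[split$missing])$y
}

#' Cubic-spline baseline reconstruction
#'
#' Reconstructs the deleted samples with a C2 piecewise cubic through the
#' kept points, using not-a-knot end conditions (third-derivative
#' continuity at the second and penultimate knots).
#'
#' @param split A split from [subsample()].
#' @param series The original time series `data.frame`.
#' @return Numeric vector of reconstructed values at the missing times.
#' @export
spline_baseline <- function(split, series) {
  if (length(split$kept) < 4) stop("need at least 4 kept points for the cubic spline")
  spline_notaknot(series$t[split$kept], series$value[split$kept],
                  series$t[split$missing])
}

#' Not-a-knot C2 cubic spline interpolation
#'
#' Solves for the knot second derivatives of the C2 piecewise cubic
#' interpolant with not-a-knot end conditions and evaluates it at `xout`.
#' With exactly cubic data the interpolant reproduces the cubic to round-off.
#'
#' @param x Strictly increasing knot abscissae (length >= 4).
#' @param y Knot ordinates.
#' @param xout Evaluation points (clamped extrapolation uses the end cubics).
#' @return Numeric vector of interpolated values.
#' @export
spline_notaknot <- function(x, y, xout) {
  n <- length(x)
  stopifnot(n >= 4, length(y) == n)
  if (any(diff(x) <= 0)) stop("knots must be strictly increasing")
  h <- diff(x)
  slope <- diff(y) / h
  A <- matrix(0, n, n)
  b <- numeric(n)
  for (i in 2:(n - 1)) {
    A[i, i - 1] <- h[i - 1]
    A[i, i] <- 2 * (h[i - 1] + h[i])
    A[i, i + 1] <- h[i]
    b[i] <- 6 * (slope[i] - slope[i - 1])
  }
  # not-a-knot: continuous third derivative at the 2nd and penultimate knots
  A[1, 1] <- h[2]; A[1, 2] <- -(h[1] + h[2]); A[1, 3] <- h[1]
  A[n, n - 2] <- h[n - 1]; A[n, n - 1] <- -(h[n - 2] + h[n - 1]); A[n, n] <- h[n - 2]
  M <- solve(A, b)                       # second derivatives at the knots
  seg <- findInterval(xout, x, all.inside = TRUE)
  dx <- xout - x[seg]
  hk <- h[seg]
  a0 <- y[seg]
  a1 <- slope[seg] - hk * (2 * M[seg] + M[seg + 1]) / 6
  a2 <- M[seg] / 2
  a3 <- (M[seg + 1] - M[seg]) / (6 * hk)
  a0 + dx * (a1 + dx * (a2 + dx * a3))
}

#' Rescale and detrend a series, keeping the inverse transform
#'
#' Optionally subtracts a least-squares linear fit in `t`, then min-max
#' rescales the values to the unit interval. The returned transform record
#' allows exact inversion so downstream errors can be reported on the
#' original scale.
#'
#' @param series A time series `data.frame`.
#' @param rescale Rescale values to `[0, 1]` (default `TRUE`).
#' @param detrend Subtract a least-squares line first (default `FALSE`).
#' @return A list with `series` (transformed) and `transform` (record for
#'   [invert_preprocess()]).
#' @export
preprocess <- function(series, rescale = TRUE, detrend = FALSE) {
  v <- series$value
  tr <- list(detrend = detrend, rescale = rescale,
             intercept = 0, slope = 0, lo = 0, range = 1)
  if (detrend) {
    fit <- stats::lm.fit(cbind(1, series$t), v)
    tr$intercept <- fit$coefficients[1]
    tr$slope <- fit$coefficients[2]
    v <- v - (tr$intercept + tr$slope * series$t)
  }
  if (rescale) {
    tr$lo <- min(v)
    tr$range <- max(v) - min(v)
    # relative check: a detrended perfect line leaves only round-off
    tiny <- .Machine$double.eps^0.5 * max(1, diff(range(series$value)))
    if (tr$range < tiny) stop("cannot rescale a (numerically) constant series to the unit interval")
    v <- (v - tr$lo) / tr$range
  }
  list(series = time_series(series$t, v), transform = tr)
}

#' Invert a preprocessing transform
#'
#' @param series A (possibly refined) time series on the transformed scale.
#' @param transform The record returned by [preprocess()].
#' @return A time series `data.frame` on the original scale.
#' @export
invert_preprocess <- function(series, transform) {
  v <- series$value
  if (transform$rescale) v <- v * transform$range + transform$lo
  if (transform$detrend) v <- v + transform$intercept + transform$slope * series$t
  time_series(series$t, v)
}

#' Deletion/reconstruction benchmark
#'
#' The validation protocol: delete samples with [subsample()], reconstruct
#' the deleted points by (a) every candidate of the initial bridge
#' population -- reporting the RMSE of the pointwise-mean series and the
#' minimum per-candidate RMSE, (b) linear interpolation, (c) a not-a-knot
#' cubic spline, and (d) the search-improved interpolation, scoring
#' everything with [rmse()] over the deleted points only.
#'
#' @param series The ground-truth time series `data.frame`.
#' @param n_interp Deleted samples per gap; also the number of points each
#'   interpolation inserts per gap.
#' @param config A [ga_config()].
#' @return A list of class `validation_report` with per-method RMSEs
#'   (`population_mean`, `population_lowest`, `linear`, `spline`,
#'   `ga_improved`), `below_best` (fraction of the initial population with
#'   RMSE strictly below the improved result), `candidate_rmse` (vector),
#'   `generations_run`, `split` and `config`.
#' @export
run_benchmark <- function(series, n_interp, config) {
  split <- subsample(series, n_interp)
  truncated <- series[seq_len(split$n), ]
  observed <- truncated[split$kept, ]
  truth <- truncated$value[split$missing]

  pop <- init_population(observed, n_interp, config)
  # candidates live on the refined grid; uniform gaps make it coincide with
  # the truncated original index grid
  cand_values <- vapply(pop$candidates, function(c) c$values,
                        numeric(split$n))
  cand_rmse <- apply(cand_values[split$missing, , drop = FALSE], 2,
                     function(v) rmse(truth, v))
  mean_series <- rowMeans(cand_values)

  res <- run_ga(observed, n_interp, config, population = pop)
  ga_rmse <- rmse(truth, res$best$values[split$missing])

  structure(list(
    population_mean = rmse(truth, mean_series[split$missing]),
    population_lowest = min(cand_rmse),
    linear = rmse(truth, linear_baseline(split, truncated)),
    spline = rmse(truth, spline_baseline(split, truncated)),
    ga_improved = ga_rmse,
    below_best = mean(cand_rmse < ga_rmse),
    candidate_rmse = cand_rmse,
    generations_run = res$generations_run,
    n_missing = length(split$missing),
    split = split,
    config = config
  ), class = "validation_report")
}
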