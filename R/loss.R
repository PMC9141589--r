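#' Second central difference of a sequence
#'
#' Returns `x_{k+1} - 2 x_k + x_{k-1}` for every interior index `k`; the
#' output is two samples shorter than the input. Affine sequences map to
#' zero.
#'
#' @param component Numeric vector of length >= 3.
#' @return Numeric vector of length `length(component) - 2`.
#' @export
second_central_diff <- function(component) {
  if (length(component) < 3) stop("need at least 3 samples for a second central difference")
  diff(component, differences = 2)
}

#' Smoothness loss of a delay-embedded trajectory
#'
#' The fitness criterion of the interpolation search: embed the series with
#' the given dimension and delay, take the second central difference of each
#' embedding component, combine the components at every interior point --
#' either as the squared Euclidean norm (`mode = "squared_norm"`,
#' `u''(i) = sum_j u''_j(i)^2`) or its square root (`mode = "norm"`) -- and
#' return the population variance of that magnitude sequence. Smooth
#' trajectories with near-constant curvature magnitude score near 0; lower
#' is fitter. Second differences annihilate affine trends, so the loss is
#' invariant (to round-off) under `x + a + b*k`, and scales as `c^4`
#' (`squared_norm`) or `c^2` (`norm`) under `x -> c x`.
#'
#' @param series Numeric vector.
#' @param dimension Embedding dimension (default 3).
#' @param delay Embedding delay in samples (default 1).
#' @param mode `"norm"` (default) or `"squared_norm"`. Candidate rankings
#'   can differ between the two, which is why both are exposed.
#' @return A single non-negative number.
#' @export
trajectory_loss <- function(series, dimension = 3, delay = 1,
                            mode = c("norm", "squared_norm")) {
  mode <- match.arg(mode)
  mag <- trajectory_magnitudes(series, dimension, delay, mode)
  pop_var(mag)
}

# Per-point combined second-derivative magnitude along the embedded
# trajectory. Valid indices are those where every component's central
# difference exists (no boundary padding).
trajectory_magnitudes <- function(series, dimension, delay, mode) {
  n <- length(series)
  stopifnot(dimension >= 1, delay >= 1)
  lo <- 2L
  hi <- n - 1L - (dimension - 1L) * delay
  if (hi < lo) {
    stop(sprintf("series of length %d too short for dimension %d, delay %d plus second differences",
                 n, dimension, delay))
  }
  d2 <- diff(series, differences = 2)   # d2[k] is the central difference at sample k+1
  idx <- lo:hi
  s <- rep(0, length(idx))
  for (j in seq_len(dimension)) {
    s <- s + d2[idx + (j - 1L) * delay - 1L]^2
  }
  if (mode == "norm") sqrt(s) else s
}

pop_var <- function(x) {
  mean((x - mean(x))^2)
}

#' Loss surface over embedding parameters
#'
#' Evaluates [trajectory_loss()] on the Cartesian grid `delays x dims`.
#' Cells where the series is too short for the requested parameters are
#' `NA`.
#'
#' @param series Numeric vector.
#' @param delays Integer vector of delays to scan.
#' @param dims Integer vector of embedding dimensions to scan.
#' @param mode Loss mode, see [trajectory_loss()].
#' @return A numeric matrix with `length(delays)` rows and `length(dims)`
#'   columns, dimnames giving the parameter values.
#' @export
loss_surface <- function(series, delays, dims, mode = c("norm", "squared_norm")) {
  mode <- match.arg(mode)
  if (length(delays) == 0 || length(dims) == 0) stop("empty parameter range")
  out <- matrix(NA_real_, nrow = length(delays), ncol = length(dims),
                dimnames = list(delay = delays, dimension = dims))
  for (a in seq_along(delays)) {
    for (b in seq_along(dims)) {
      out[a, b] <- tryCatch(
        trajectory_loss(series, dimension = dims[b], delay = delays[a], mode = mode),
        error = function(e) NA_real_)
    }
  }
  out
}
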