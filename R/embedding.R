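#' Takens delay embedding
#'
#' Builds the matrix of delay vectors
#' `y_i = (x_i, x_{i+tau}, ..., x_{i+(d_E-1) tau})` reconstructing the phase
#' space of a scalar signal. Row `i`, column `j` equals sample
#' `i + (j - 1) * delay` (1-based).
#'
#' @param series Numeric vector.
#' @param dimension Embedding dimension `d_E` (>= 1).
#' @param delay Time delay `tau` in samples (>= 1).
#' @return A numeric matrix with `length(series) - (dimension - 1) * delay`
#'   rows and `dimension` columns.
#' @export
delay_embed <- function(series, dimension = 3, delay = 1) {
  n <- length(series)
  stopifnot(dimension >= 1, delay >= 1)
  m <- n - (dimension - 1) * delay
  if (m < 1) {
    stop(sprintf("series of length %d too short for dimension %d, delay %d",
                 n, dimension, delay))
  }
  out <- matrix(NA_real_, nrow = m, ncol = dimension)
  for (j in seq_len(dimension)) {
    out[, j] <- series[(1:m) + (j - 1) * delay]
  }
  out
}

#' Estimate the embedding delay from the autocorrelation function
#'
#' Returns the smallest lag at which the sample autocorrelation (biased
#' estimator, normalized by lag 0) first becomes non-positive. If the ACF
#' never crosses zero, returns 1 with a warning.
#'
#' @param series Numeric vector, length >= 10.
#' @return A positive integer lag.
#' @export
estimate_delay_autocorr <- function(series) {
  n <- length(series)
  if (n < 10) stop("need at least 10 samples")
  if (stats::sd(series) == 0) stop("autocorrelation undefined for a constant series")
  rho <- as.numeric(stats::acf(series, lag.max = n - 1, plot = FALSE)$acf)[-1]
  hit <- which(rho <= 0)
  if (length(hit) == 0) {
    warning("autocorrelation never crosses zero; returning delay 1")
    return(1L)
  }
  as.integer(hit[1])
}

# Histogram mutual information between x and its lag-ell copy.
lagged_mutual_info <- function(series, ell, bins) {
  n <- length(series)
  a <- series[1:(n - ell)]
  b <- series[(1 + ell):n]
  br <- seq(min(series), max(series), length.out = bins + 1)
  ia <- findInterval(a, br, rightmost.closed = TRUE, all.inside = TRUE)
  ib <- findInterval(b, br, rightmost.closed = TRUE, all.inside = TRUE)
  joint <- table(factor(ia, levels = 1:bins), factor(ib, levels = 1:bins))
  p <- joint / sum(joint)
  px <- rowSums(p); py <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / outer(px, py)[nz]))
}

#' Estimate the embedding delay from average mutual information
#'
#' Returns the smallest lag that is a local minimum of the
#' histogram-estimated mutual information `I(x_k; x_{k+lag})`, searching lags
#' up to `n / 4`. If no local minimum is found, returns 1 with a warning.
#'
#' @param series Numeric vector with `length >= 10 * bins`.
#' @param bins Number of histogram bins (>= 2).
#' @return A positive integer lag.
#' @export
estimate_delay_mutual_info <- function(series, bins = 16) {
  if (bins < 2) stop("`bins` must be at least 2")
  n <- length(series)
  if (n < 10 * bins) stop("need at least 10 * bins samples")
  if (stats::sd(series) == 0) stop("mutual information undefined for a constant series")
  max_lag <- max(2L, floor(n / 4))
  mi <- vapply(seq_len(max_lag), function(l) lagged_mutual_info(series, l, bins),
               numeric(1))
  for (l in seq_len(max_lag - 1)) {
    left_ok <- l == 1 || mi[l] < mi[l - 1]
    if (left_ok && mi[l] < mi[l + 1]) return(as.integer(l))
  }
  warning("no local minimum of mutual information within lag <= n/4; returning delay 1")
  1L
}

#' Estimate the embedding dimension by false nearest neighbours
#'
#' Kennel-style criterion: for each trial dimension `d`, the nearest
#' neighbour of every delay vector is found; the neighbour is declared false
#' if the extra coordinate added in dimension `d + 1` either inflates the
#' distance by more than `r_tol` (ratio test) or exceeds `a_tol` times the
#' attractor size (measured as the standard deviation of the series). The
#' smallest `d` whose false-neighbour fraction drops below `threshold` is
#' returned, capped at `max_dim`; if the cap is hit the function returns
#' `NA` with a warning ("no embedding found").
#'
#' @param series Numeric vector, length >= 50.
#' @param delay Embedding delay in samples.
#' @param r_tol Ratio-test threshold (default 10, the standard value).
#' @param a_tol Attractor-size-test threshold (default 2).
#' @param threshold Acceptable false-neighbour fraction (default 0.01).
#' @param max_dim Largest dimension tried (default 10).
#' @return A positive integer dimension, or `NA` if none is found.
#' @export
estimate_dim_fnn <- function(series, delay = 1, r_tol = 10, a_tol = 2,
                             threshold = 0.01, max_dim = 10) {
  n <- length(series)
  if (n < 50) stop("need at least 50 samples")
  if (stats::sd(series) == 0) stop("degenerate (constant) series")
  r_a <- stats::sd(series)
  for (d in seq_len(max_dim)) {
    frac <- fnn_fraction(series, d, delay, r_tol, a_tol, r_a)
    if (is.na(frac)) break
    if (frac < threshold) return(as.integer(d))
  }
  warning("no embedding found: false-neighbour fraction stayed above threshold up to the cap")
  NA_integer_
}

fnn_fraction <- function(series, d, delay, r_tol, a_tol, r_a) {
  n <- length(series)
  m <- n - d * delay           # vectors for which the (d+1)-th coordinate exists
  if (m < 2) return(NA_real_)
  emb <- delay_embed(series[1:(n - delay)], dimension = d, delay = delay)
  emb <- emb[1:m, , drop = FALSE]
  dm <- as.matrix(stats::dist(emb))
  diag(dm) <- Inf
  nn <- apply(dm, 1, which.min)
  rd <- dm[cbind(seq_len(m), nn)]
  extra <- abs(series[(1:m) + d * delay] - series[nn + d * delay])
  # near-duplicate states (exact repeats of a noiseless periodic signal)
  # make the ratio test 0/0-indeterminate; an absolute floor keeps them
  # classified as true neighbours
  ratio_false <- extra > pmax(r_tol * rd, 1e-9 * r_a)
  size_false <- sqrt(rd^2 + extra^2) / r_a > a_tol
  mean(ratio_false | size_false)
}
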