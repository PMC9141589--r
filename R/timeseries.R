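#' @keywords internal
"_PACKAGE"

#' Construct a time series record
#'
#' The universal input/output record of the package: a data frame with
#' numeric columns `t` (strictly increasing sampling times or indices) and
#' `value`.
#'
#' @param t Numeric vector of sampling times, strictly increasing.
#' @param value Numeric vector of observations, same length as `t`.
#' @return A `data.frame` with columns `t` and `value`.
#' @export
time_series <- function(t, value) {
  t <- as.numeric(t)
  value <- as.numeric(value)
  if (length(t) != length(value)) {
    stop("`t` and `value` must have the same length")
  }
  if (anyNA(t) || anyNA(value)) stop("time series must not contain NA")
  bad <- which(diff(t) <= 0)
  if (length(bad) > 0) {
    stop(sprintf("times must be strictly increasing; first violation at row %d (t = %g)",
                 bad[1] + 1L, t[bad[1] + 1L]))
  }
  data.frame(t = t, value = value)
}

#' Read a time series from CSV
#'
#' Expects a two-column CSV with header `t,value`. A single-column file is
#' accepted with a warning; times are then assigned `0..n-1`.
#'
#' @param path Path to a CSV file.
#' @return A time series `data.frame` (see [time_series()]).
#' @export
read_series <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("empty series file: ", path)
  if (ncol(df) == 1) {
    warning("single-column input: assigning times 0..n-1")
    return(time_series(seq_len(nrow(df)) - 1, df[[1]]))
  }
  if (!all(c("t", "value") %in% names(df))) {
    df <- df[, 1:2]
    names(df) <- c("t", "value")
  }
  for (col in c("t", "value")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (anyNA(v)) {
      stop(sprintf("non-numeric cell in column '%s' at row %d", col, which(is.na(v))[1]))
    }
    df[[col]] <- v
  }
  time_series(df$t, df$value)
}

#' Write a time series to CSV
#'
#' Values are written with 17 significant digits so that a write/read round
#' trip is lossless for doubles.
#'
#' @param series A time series `data.frame`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_series <- function(series, path) {
  series <- time_series(series$t, series$value)
  lines <- c("t,value",
             sprintf("%.17g,%.17g", series$t, series$value))
  writeLines(lines, path)
  invisible(path)
}

#' Generate a synthetic seasonal fixture series
#'
#' Emulates the statistical shape of short seasonal records (sharp repetitive
#' peaks riding on a linear trend plus observation noise):
#' `value_k = trend_slope * k + amplitude * |sin(pi k / period)|^peak_power + eps_k`
#' with `eps_k ~ N(0, noise_sd^2)`. Large `peak_power` sharpens the peaks
#' (epidemic-outbreak-like); `peak_power = 1` gives a smooth seasonal wave.
#'
#' @param length Number of samples (>= 2 * period for a seasonal fixture).
#' @param period Seasonal period, in samples.
#' @param trend_slope Linear trend per sample.
#' @param noise_sd Standard deviation of additive Gaussian noise.
#' @param amplitude Peak amplitude of the seasonal component.
#' @param peak_power Exponent sharpening the seasonal peaks.
#' @param seed Integer seed; the fixture is reproducible.
#' @return A time series `data.frame` with `t = 0..length-1`.
#' @export
make_fixture <- function(length = 120, period = 12, trend_slope = 0,
                         noise_sd = 0.05, amplitude = 1, peak_power = 1,
                         seed = 1) {
  stopifnot(length >= 2, period > 0)
  if (length < 2 * period) stop("`length` must be at least 2 * `period` for a seasonal fixture")
  k <- seq_len(length) - 1
  base <- trend_slope * k + amplitude * abs(sin(pi * k / period))^peak_power
  noise <- if (noise_sd > 0) {
    with_seed(seed, stats::rnorm(length, sd = noise_sd))
  } else {
    rep(0, length)
  }
  time_series(k, base + noise)
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}
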