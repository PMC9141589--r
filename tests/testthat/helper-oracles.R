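# Independent brute-force oracles used across the suite. These build every
# quantity by definition (explicit loops, direct covariance algebra) and are
# deliberately kept free of the package's vectorized implementations.

# Trajectory smoothness loss by direct construction: embed explicitly,
# second-difference each component at each valid interior index, combine,
# and take the population variance.
oracle_trajectory_loss <- function(x, d, tau, mode) {
  n <- length(x)
  m <- n - (d - 1) * tau
  mags <- c()
  for (i in seq_len(m)) {
    comps <- numeric(0)
    ok <- TRUE
    for (j in seq_len(d)) {
      center <- i + (j - 1) * tau
      if (center - 1 < 1 || center + 1 > n) { ok <- FALSE; break }
      comps[j] <- x[center + 1] - 2 * x[center] + x[center - 1]
    }
    if (ok) {
      s <- sum(comps^2)
      mags <- c(mags, if (mode == "norm") sqrt(s) else s)
    }
  }
  mean((mags - mean(mags))^2)
}

# Conditional Gaussian law for fBm on a small grid given constraints, by
# direct covariance algebra: mean = C_gc C_cc^{-1} v, cov = C_gg - C_gc
# C_cc^{-1} C_cg.
oracle_conditional_gaussian <- function(times, ctimes, cvalues, h) {
  cov2 <- function(a, b) 0.5 * (a^(2 * h) + b^(2 * h) - abs(a - b)^(2 * h))
  Cgg <- outer(times, times, cov2)
  Cgc <- outer(times, ctimes, cov2)
  Ccc <- outer(ctimes, ctimes, cov2)
  list(mean = as.numeric(Cgc %*% solve(Ccc, cvalues)),
       cov = Cgg - Cgc %*% solve(Ccc, t(Cgc)))
}

# First non-positive lag of the sample autocorrelation, computed from
# scratch with the biased covariance estimator.
oracle_acf_zero_crossing <- function(x) {
  n <- length(x)
  xc <- x - mean(x)
  c0 <- sum(xc^2)
  for (l in seq_len(n - 1)) {
    if (sum(xc[1:(n - l)] * xc[(1 + l):n]) / c0 <= 0) return(l)
  }
  NA_integer_
}

lorenz_fixture <- local({
  cache <- new.env()
  function(n_interp) {
    key <- paste0("n", n_interp)
    if (is.null(cache[[key]])) cache[[key]] <- simulate_lorenz_x(n_interp)
    cache[[key]]
  }
})
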