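test_that("fBm covariance matches the closed form and is symmetric", {
  expect_equal(fbm_covariance(1, 1, 0.3), 1.0)
  expect_equal(fbm_covariance(2, 3, 0.5), 2.0)    # Brownian case: min(t, t')
  expect_equal(fbm_covariance(1, 2, 0.75), sqrt(2), tolerance = 1e-12)
  for (h in c(0.2, 0.5, 0.8)) {
    t1 <- runif(20, 0, 10); t2 <- runif(20, 0, 10)
    expect_equal(fbm_covariance(t1, t2, h), fbm_covariance(t2, t1, h))
  }
  expect_error(fbm_covariance(1, 1, 0), "Hurst")
  expect_error(fbm_covariance(1, 1, 1), "Hurst")
  expect_error(fbm_covariance(-1, 1, 0.5), "non-negative")
})

test_that("fBm sampling is pinned at the origin, seeded, and has the right variance", {
  expect_identical(sample_fbm(0, 0.3, seed = 5)$values, 0)
  g <- seq(0, 10, by = 0.5)
  p1 <- sample_fbm(g, 0.6, seed = 11)
  p2 <- sample_fbm(g, 0.6, seed = 11)
  expect_identical(p1$values, p2$values)
  expect_identical(p1$values[1], 0)

  # Monte-Carlo check of Var[X(t)] = t^{2H} over 2000 draws
  grid <- 0:200
  draws <- phasefill:::with_seed(2024, phasefill:::fbm_draw(grid, 0.5, n = 2000))
  for (tt in c(50, 100, 200)) {
    v <- var(draws[tt + 1, ])
    expect_lt(abs(v - tt) / tt, 0.10)
  }
  draws8 <- phasefill:::with_seed(2025, phasefill:::fbm_draw(grid, 0.8, n = 2000))
  v <- var(draws8[101, ])
  expect_lt(abs(v - 100^1.6) / 100^1.6, 0.10)
})

test_that("conditioning passes exactly through arbitrary constraint sets", {
  grid <- 0:60
  for (h in seq(0.1, 0.9, by = 0.1)) {
    set.seed(round(1000 * h))
    nc <- sample(1:30, 1)
    ct <- sort(sample(grid[-1], nc))
    cv <- rnorm(nc, sd = 3)
    path <- sample_fbm(grid, h, seed = round(7000 * h))
    b <- condition_on_points(path, data.frame(t = ct, value = cv))
    expect_lt(max(abs(b$values[match(ct, grid)] - cv)), 1e-8)
  }
})

test_that("conditioning a path that already satisfies the constraints is the identity", {
  grid <- 0:40
  path <- sample_fbm(grid, 0.7, seed = 3)
  ct <- c(5, 17, 33)
  cons <- data.frame(t = ct, value = path$values[match(ct, grid)])
  b <- condition_on_points(path, cons)
  expect_equal(b$values, path$values, tolerance = 1e-10)
})

test_that("the zero-path bridge is the Gaussian conditional mean (linear for H = 1/2)", {
  grid <- seq(0, 1, by = 0.05)
  zero <- structure(list(times = grid, values = rep(0, length(grid)), hurst = 0.5),
                    class = "gaussian_path")
  b <- condition_on_points(zero, data.frame(t = 1, value = 5))
  expect_equal(b$values, 5 * grid, tolerance = 1e-8)

  # piecewise linear between consecutive constraints
  grid2 <- 0:20
  zero2 <- structure(list(times = grid2, values = rep(0, 21), hurst = 0.5),
                     class = "gaussian_path")
  b2 <- condition_on_points(zero2, data.frame(t = c(5, 12, 20), value = c(2, -1, 4)))
  expected <- approx(c(0, 5, 12, 20), c(0, 2, -1, 4), xout = grid2)$y
  expect_equal(b2$values, expected, tolerance = 1e-8)
})

test_that("bridge sampling matches the brute-force conditional Gaussian law", {
  grid <- c(0, 1, 2, 3)
  h <- 0.7
  ct <- 2; cv <- 1.5
  n <- 10000
  draws <- phasefill:::with_seed(99, phasefill:::fbm_draw(grid, h, n = n))
  bridges <- apply(draws, 2, function(x) {
    p <- structure(list(times = grid, values = x, hurst = h), class = "gaussian_path")
    condition_on_points(p, data.frame(t = ct, value = cv))$values
  })
  oracle <- oracle_conditional_gaussian(c(1, 3), ct, cv, h)
  for (k in 1:2) {
    row <- bridges[c(2, 4)[k], ]
    se_mean <- sd(row) / sqrt(n)
    expect_lt(abs(mean(row) - oracle$mean[k]), 5 * se_mean)
    se_var <- oracle$cov[k, k] * sqrt(2 / (n - 1))
    expect_lt(abs(var(row) - oracle$cov[k, k]), 5 * se_var)
  }
})

test_that("conditioning errors are explicit about the offending time", {
  path <- sample_fbm(0:10, 0.5, seed = 1)
  expect_error(condition_on_points(path, data.frame(t = c(3, 3), value = c(1, 2))),
               "t = 3")
  expect_error(condition_on_points(path, data.frame(t = 0, value = 1)), "t = 0")
  expect_error(condition_on_points(path, data.frame(t = 4.5, value = 1)),
               "not a member")
})

test_that("gap interpolation honours its contract", {
  obs <- time_series(c(0, 1), c(3, 7))
  expect_error(interpolate_gaps(obs, 0, 0.5, seed = 1), "positive integer")
  expect_error(interpolate_gaps(obs[1, ], 2, 0.5, seed = 1), "at least 2")

  # determinism is byte-identical
  obs2 <- time_series(c(0, 2, 3, 7), c(1, -2, 4, 0))
  a <- interpolate_gaps(obs2, 3, 0.65, seed = 12)
  b <- interpolate_gaps(obs2, 3, 0.65, seed = 12)
  expect_identical(a, b)
  # observed points appear unchanged, non-equidistant gaps are refined uniformly
  expect_equal(nrow(a), 4 + 3 * 3)
  anchor_rows <- match(obs2$t, a$t)
  expect_identical(a$value[anchor_rows], obs2$value)
  expect_equal(a$t[1:5], c(0, 0.5, 1.0, 1.5, 2.0))
})

test_that("two-point Brownian interpolation averages to the straight line", {
  obs <- time_series(c(0, 1), c(0, 4))
  n <- 5000
  acc <- matrix(0, nrow = 5, ncol = n)
  for (s in seq_len(n)) {
    acc[, s] <- interpolate_gaps(obs, 3, 0.5, seed = s)$value
  }
  m <- rowMeans(acc)
  expected <- c(0, 1, 2, 3, 4)
  se <- apply(acc, 1, sd) / sqrt(n)
  expect_true(all(abs(m - expected) <= pmax(5 * se, 1e-12)))
})
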