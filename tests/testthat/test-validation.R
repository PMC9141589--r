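test_that("the deletion split keeps a stride of n_interp + 1 and truncates", {
  sp <- subsample(time_series(0:6, rnorm(7)), 2)
  expect_identical(sp$kept, c(1L, 4L, 7L))
  expect_identical(sp$missing, c(2L, 3L, 5L, 6L))
  sp2 <- subsample(time_series(0:4, rnorm(5)), 1)
  expect_identical(sp2$kept, c(1L, 3L, 5L))
  expect_identical(sp2$missing, c(2L, 4L))
  # union covers the truncated series; every gap interior has n_interp points
  for (nI in 1:4) {
    sp3 <- subsample(time_series(0:25, rnorm(26)), nI)
    expect_setequal(c(sp3$kept, sp3$missing), seq_len(sp3$n))
    expect_true(all(diff(sp3$kept) == nI + 1))
  }
  expect_error(subsample(time_series(0:1, c(1, 2)), 1), "too short")
})

test_that("rmse matches hand arithmetic and a per-element oracle", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(0, 0), c(3, 4)), sqrt(25 / 2))
  set.seed(12)
  for (rep in 1:10) {
    a <- rnorm(20); b <- rnorm(20)
    acc <- 0
    for (i in seq_along(a)) acc <- acc + (b[i] - a[i])^2
    expect_equal(rmse(a, b), sqrt(acc / length(a)), tolerance = 1e-12)
  }
  expect_error(rmse(1:3, 1:4), "length mismatch")
  expect_error(rmse(numeric(0), numeric(0)), "empty")
})

test_that("baselines reconstruct straight lines and cubics exactly", {
  # linear midpoint
  s <- time_series(0:2, c(0, 99, 2))
  sp <- subsample(s, 1)
  expect_equal(linear_baseline(sp, s), 1.0)
  # both baselines are exact on a straight line
  line <- time_series(0:12, 2 * (0:12) - 5)
  spl <- subsample(line, 2)
  expect_equal(linear_baseline(spl, line), line$value[spl$missing])
  expect_equal(spline_baseline(spl, line), line$value[spl$missing],
               tolerance = 1e-10)
  # the not-a-knot spline reproduces a cubic polynomial
  cub <- function(x) 0.3 * x^3 - x^2 + 2 * x + 1
  s3 <- time_series(0:16, cub(0:16))
  sp3 <- subsample(s3, 3)
  expect_lt(max(abs(spline_baseline(sp3, s3) - s3$value[sp3$missing])), 1e-9)
})

test_that("the not-a-knot spline matches an independent reference implementation", {
  # reference values computed with an independent C2 not-a-knot cubic
  # spline on this fixture, frozen to 8 decimals
  x <- c(0, 1, 2.2, 3.1, 4.5, 6, 7.3)
  y <- c(0.5, -1.2, 2, 0.3, 1.7, -0.4, 2.2)
  xo <- c(0.5, 1.5, 2, 2.8, 3.9, 5.2, 6.9)
  ref <- c(-1.68107458, 0.46993705, 1.85544987, 0.88718205, 0.90618368,
           1.04391492, 0.22528700)
  expect_equal(spline_notaknot(x, y, xo), ref, tolerance = 1e-7)
  expect_error(spline_notaknot(c(0, 1, 2), c(1, 2, 3), 0.5), "n >= 4")
})

test_that("preprocessing rescales, detrends and inverts exactly", {
  s <- time_series(0:2, c(2, 4, 6))
  expect_equal(preprocess(s, rescale = TRUE)$series$value, c(0, 0.5, 1))
  # a perfect line detrends to zeros; rescaling the residual then fails
  line <- time_series(0:9, 3 + 2 * (0:9))
  det <- preprocess(line, rescale = FALSE, detrend = TRUE)
  expect_equal(det$series$value, rep(0, 10), tolerance = 1e-10)
  expect_error(preprocess(line, rescale = TRUE, detrend = TRUE), "constant")
  expect_error(preprocess(time_series(0:3, rep(1, 4)), rescale = TRUE), "constant")
  # round trip
  set.seed(30)
  r <- time_series(0:49, cumsum(rnorm(50)) + 0.3 * (0:49))
  pre <- preprocess(r, rescale = TRUE, detrend = TRUE)
  back <- invert_preprocess(pre$series, pre$transform)
  expect_equal(back$value, r$value, tolerance = 1e-12)
})

test_that("the benchmark report is internally consistent on a small run", {
  series <- lorenz_fixture(2)[1:301, ]
  cfg <- ga_config(population_size = 12, seed = 5, max_generations = 12,
                   stall_generations = 4)
  rep <- run_benchmark(series, 2, cfg)
  expect_gte(rep$below_best, 0)
  expect_lte(rep$below_best, 1)
  expect_lte(rep$population_lowest, max(rep$candidate_rmse))
  expect_equal(rep$below_best, mean(rep$candidate_rmse < rep$ga_improved))
  expect_equal(rep$n_missing, length(rep$split$missing))
  # deterministic given the seed
  rep2 <- run_benchmark(series, 2, cfg)
  expect_identical(rep$ga_improved, rep2$ga_improved)
  expect_identical(rep$candidate_rmse, rep2$candidate_rmse)
})
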