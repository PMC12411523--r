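test_that("normalize_profile centers and is idempotent", {
  expect_equal(normalize_profile(c(1, 2, 3)), c(-1, 0, 1))
  expect_equal(normalize_profile(c(-1, 0, 1)), c(-1, 0, 1))
  expect_equal(normalize_profile(c(5, 5, 5)), c(0, 0, 0))
  p <- structure(list(values = c(2, 4), angle_deg = 0, step_um = 0.01,
                      n_points = 2L), class = "intensity_profile")
  expect_equal(normalize_profile(p)$values, c(-1, 1))
})

test_that("autocorrelation matches the closed form for an alternating profile", {
  x <- rep(c(1, -1), 50)
  a <- autocorrelate(x, step_um = 0.01)
  expect_equal(a$values[1], 1)
  expect_equal(a$values[2], -0.99)
  expect_equal(a$values[3], 0.98)
  # closed form A_norm(k) = (-1)^k (N-k)/N for all lags
  k <- 0:99
  expect_equal(a$values, (-1)^k * (100 - k) / 100)
  expect_error(autocorrelate(normalize_profile(rep(2, 10)), step_um = 0.01),
               class = "mpscorr_zero_variance")
  expect_error(crosscorrelate(normalize_profile(rep(2, 10)),
                              normalize_profile(rnorm(10)), step_um = 0.01),
               class = "mpscorr_zero_variance")
})

test_that("auto- and cross-correlation agree with brute-force double loops", {
  set.seed(42)
  worst_a <- 0; worst_c <- 0
  for (i in 1:25) {
    n <- sample(8:256, 1)
    x <- normalize_profile(rnorm(n))
    y <- normalize_profile(rnorm(n))
    a <- autocorrelate(x, step_um = 0.01)
    worst_a <- max(worst_a, max(abs(a$values - bf_autocorr(x))))
    cc <- crosscorrelate(x, y, step_um = 0.01)
    worst_c <- max(worst_c, max(abs(cc$values - bf_crosscorr(x, y))))
    expect_equal(cc$lags, -(n - 1):(n - 1))
  }
  expect_lt(worst_a, 1e-12)
  expect_lt(worst_c, 1e-12)
})

test_that("cross-correlation of a profile with itself mirrors its autocorrelation", {
  set.seed(5)
  x <- normalize_profile(rnorm(64))
  a <- autocorrelate(x, step_um = 0.01)
  cc <- crosscorrelate(x, x, step_um = 0.01)
  expect_equal(cc$values[64:127], a$values)
  expect_equal(cc$values[64:1], cc$values[64:127])  # even in lag
  expect_equal(which.max(cc$values), 64L)           # peak 1 at lag 0
  expect_equal(max(cc$values), 1)
})

test_that("a delayed copy peaks at its delay; independent noise stays small", {
  set.seed(2)
  x <- rnorm(100)
  y <- c(rep(0, 5), x[1:95])
  cc <- crosscorrelate(normalize_profile(x), normalize_profile(y),
                       step_um = 0.01)
  expect_equal(abs(cc$lags[which.max(cc$values)]), 5L)

  set.seed(99)
  peak <- replicate(100, {
    u <- normalize_profile(rnorm(100))
    v <- normalize_profile(rnorm(100))
    max(abs(crosscorrelate(u, v, step_um = 0.01)$values))
  })
  expect_lt(max(peak), 0.35)  # empirical Monte-Carlo bound
})

test_that("channel swap mirrors the cross-correlogram", {
  set.seed(8)
  x <- normalize_profile(rnorm(40))
  y <- normalize_profile(rnorm(40))
  c12 <- crosscorrelate(x, y, step_um = 0.01)
  c21 <- crosscorrelate(y, x, step_um = 0.01)
  expect_equal(c12$values, rev(c21$values))
})

test_that("find_extrema locates sign changes and plateau centers", {
  dec <- list(lags = 0:9, values = 10:1 / 10)
  ex <- find_extrema(dec)
  expect_equal(nrow(ex$maxima), 0)

  # damped cosine, period 20
  k <- 0:99
  damp <- list(lags = k, values = (1 - k / 100) * cos(2 * pi * k / 20))
  ex <- find_extrema(damp)
  expect_equal(ex$maxima$lag[1:3], c(20, 40, 60))
  expect_equal(ex$minima$lag[1:3], c(10, 30, 50))

  flat <- list(lags = 0:3, values = c(0, 1, 1, 0))
  ex <- find_extrema(flat)
  expect_equal(ex$maxima$lag, 1L)
  expect_equal(nrow(ex$minima), 0)
})

test_that("autocorrelation invariants hold on random profiles", {
  set.seed(123)
  for (i in 1:200) {
    x <- normalize_profile(rnorm(sample(4:128, 1)))
    a <- autocorrelate(x, step_um = 0.01)
    expect_equal(a$values[1], 1)
    expect_true(all(abs(a$values) <= 1 + 1e-12))
  }
})

test_that("auto_features extracts period and peak-to-trough amplitude", {
  x <- normalize_profile(cos(2 * pi * (0:199) / 20))
  a <- autocorrelate(x, step_um = 0.01)  # 100 px/um
  f <- auto_features(a)
  expect_equal(f$frequency_nm, 200)
  expect_equal(f$amplitude, 1.85, tolerance = 0.02 / 1.85)

  # monotone decay: no period
  dec <- autocorrelate(normalize_profile(exp(-(0:50) / 10)), step_um = 0.01)
  f2 <- auto_features(dec)
  expect_true(is.na(f2$frequency_nm))
  expect_equal(f2$amplitude, 0)

  alt <- autocorrelate(rep(c(1, -1), 50), step_um = 0.01)
  f3 <- auto_features(alt)
  expect_equal(f3$frequency_nm, 20)  # 2 px at 100 px/um
  expect_equal(f3$amplitude, 1.97, tolerance = 0.02)
})

test_that("sinusoid frequency is recovered within one lag across periods", {
  for (T in c(10, 18, 26, 34, 40)) {
    n <- 5 * T
    x <- normalize_profile(cos(2 * pi * (0:(n - 1)) / T))
    f <- auto_features(autocorrelate(x, step_um = 0.01))
    expect_lte(abs(f$frequency_nm / 10 - T), 1)
  }
})

test_that("cross_shift picks the stronger near-zero maximum with fixed ties", {
  x <- normalize_profile(cos(2 * pi * (0:199) / 20))
  cc <- crosscorrelate(x, x, step_um = 0.01)
  expect_equal(cross_shift(cc)$shift_lag, 0L)

  y <- normalize_profile(cos(2 * pi * ((0:199) - 10) / 20))
  cc2 <- crosscorrelate(x, y, step_um = 0.01)
  expect_equal(abs(cross_shift(cc2)$shift_lag), 10L)

  # anti-phase: symmetric candidates at -10/+10, tie resolves to +10
  cc3 <- crosscorrelate(x, -x, step_um = 0.01)
  expect_equal(cross_shift(cc3)$shift_lag, 10L)
  expect_equal(cross_shift(cc3)$shift_nm, 100)

  flatc <- structure(list(lags = -3:3, values = as.numeric(7:1),
                          step_um = 0.01, sigma = c(1, 1), type = "cross"),
                     class = "correlogram")
  expect_error(cross_shift(flatc), class = "mpscorr_no_shift")
})
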