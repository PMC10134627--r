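test_that("low-pass filter passes DC and 1 Hz, rejects 20 Hz", {
  s <- const_series(0.2, 0.3, 0.9, n = 500)
  f <- lowpass_10hz(s)
  expect_lt(max(abs(f$ax - 0.2), abs(f$ay - 0.3), abs(f$az - 0.9)), 1e-6)
  # measured sine gains against the filter's own squared-magnitude response
  flt <- signal::butter(4, 10 / 25, type = "low")
  g20 <- max(abs(lowpass_10hz(sine_series(20))$ax))
  expect_lt(g20, 0.10)
  expect_equal(g20, zero_phase_gain(flt, 20, 50), tolerance = 0.15)
  g1 <- max(abs(lowpass_10hz(sine_series(1))$ax))
  expect_gt(g1, 0.99)
  expect_equal(g1, zero_phase_gain(flt, 1, 50), tolerance = 0.01)
  expect_error(lowpass_10hz(const_series(0, 1, 0, fs = 15)), "twice the cutoff")
})

test_that("euclidean_norm computes the per-sample magnitude", {
  s <- triaxial_series(c(3, 0, 1), c(4, 0, 1), c(0, 0, 1), fs = 50,
                       start_time = t0_utc)
  expect_equal(euclidean_norm(s)$values, c(5, 0, sqrt(3)))
})

test_that("norm and jerk magnitude are invariant to axis permutation and sign", {
  withr::local_seed(4)
  for (i in 1:5) {
    a <- matrix(rnorm(3 * 50), ncol = 3)
    perm <- sample(3); flip <- sample(c(-1, 1), 3, replace = TRUE)
    b <- sweep(a[, perm], 2, flip, `*`)
    s1 <- triaxial_series(a[, 1], a[, 2], a[, 3], fs = 50, start_time = t0_utc)
    s2 <- triaxial_series(b[, 1], b[, 2], b[, 3], fs = 50, start_time = t0_utc)
    expect_equal(euclidean_norm(s1)$values, euclidean_norm(s2)$values)
    expect_equal(jerk_magnitude(jerk_triaxial(s1))$values,
                 jerk_magnitude(jerk_triaxial(s2))$values)
  }
})

test_that("centered-difference jerk is exact for linear, bounded for sinusoid", {
  fs <- 50
  n <- 500
  t <- (seq_len(n) - 1) / fs
  # constant acceleration -> zero jerk
  j <- jerk_triaxial(const_series(0.3, 0.4, 0.5, n = n))
  expect_equal(max(abs(c(j$jx, j$jy, j$jz))), 0)
  expect_length(j$jx, n - 2)
  # linear ramp a = c t -> jerk exactly c
  s <- triaxial_series(2.5 * t / 10, rep(0, n), rep(0, n), fs = fs,
                       start_time = t0_utc)
  expect_equal(jerk_triaxial(s)$jx, rep(0.25, n - 2))
  # sinusoid: within the centered-difference truncation bound
  # |err| <= max|a'''| h^2 / 6
  s <- triaxial_series(sin(2 * pi * t), rep(0, n), rep(0, n), fs = fs,
                       start_time = t0_utc)
  j <- jerk_triaxial(s)$jx
  analytic <- 2 * pi * cos(2 * pi * t[2:(n - 1)])
  bound <- (2 * pi)^3 * (1 / fs)^2 / 6
  expect_lt(max(abs(j - analytic)), bound)
  expect_error(jerk_triaxial(const_series(0, 1, 0, n = 2)), "at least 3")
})

test_that("jerk of a time-reversed series is the negated reversed jerk", {
  withr::local_seed(9)
  a <- rnorm(100); b <- rnorm(100); c <- rnorm(100)
  s <- triaxial_series(a, b, c, fs = 50, start_time = t0_utc)
  r <- triaxial_series(rev(a), rev(b), rev(c), fs = 50, start_time = t0_utc)
  expect_equal(jerk_triaxial(r)$jx, -rev(jerk_triaxial(s)$jx))
  expect_equal(jerk_triaxial(r)$jy, -rev(jerk_triaxial(s)$jy))
})

test_that("elevation angle maps the gravity direction to signed elevation", {
  s <- triaxial_series(c(1, 0, 0, 1 / sqrt(2)), c(0, 1, -1, 1 / sqrt(2)),
                       c(0, 0, 0, 0), fs = 50, start_time = t0_utc)
  expect_equal(elevation_angle(s)$values, c(0, 90, -90, 45))
  # zero-norm sample flagged invalid (NA), not an error
  z <- triaxial_series(c(1, 0, 1), c(0, 0, 0), c(0, 0, 0), fs = 50,
                       start_time = t0_utc)
  expect_equal(is.na(elevation_angle(z)$values), c(FALSE, TRUE, FALSE))
})

test_that("elevation recovers prescribed angles: exact when static, <6 deg with 0.1 g dynamics", {
  withr::local_seed(21)
  alpha <- seq(-80, 80, length.out = 1000)
  s <- gravity_series(alpha)
  expect_lt(max(abs(elevation_angle(s)$values - alpha)), 0.1)
  # moderate linear acceleration perturbs the estimate by < 6 degrees
  arad <- alpha * pi / 180
  dyn <- function() {
    bp <- signal::butter(2, c(0.5, 3) / 25, type = "pass")
    x <- signal::filtfilt(bp, rnorm(length(alpha)))
    x / max(abs(x)) * 0.1
  }
  sd_ <- triaxial_series(cos(arad) + dyn(), sin(arad), dyn(), fs = 50,
                         start_time = t0_utc)
  err <- abs(elevation_angle(sd_)$values - alpha)
  expect_lt(max(err), 6)
})
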