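test_that("a well-formed CSV parses to a validated series", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "timestamp,ax,ay,az",
    "2026-01-05T10:00:00.000,0.010000,0.980000,0.050000",
    "2026-01-05T10:00:00.020,0.020000,0.970000,0.040000",
    "2026-01-05T10:00:00.040,0.030000,0.960000,0.030000",
    "2026-01-05T10:00:00.060,0.040000,0.950000,0.020000"), f)
  s <- read_recording_csv(f, fs_expected = 50)
  expect_s3_class(s, "triaxial_series")
  expect_equal(n_samples(s), 4)
  expect_equal(s$ax, c(0.01, 0.02, 0.03, 0.04))
  expect_equal(s$fs, 50)
})

test_that("malformed CSVs are rejected with descriptive errors", {
  f <- withr::local_tempfile(fileext = ".csv")
  # duplicated timestamp, named by row
  writeLines(c("timestamp,ax,ay,az",
               "2026-01-05T10:00:00.000,0,1,0",
               "2026-01-05T10:00:00.020,0,1,0",
               "2026-01-05T10:00:00.020,0,1,0",
               "2026-01-05T10:00:00.040,0,1,0"), f)
  expect_error(read_recording_csv(f, 50), "duplicated timestamp at row 3")
  # sampled at 100 Hz when 50 expected
  writeLines(c("timestamp,ax,ay,az",
               sprintf("2026-01-05T10:00:%06.3f,0,1,0", seq(0, 0.05, 0.01))), f)
  expect_error(read_recording_csv(f, 50), "deviates")
  # missing column
  writeLines(c("timestamp,ax,ay",
               "2026-01-05T10:00:00.000,0,1",
               "2026-01-05T10:00:00.020,0,1"), f)
  expect_error(read_recording_csv(f, 50), "missing column")
  # gap larger than one sample
  writeLines(c("timestamp,ax,ay,az",
               sprintf("2026-01-05T10:00:%06.3f,0,1,0",
                       c(0, 0.02, 0.04, 0.5, 0.52, 0.54, 0.56, 0.58))), f)
  expect_error(read_recording_csv(f, 50), "gap")
  # out-of-clip value
  writeLines(c("timestamp,ax,ay,az",
               "2026-01-05T10:00:00.000,0,1,0",
               "2026-01-05T10:00:00.020,9.5,1,0",
               "2026-01-05T10:00:00.040,0,1,0"), f)
  expect_error(read_recording_csv(f, 50), "clip")
})

test_that("write then read round-trips values to the printed precision", {
  withr::local_seed(11)
  s <- triaxial_series(rnorm(400, 0, 0.5), rnorm(400, 0.9, 0.1),
                       rnorm(400, 0, 0.5), fs = 50, start_time = t0_utc)
  f <- withr::local_tempfile(fileext = ".csv")
  write_recording_csv(s, f)
  r <- read_recording_csv(f, 50)
  expect_equal(r$ax, s$ax, tolerance = 1e-6)
  expect_equal(r$ay, s$ay, tolerance = 1e-6)
  expect_equal(r$az, s$az, tolerance = 1e-6)
  expect_equal(as.numeric(r$start_time), as.numeric(s$start_time),
               tolerance = 1e-3)
})

test_that("slice_days partitions samples without loss or duplication", {
  fs <- 50
  mk <- function(hours, start) {
    n <- hours * 3600 * fs
    triaxial_series(seq_len(n) / n, rep(0.5, n), rep(0, n), fs = fs,
                    start_time = as.POSIXct(start, tz = "UTC"))
  }
  # 48 h starting exactly at the boundary -> 2 slices of 24 h
  s <- mk(48 / 60, "2026-01-05 00:00:00")     # 48 min standing in for 48 h
  sl <- slice_days(s, day_boundary = "00:24:00")
  expect_length(sl, 2)
  expect_equal(vapply(sl, function(d) n_samples(d$series), numeric(1)),
               rep(24 * 60 * fs, 2))
  # 30 h starting 6 h before the boundary -> slices of 6 h and 24 h
  s <- mk(30 / 60, "2026-01-05 00:18:00")
  sl <- slice_days(s, day_boundary = "00:24:00")
  expect_length(sl, 2)
  expect_equal(n_samples(sl[[1]]$series), 6 * 60 * fs)
  expect_equal(n_samples(sl[[2]]$series), 24 * 60 * fs)
  # 1 h (no boundary crossed) -> single slice
  s <- mk(1 / 60, "2026-01-05 03:00:00")
  sl <- slice_days(s)
  expect_length(sl, 1)
  # conservation: concatenating slices reproduces the input
  s <- mk(30 / 60, "2026-01-05 00:11:00")
  sl <- slice_days(s, day_boundary = "00:24:00")
  expect_equal(unlist(lapply(sl, function(d) d$series$ax)), s$ax)
  expect_equal(vapply(sl, `[[`, numeric(1), "day_index"), seq_along(sl))
})

test_that("pair_limbs assigns roles from metadata and trims to overlap", {
  fs <- 50
  left <- const_series(0.1, 0.9, 0, n = 600, fs = fs)
  right <- const_series(0.2, 0.9, 0, n = 600, fs = fs)
  stroke <- subject_meta("s1", "stroke", dominant_side = "right",
                         affected_side = "left", fm_ue = 40)
  p <- pair_limbs(left, right, stroke)
  expect_equal(p$test$side, "left")
  expect_equal(p$reference$side, "right")
  healthy <- subject_meta("h1", "healthy", dominant_side = "right")
  p <- pair_limbs(left, right, healthy)
  expect_equal(p$test$side, "left")   # non-dominant
  # offset starts trim both to the common 10 s-shorter overlap
  late <- triaxial_series(right$ax, right$ay, right$az, fs = fs,
                          start_time = t0_utc + 10)
  p <- pair_limbs(left, late, healthy)
  expect_equal(n_samples(p$test$series), 600 - 10 * fs)
  expect_equal(n_samples(p$reference$series), n_samples(p$test$series))
  expect_error(pair_limbs(left, triaxial_series(right$ax, right$ay, right$az,
                                                fs = 25, start_time = t0_utc),
                          healthy), "fs mismatch")
  far <- triaxial_series(right$ax, right$ay, right$az, fs = fs,
                         start_time = t0_utc + 3600)
  expect_error(pair_limbs(left, far, healthy), "overlap")
})

test_that("subject metadata enforces group-dependent fields", {
  expect_error(subject_meta("x", "stroke", dominant_side = "left"),
               "affected_side")
  expect_error(subject_meta("x", "stroke", dominant_side = "left",
                            affected_side = "left", fm_ue = 80), "0, 66")
  expect_error(subject_meta("x", "healthy", dominant_side = "left",
                            fm_ue = 30), "only apply")
  m <- subject_meta("x", "healthy", dominant_side = "left")
  expect_equal(test_side(m), "right")
})
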