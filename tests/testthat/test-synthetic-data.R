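test_that("scripts validate epoch layout", {
  expect_error(activity_script(test = list(epoch_rest(0, 100),
                                           epoch_fidget(50, 100)),
                               day_length_s = 300),
               "overlapping")
  expect_error(activity_script(test = list(epoch_rest(200, 200)),
                               day_length_s = 300), "past day end")
  expect_error(epoch_functional(0, 10, amplitude_deg = 120), "\\[0, 90\\]")
  expect_error(synth_day(activity_script(
    test = list(epoch_functional(0.3, 10, repeats = 2)), day_length_s = 60)),
    "window grid")
})

test_that("identical seed and script give bit-identical recordings", {
  sc <- activity_script(test = list(epoch_functional(10, 11, repeats = 5)),
                        reference = list(epoch_armswing(30, 20)),
                        day_length_s = 60, seed = 77)
  d1 <- synth_day(sc); d2 <- synth_day(sc)
  expect_identical(d1$pair$test$series$ax, d2$pair$test$series$ax)
  expect_identical(d1$pair$reference$series$az, d2$pair$reference$series$az)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_recording_csv(d1$pair$test$series, f1)
  write_recording_csv(d2$pair$test$series, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  # a different seed changes the noise
  sc2 <- activity_script(test = list(epoch_functional(10, 11, repeats = 5)),
                         reference = list(epoch_armswing(30, 20)),
                         day_length_s = 60, seed = 78)
  expect_false(identical(synth_day(sc2)$pair$test$series$ax,
                         d1$pair$test$series$ax))
})

test_that("an all-rest day stays below the activity threshold almost everywhere", {
  sc <- activity_script(day_length_s = 300, seed = 41)
  d <- synth_day(sc)
  cfg <- actimetry_config()
  s30 <- resample_to_30hz(d$pair$test$series)
  ec <- epoch_counts(bandpass_activity(s30))
  expect_gte(mean(ec$counts <= cfg$count_threshold), 0.99)
  # and the elevation sits at the rest angle with jerk at noise level
  al <- elevation_angle(lowpass_10hz(d$pair$test$series))
  expect_lt(max(abs(al$values + 70)), 3)
  expect_equal(compute_daily_variables(d$pair)$variables$func_use30_test, 0)
})

test_that("scheduled sweeps are recovered exactly and armswing is excluded", {
  for (k in c(10, 40)) {
    sc <- activity_script(
      test = list(epoch_functional(10, k + 1, repeats = k)),
      reference = list(epoch_armswing(100, 60)),
      day_length_s = 200, seed = 50 + k)
    v <- compute_daily_variables(synth_day(sc)$pair)$variables
    expect_equal(v$func_use30_test, k)
    expect_equal(v$func_use30_ref, 0)    # armswing never functional
    expect_gt(v$uh_ref, 0)               # but it does register use
  }
})

test_that("scripted active time is recovered by use hours within 5%", {
  active_s <- 600
  sc <- activity_script(
    test = list(epoch_functional(10, 300, repeats = 100,
                                 dyn_rms_g = 0.1),
                epoch_armswing(400, 300)),
    day_length_s = 720, seed = 60)
  d <- synth_day(sc)
  expect_equal(unname(d$labels$active_s["test"]), active_s)
  v <- compute_daily_variables(d$pair)$variables
  expect_lt(abs(v$uh_test * 3600 - active_s) / active_s, 0.05)
})

test_that("cohort ratios are balanced at u = 0.5 and monotone in u", {
  # balanced cohort: every ratio near 1
  spec <- cohort_spec(n_stroke = 0, n_healthy = 3, days = 3,
                      day_length_s = 300, events_per_day = 60,
                      u_values = rep(0.5, 3), seed = 70)
  co <- synth_cohort(spec)
  res <- lapply(co, function(s) run_synth_subject(s$days, s$meta))
  summ <- dplyr::bind_rows(lapply(res, `[[`, "summary"))
  for (v in c("jr50", "func_use_ratio30", "use_hours_ratio")) {
    expect_lt(abs(median(summ[[v]]) - 1), 0.1)
  }
  # a u grid: all three estimated ratios increase with u
  ug <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  spec <- cohort_spec(n_stroke = length(ug), n_healthy = 0, days = 1,
                      day_length_s = 300, events_per_day = 40,
                      u_values = ug, seed = 71)
  co <- synth_cohort(spec)
  res <- lapply(co, function(s) run_synth_subject(s$days, s$meta))
  summ <- dplyr::bind_rows(lapply(res, `[[`, "summary"))
  expect_true(all(diff(summ$func_use_ratio30) > 0))
  expect_true(all(diff(summ$use_hours_ratio) > 0))
  expect_true(all(diff(summ$jr50) > 0))
})

test_that("the cohort CSV tree round-trips through the ingestion reader", {
  spec <- cohort_spec(n_stroke = 1, n_healthy = 0, days = 1,
                      day_length_s = 60, events_per_day = 10, seed = 73)
  co <- synth_cohort(spec)
  dir <- withr::local_tempdir()
  write_cohort_csv(co, dir)
  meta <- yaml::read_yaml(file.path(dir, "cohort.yaml"))
  expect_equal(meta$S01$group, "stroke")
  s <- read_recording_csv(file.path(dir, meta$S01$files[[1]]$left), 50)
  expect_equal(n_samples(s), n_samples(co[[1]]$days[[1]]$pair$test$series))
  expect_equal(s$ax, co[[1]]$days[[1]]$pair$test$series$ax, tolerance = 1e-6)
  labels <- yaml::read_yaml(file.path(dir, "labels.yaml"))
  expect_equal(labels$S01$u, co[[1]]$u)
})
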