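#' Scripted behavioural epochs for the synthetic generator
#'
#' Epochs describe what one limb does over a time interval of a
#' synthetic day. Outside any epoch the limb rests at the script's rest
#' angle with only sensor noise.
#'
#' * `epoch_rest`: static limb at `angle_deg`.
#' * `epoch_fidget`: static posture plus band-limited (0.5-3 Hz)
#'   movement acceleration of the given rms.
#' * `epoch_armswing`: walking-like swing of the hanging arm, elevation
#'   oscillating around `center_deg` (default -70, well outside the
#'   functional band) at `cadence_hz`, plus movement acceleration.
#' * `epoch_functional`: `repeats` reach-like sweeps, each a triangular
#'   elevation excursion of one amplitude rising from a common baseline
#'   (`center_deg - max(amplitude_deg)/2`) and returning within one
#'   0.5 s analysis window. Sweeps are aligned to the window grid
#'   (`start_s` must be a multiple of the window length) and spread from
#'   the epoch's second window on (the first window absorbs the
#'   posture transition into the epoch), so a script of K sweeps yields
#'   exactly K functional windows. Movement acceleration of rms `dyn_rms_g`
#'   persists for the whole epoch so activity counts register the epoch
#'   as active throughout.
#'
#' @param start_s Epoch start in seconds from the beginning of the day.
#' @param duration_s Epoch duration in seconds (> 0).
#' @param angle_deg,center_deg Static / central elevation in degrees.
#' @param rms_g,dyn_rms_g Movement-band acceleration rms in g.
#' @param amplitude_deg Sweep amplitude(s) in degrees, in \[0, 90\]:
#'   scalar or one value per repeat.
#' @param cadence_hz Arm-swing frequency in Hz.
#' @param movement_duration_s Duration of each sweep (default 0.4, must
#'   fit inside one window).
#' @param repeats Number of sweeps.
#' @return A list describing the epoch (class `activity_epoch`).
#' @name activity_epochs
NULL

new_epoch <- function(kind, start_s, duration_s, ...) {
  if (duration_s <= 0) stop("epoch duration must be > 0", call. = FALSE)
  if (start_s < 0) stop("epoch start must be >= 0", call. = FALSE)
  structure(list(kind = kind, start_s = start_s, duration_s = duration_s, ...),
            class = "activity_epoch")
}

#' @rdname activity_epochs
#' @export
epoch_rest <- function(start_s, duration_s, angle_deg = -70) {
  new_epoch("rest", start_s, duration_s, angle_deg = angle_deg)
}

#' @rdname activity_epochs
#' @export
epoch_fidget <- function(start_s, duration_s, rms_g = 0.02, angle_deg = -70) {
  new_epoch("fidget", start_s, duration_s, rms_g = rms_g, angle_deg = angle_deg)
}

#' @rdname activity_epochs
#' @export
epoch_armswing <- function(start_s, duration_s, center_deg = -70,
                           amplitude_deg = 15, cadence_hz = 1,
                           dyn_rms_g = 0.1) {
  stopifnot(amplitude_deg >= 0, amplitude_deg <= 90)
  new_epoch("armswing", start_s, duration_s, center_deg = center_deg,
            amplitude_deg = amplitude_deg, cadence_hz = cadence_hz,
            dyn_rms_g = dyn_rms_g)
}

#' @rdname activity_epochs
#' @export
epoch_functional <- function(start_s, duration_s, center_deg = 0,
                             amplitude_deg = 45, movement_duration_s = 0.4,
                             repeats = 1, dyn_rms_g = 0.05) {
  if (any(amplitude_deg < 0 | amplitude_deg > 90)) {
    stop("epoch_functional: amplitudes must lie in [0, 90] degrees",
         call. = FALSE)
  }
  if (!length(amplitude_deg) %in% c(1L, repeats)) {
    stop("epoch_functional: amplitude_deg must be scalar or one per repeat",
         call. = FALSE)
  }
  new_epoch("functional", start_s, duration_s, center_deg = center_deg,
            amplitude_deg = rep_len(amplitude_deg, repeats),
            movement_duration_s = movement_duration_s,
            repeats = as.integer(repeats), dyn_rms_g = dyn_rms_g)
}

#' Ground-truth activity script for one synthetic day
#'
#' Holds the scheduled epochs of both limbs, the sensor noise floor and
#' the RNG seed; this is the oracle against which recovery of the
#' pipeline's variables is tested.
#'
#' @param test,reference Lists of [activity_epochs] for the test and
#'   reference limb (non-overlapping within each limb).
#' @param day_length_s Length of the synthetic day in seconds.
#' @param noise_rms_g Gaussian sensor-noise rms in g (default 0.005).
#' @param rest_angle_deg Elevation outside any epoch (default -70,
#'   hanging arm).
#' @param seed Integer RNG seed; identical scripts give bit-identical
#'   recordings.
#' @return An object of class `activity_script`.
#' @export
activity_script <- function(test = list(), reference = list(),
                            day_length_s = 600, noise_rms_g = 0.005,
                            rest_angle_deg = -70, seed = 1L) {
  check_limb <- function(eps, limb) {
    if (!length(eps)) return(invisible())
    stopifnot(all(vapply(eps, inherits, logical(1), "activity_epoch")))
    o <- order(vapply(eps, `[[`, numeric(1), "start_s"))
    eps <- eps[o]
    s <- vapply(eps, `[[`, numeric(1), "start_s")
    e <- s + vapply(eps, `[[`, numeric(1), "duration_s")
    if (any(e > day_length_s + 1e-9)) {
      stop("activity_script: ", limb, " epoch extends past day end", call. = FALSE)
    }
    if (length(eps) > 1 && any(s[-1] < e[-length(e)] - 1e-9)) {
      stop("activity_script: overlapping epochs on the ", limb, " limb",
           call. = FALSE)
    }
    invisible()
  }
  check_limb(test, "test"); check_limb(reference, "reference")
  structure(list(test = test, reference = reference,
                 day_length_s = day_length_s, noise_rms_g = noise_rms_g,
                 rest_angle_deg = rest_angle_deg, seed = as.integer(seed)),
            class = "activity_script")
}

# Render one limb's script into elevation trajectory, movement-noise rms
# envelope and ground-truth movement labels.
render_limb <- function(epochs, n, fs, rest_angle_deg, window_s = 0.5) {
  alpha <- rep(rest_angle_deg, n)
  env <- numeric(n)
  active_s <- 0
  labels <- list()
  wlen <- as.integer(round(window_s * fs))
  for (ep in epochs) {
    i0 <- round(ep$start_s * fs) + 1L
    i1 <- min(n, round((ep$start_s + ep$duration_s) * fs))
    seg <- i0:i1
    if (ep$kind == "rest") {
      alpha[seg] <- ep$angle_deg
    } else if (ep$kind == "fidget") {
      alpha[seg] <- ep$angle_deg
      env[seg] <- ep$rms_g
    } else if (ep$kind == "armswing") {
      tt <- (seq_along(seg) - 1) / fs
      alpha[seg] <- ep$center_deg +
        ep$amplitude_deg * sin(2 * pi * ep$cadence_hz * tt)
      env[seg] <- ep$dyn_rms_g
      active_s <- active_s + ep$duration_s
    } else if (ep$kind == "functional") {
      if (abs((ep$start_s / window_s) %% 1) > 1e-9) {
        stop("functional epochs must start on the window grid", call. = FALSE)
      }
      baseline <- ep$center_deg - max(ep$amplitude_deg) / 2
      alpha[seg] <- baseline
      env[seg] <- ep$dyn_rms_g
      active_s <- active_s + ep$duration_s
      nwin <- floor(ep$duration_s / window_s)
      # the first window absorbs the smoothed rest-to-baseline transition
      stride <- (nwin - 1L) %/% ep$repeats
      if (stride < 1) {
        stop("functional epoch too short for its repeats", call. = FALSE)
      }
      md <- round(ep$movement_duration_s * fs)
      if (md > wlen) stop("movement_duration_s exceeds the window", call. = FALSE)
      half <- md %/% 2L
      tri <- c(seq(0, 1, length.out = half + 1L),
               seq(1, 0, length.out = md - half))[-(half + 1L)]
      tri <- c(tri, 0)[seq_len(md)]
      for (k in seq_len(ep$repeats)) {
        w0 <- i0 + ((k - 1L) * stride + 1L) * wlen   # first sample of the window
        idx <- w0:(w0 + md - 1L)
        alpha[idx] <- baseline + ep$amplitude_deg[k] * tri
        labels[[length(labels) + 1L]] <- tibble::tibble(
          window_start_s = (w0 - 1L) / fs,
          amplitude_deg = ep$amplitude_deg[k])
      }
    } else {
      stop("unknown epoch kind: ", ep$kind, call. = FALSE)
    }
  }
  movements <- if (length(labels)) dplyr::bind_rows(labels) else
    tibble::tibble(window_start_s = numeric(0), amplitude_deg = numeric(0))
  list(alpha = alpha, env = env, movements = movements, active_s = active_s)
}

# Band-limited (0.5-3 Hz) unit-rms movement noise, scaled by an rms
# envelope, on the x and z axes.
movement_noise <- function(n, fs, env) {
  if (all(env == 0)) return(numeric(n))
  bp <- signal::butter(2, c(0.5, 3) / (fs / 2), type = "pass")
  bn <- zero_phase(bp, rnorm(n), pad = min(n - 1L, 200L))
  bn / sd(bn) * env
}

#' Synthesize one day of bilateral wrist acceleration
#'
#' Renders an [activity_script] into a paired two-limb recording:
#' gravity rotated through the prescribed elevation trajectory
#' (`ay = sin(alpha)` g, `ax = cos(alpha)` g), plus band-limited
#' movement acceleration on the x/z axes during active epochs, plus
#' Gaussian sensor noise on all axes. Identical scripts (same seed)
#' produce bit-identical recordings.
#'
#' @param script An [activity_script].
#' @param fs Sampling rate in Hz (default 50).
#' @param subject_id Identifier stamped on the returned pair.
#' @param day_index Day tag (1-based).
#' @param start_time Absolute time of the first sample.
#' @return A list with `pair` (a `day_pair`; the test limb is the left
#'   wrist by convention) and `labels`: `movements` (tibble of limb,
#'   scheduled window start, amplitude) and `active_s` (named vector of
#'   scripted active seconds per limb).
#' @export
synth_day <- function(script, fs = 50, subject_id = "synthetic",
                      day_index = 1L,
                      start_time = as.POSIXct("2026-01-05 00:00:00", tz = "UTC")) {
  stopifnot(inherits(script, "activity_script"))
  n <- as.integer(round(script$day_length_s * fs))
  withr::with_seed(script$seed, {
    mk_limb <- function(epochs) {
      r <- render_limb(epochs, n, fs, script$rest_angle_deg)
      arad <- r$alpha * pi / 180
      dyn_x <- movement_noise(n, fs, r$env)
      dyn_z <- movement_noise(n, fs, r$env)
      s <- triaxial_series(
        ax = cos(arad) + dyn_x + rnorm(n, 0, script$noise_rms_g),
        ay = sin(arad) + rnorm(n, 0, script$noise_rms_g),
        az = dyn_z + rnorm(n, 0, script$noise_rms_g),
        fs = fs, start_time = start_time)
      list(series = s, movements = r$movements, active_s = r$active_s)
    }
    lt <- mk_limb(script$test)
    lr <- mk_limb(script$reference)
    pair <- structure(list(
      subject_id = as.character(subject_id),
      day_index = as.integer(day_index),
      test = structure(list(side = "left", role = "test",
                            series = lt$series), class = "wrist_recording"),
      reference = structure(list(side = "right", role = "reference",
                                 series = lr$series), class = "wrist_recording")
    ), class = "day_pair")
    movements <- dplyr::bind_rows(
      if (nrow(lt$movements)) tibble::tibble(limb = "test", lt$movements),
      if (nrow(lr$movements)) tibble::tibble(limb = "reference", lr$movements))
    list(pair = pair,
         labels = list(movements = movements,
                       active_s = c(test = lt$active_s,
                                    reference = lr$active_s)))
  })
}

#' Specification of a synthetic cohort
#'
#' Each subject carries a latent use-asymmetry `u` in \[0, 1\]: the
#' fraction of the day's bilateral functional movements performed by the
#' test limb. Healthy subjects draw `u` near 0.5 (balanced use); stroke
#' subjects draw `u` low, and their Fugl-Meyer score increases linearly
#' with `u` over \[27, 66\] (the moderate-to-mild range), so every use
#' ratio should decrease with impairment. The test limb's sweep
#' amplitudes also shrink as `u` falls below 0.5, reproducing the loss
#' of large-amplitude movements that makes the functional-use ratio fall
#' off with amplitude bin in paretic limbs.
#'
#' @param n_stroke,n_healthy Group sizes (defaults 19 and 11).
#' @param days Days per subject (default 7).
#' @param day_length_s Seconds of recording per synthetic day (default
#'   600; a compressed day with the same epoch structure as a full one).
#' @param events_per_day Total bilateral functional movements per day
#'   (default 60).
#' @param fs Sampling rate in Hz (default 50).
#' @param u_values Optional explicit latent `u` per subject (length
#'   `n_stroke + n_healthy`, stroke first); overrides the group draws.
#' @param seed Integer RNG seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_stroke = 19, n_healthy = 11, days = 7,
                        day_length_s = 600, events_per_day = 60, fs = 50,
                        u_values = NULL, seed = 1L) {
  if (!is.null(u_values)) {
    stopifnot(length(u_values) == n_stroke + n_healthy,
              all(u_values >= 0 & u_values <= 1))
  }
  structure(list(n_stroke = n_stroke, n_healthy = n_healthy, days = days,
                 day_length_s = day_length_s, events_per_day = events_per_day,
                 fs = fs, u_values = u_values, seed = as.integer(seed)),
            class = "cohort_spec")
}

# Map latent asymmetry u to an FM-UE score in [27, 66].
u_to_fm <- function(u) {
  as.integer(pmin(66, pmax(27, round(27 + 39 * (u - 0.05) / 0.45))))
}

# Build one subject-day script pair from the latent asymmetry.
day_script_for_u <- function(u, spec, seed) {
  L <- spec$day_length_s
  E <- spec$events_per_day
  e_test <- round(u * E)
  e_ref <- E - e_test
  amax_test <- 25 + 30 * min(1, u / 0.5)
  walk_len <- round(0.15 * L)
  walk_start <- round(0.8 * L) - walk_len / 2
  withr::with_seed(seed, {
    a_test <- if (e_test > 0) runif(e_test, 25, amax_test) else numeric(0)
    a_ref <- if (e_ref > 0) runif(e_ref, 25, 55) else numeric(0)
  })
  func_ep <- function(start, amps) {
    epoch_functional(start, duration_s = length(amps) * 1.0,
                     center_deg = 0, amplitude_deg = amps,
                     movement_duration_s = 0.4, repeats = length(amps),
                     dyn_rms_g = 0.05)
  }
  test_eps <- list(epoch_armswing(walk_start, walk_len))
  ref_eps <- list(epoch_armswing(walk_start, walk_len))
  t0 <- 10
  if (e_test > 0) test_eps <- c(test_eps, list(func_ep(t0, a_test)))
  r0 <- t0 + ceiling(e_test * 1.0) + 10
  if (e_ref > 0) ref_eps <- c(ref_eps, list(func_ep(r0, a_ref)))
  if (r0 + e_ref * 1.0 >= walk_start) {
    stop("day too short for the scripted events", call. = FALSE)
  }
  activity_script(test = test_eps, reference = ref_eps, day_length_s = L,
                  seed = seed)
}

#' Generate a synthetic bilateral-actimetry cohort
#'
#' Draws each subject's latent asymmetry `u`, builds `days` scripted
#' day pairs per subject via [synth_day], and attaches [subject_meta]
#' (stroke subjects get an FM-UE score increasing with `u`).
#' Deterministic under a fixed spec and seed.
#'
#' @param spec A [cohort_spec].
#' @return A list of subjects, each `list(meta, u, days)` where `days`
#'   is a list of `list(pair, labels)` as returned by [synth_day].
#' @export
synth_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n_all <- spec$n_stroke + spec$n_healthy
  u <- spec$u_values
  if (is.null(u)) {
    withr::with_seed(spec$seed, {
      u_stroke <- if (spec$n_stroke > 0) {
        pmin(0.45, pmax(0.08,
          seq(0.08, 0.45, length.out = spec$n_stroke) +
            rnorm(spec$n_stroke, 0, 0.015)))
      } else numeric(0)
      u_healthy <- if (spec$n_healthy > 0) runif(spec$n_healthy, 0.45, 0.55)
        else numeric(0)
    })
    u <- c(u_stroke, u_healthy)
  }
  subjects <- vector("list", n_all)
  for (i in seq_len(n_all)) {
    is_stroke <- i <= spec$n_stroke
    sid <- sprintf("%s%02d", if (is_stroke) "S" else "H",
                   if (is_stroke) i else i - spec$n_stroke)
    meta <- if (is_stroke) {
      subject_meta(sid, "stroke", dominant_side = "right",
                   affected_side = "left", fm_ue = u_to_fm(u[i]))
    } else {
      subject_meta(sid, "healthy", dominant_side = "right")
    }
    days <- vector("list", spec$days)
    for (d in seq_len(spec$days)) {
      day_seed <- (spec$seed %% 100000L) * 10000L + i * 100L + d
      script <- day_script_for_u(u[i], spec, day_seed)
      days[[d]] <- synth_day(script, fs = spec$fs, subject_id = sid,
                             day_index = d)
    }
    subjects[[i]] <- list(meta = meta, u = u[i], days = days)
  }
  subjects
}

#' Write a synthetic cohort as a CSV tree
#'
#' Writes, under `dir`, one recording CSV per subject-day-wrist in the
#' dialect [read_recording_csv] expects
#' (`<subject>/day<k>_<left|right>.csv`), a `cohort.yaml` metadata file
#' (group, sides, FM-UE, file paths) and a `labels.yaml` ground-truth
#' file (latent `u`, scripted movements and active seconds per day).
#'
#' @param cohort Output of [synth_cohort].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort_csv <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta_all <- list(); labels_all <- list()
  for (subj in cohort) {
    sid <- subj$meta$subject_id
    sdir <- file.path(dir, sid)
    dir.create(sdir, showWarnings = FALSE)
    files <- list()
    day_labels <- list()
    for (day in subj$days) {
      d <- day$pair$day_index
      # test limb is the left wrist by generator convention
      fl <- file.path(sdir, sprintf("day%d_left.csv", d))
      fr <- file.path(sdir, sprintf("day%d_right.csv", d))
      write_recording_csv(day$pair$test$series, fl)
      write_recording_csv(day$pair$reference$series, fr)
      # paths are stored relative to the tree root so the tree is
      # relocatable and byte-reproducible
      files[[length(files) + 1L]] <- list(
        day = d,
        left = file.path(sid, basename(fl)),
        right = file.path(sid, basename(fr)))
      day_labels[[length(day_labels) + 1L]] <- list(
        day = d,
        active_s = as.list(day$labels$active_s),
        movements = lapply(seq_len(nrow(day$labels$movements)), function(k)
          as.list(day$labels$movements[k, ])))
    }
    meta_all[[sid]] <- list(
      subject_id = sid, group = subj$meta$group,
      dominant_side = subj$meta$dominant_side,
      affected_side = subj$meta$affected_side,
      fm_ue = if (is.na(subj$meta$fm_ue)) NULL else subj$meta$fm_ue,
      files = files)
    labels_all[[sid]] <- list(u = subj$u, days = day_labels)
  }
  yaml::write_yaml(meta_all, file.path(dir, "cohort.yaml"))
  yaml::write_yaml(labels_all, file.path(dir, "labels.yaml"))
  invisible(dir)
}
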