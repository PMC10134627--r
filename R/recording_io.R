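#' Read a per-wrist accelerometer CSV export
#'
#' Reads one wrist's logger export: a header row `timestamp,ax,ay,az`,
#' ISO-8601 timestamps, acceleration in g. The file must be sampled on a
#' regular grid: the rate implied by the timestamps may deviate at most
#' 1% from `fs_expected`, timestamps must be strictly increasing, and
#' gaps larger than 1.5 sampling intervals are rejected rather than
#' imputed (continuous wear is assumed). Downstream computation trusts
#' the regular `fs_expected` grid; sub-millisecond timestamp jitter is
#' ignored.
#'
#' @param path CSV file path.
#' @param fs_expected Expected sampling rate in Hz (default 50).
#' @param tz Timezone used to interpret timestamps (default `"UTC"`).
#' @return A [triaxial_series].
#' @export
read_recording_csv <- function(path, fs_expected = 50, tz = "UTC") {
  if (!file.exists(path)) stop("read_recording_csv: no such file: ", path,
                               call. = FALSE)
  dt <- data.table::fread(path, colClasses = list(character = "timestamp"),
                          showProgress = FALSE)
  need <- c("timestamp", "ax", "ay", "az")
  missing_cols <- setdiff(need, names(dt))
  if (length(missing_cols)) {
    stop("read_recording_csv: missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  tt <- as.POSIXct(dt$timestamp, format = "%Y-%m-%dT%H:%M:%OS", tz = tz)
  if (anyNA(tt)) {
    stop(sprintf("read_recording_csv: unparseable timestamp at row %d",
                 which(is.na(tt))[1]), call. = FALSE)
  }
  ts <- as.numeric(tt)
  d <- diff(ts)
  if (any(d <= 0)) {
    i <- which(d <= 0)[1]
    if (abs(d[i]) < 1e-9) {
      stop(sprintf("read_recording_csv: duplicated timestamp at row %d", i + 1L),
           call. = FALSE)
    }
    stop(sprintf("read_recording_csv: non-monotone timestamp at row %d", i + 1L),
         call. = FALSE)
  }
  dt_med <- median(d)
  fs_obs <- 1 / dt_med
  if (abs(fs_obs - fs_expected) > 0.01 * fs_expected) {
    stop(sprintf(paste0("read_recording_csv: sampling rate %.3f Hz deviates ",
                        "more than 1%% from expected %g Hz"),
                 fs_obs, fs_expected), call. = FALSE)
  }
  gap <- which(d > 1.5 * dt_med)
  if (length(gap)) {
    stop(sprintf("read_recording_csv: gap of %.3f s (> 1 sample) after row %d",
                 d[gap[1]], gap[1] + 1L), call. = FALSE)
  }
  triaxial_series(dt$ax, dt$ay, dt$az, fs = fs_expected, start_time = tt[1])
}

#' Write a tri-axial series as a recording CSV
#'
#' Inverse of [read_recording_csv]: ISO-8601 timestamps with millisecond
#' precision on the regular `fs` grid and acceleration printed with 6
#' decimals, so a write/read round trip reproduces values to the printed
#' precision and identical inputs produce byte-identical files.
#'
#' @param series A [triaxial_series].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_recording_csv <- function(series, path) {
  validate_triaxial_series(series)
  n <- n_samples(series)
  t0 <- as.numeric(series$start_time)
  secs <- t0 + (seq_len(n) - 1) / series$fs
  stamp <- format(as.POSIXct(round(secs * 1000) / 1000, tz = "UTC",
                             origin = "1970-01-01"),
                  "%Y-%m-%dT%H:%M:%OS3", tz = "UTC")
  out <- data.table::data.table(
    timestamp = stamp,
    ax = sprintf("%.6f", series$ax),
    ay = sprintf("%.6f", series$ay),
    az = sprintf("%.6f", series$az)
  )
  data.table::fwrite(out, path, quote = FALSE, eol = "\n")
  invisible(path)
}

#' Subject metadata
#'
#' @param subject_id Opaque subject identifier.
#' @param group `"stroke"` or `"healthy"`.
#' @param dominant_side `"left"` or `"right"`.
#' @param affected_side Stroke-affected side (`"left"`/`"right"`);
#'   required iff `group = "stroke"`.
#' @param fm_ue Fugl-Meyer Upper Extremity score, integer in \[0, 66\];
#'   required iff `group = "stroke"`.
#' @return An object of class `subject_meta`.
#' @export
subject_meta <- function(subject_id, group = c("stroke", "healthy"),
                         dominant_side = c("right", "left"),
                         affected_side = NULL, fm_ue = NULL) {
  group <- match.arg(group)
  dominant_side <- match.arg(dominant_side)
  if (group == "stroke") {
    if (is.null(affected_side) || is.null(fm_ue)) {
      stop("subject_meta: stroke subjects need affected_side and fm_ue",
           call. = FALSE)
    }
    affected_side <- match.arg(affected_side, c("left", "right"))
    if (fm_ue < 0 || fm_ue > 66) {
      stop("subject_meta: fm_ue must be within [0, 66]", call. = FALSE)
    }
  } else {
    if (!is.null(affected_side) || !is.null(fm_ue)) {
      stop("subject_meta: affected_side/fm_ue only apply to stroke subjects",
           call. = FALSE)
    }
  }
  structure(list(subject_id = as.character(subject_id), group = group,
                 dominant_side = dominant_side, affected_side = affected_side,
                 fm_ue = if (is.null(fm_ue)) NA_integer_ else as.integer(fm_ue)),
            class = "subject_meta")
}

#' Test-limb side implied by subject metadata
#'
#' The "test" limb is the paretic limb for stroke subjects and the
#' non-dominant limb for healthy subjects; the contralateral limb is the
#' "reference" (non-paretic / dominant) limb.
#'
#' @param meta A [subject_meta].
#' @return `"left"` or `"right"`.
#' @export
test_side <- function(meta) {
  stopifnot(inherits(meta, "subject_meta"))
  if (meta$group == "stroke") meta$affected_side
  else setdiff(c("left", "right"), meta$dominant_side)
}

#' Slice a recording into calendar days
#'
#' Cuts a continuous recording at a fixed local time-of-day boundary
#' (default midnight). Slices are tagged `1..N` in time order; their
#' concatenation reproduces the input with no loss or duplication, and
#' each slice spans at most 24 h.
#'
#' @param series A [triaxial_series].
#' @param day_boundary Boundary as `"HH:MM:SS"` (default `"00:00:00"`).
#' @param tz Timezone in which the boundary is interpreted.
#' @return A list of `list(day_index, series)`.
#' @export
slice_days <- function(series, day_boundary = "00:00:00", tz = "UTC") {
  validate_triaxial_series(series)
  n <- n_samples(series)
  t0 <- as.numeric(series$start_time)
  hms <- as.numeric(strsplit(day_boundary, ":")[[1]])
  if (length(hms) != 3 || anyNA(hms)) {
    stop("slice_days: day_boundary must be 'HH:MM:SS'", call. = FALSE)
  }
  bsec <- hms[1] * 3600 + hms[2] * 60 + hms[3]
  day0 <- as.numeric(as.POSIXct(format(series$start_time, "%Y-%m-%d", tz = tz),
                                tz = tz))
  b <- day0 + bsec
  while (b <= t0 + 1e-9) b <- b + 86400
  t_end <- t0 + (n - 1) / series$fs
  cuts <- if (b > t_end) numeric(0) else seq(b, t_end, by = 86400)
  # first sample index of each new day: smallest i with time >= boundary
  idx_cuts <- ceiling((cuts - t0) * series$fs - 1e-9) + 1L
  idx_cuts <- idx_cuts[idx_cuts > 1L & idx_cuts <= n]
  starts <- c(1L, idx_cuts)
  ends <- c(idx_cuts - 1L, n)
  out <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    i <- starts[k]:ends[k]
    out[[k]] <- list(
      day_index = k,
      series = triaxial_series(series$ax[i], series$ay[i], series$az[i],
                               fs = series$fs,
                               start_time = series$start_time +
                                 (starts[k] - 1) / series$fs)
    )
  }
  out
}

#' Pair the two wrists of one subject-day
#'
#' Trims the left and right recordings to their common time span and
#' assigns limb roles from the metadata: the affected side (stroke) or
#' non-dominant side (healthy) becomes the *test* limb, the other wrist
#' the *reference* limb.
#'
#' @param left,right [triaxial_series] for the left and right wrist.
#' @param meta A [subject_meta].
#' @param day_index Integer day tag (1-based).
#' @return An object of class `day_pair` with elements `subject_id`,
#'   `day_index`, `test` and `reference` (each a `wrist_recording` with
#'   `side`, `role`, `series`).
#' @export
pair_limbs <- function(left, right, meta, day_index = 1L) {
  validate_triaxial_series(left)
  validate_triaxial_series(right)
  stopifnot(inherits(meta, "subject_meta"))
  if (left$fs != right$fs) stop("pair_limbs: fs mismatch", call. = FALSE)
  fs <- left$fs
  s1 <- as.numeric(left$start_time); s2 <- as.numeric(right$start_time)
  e1 <- s1 + (n_samples(left) - 1) / fs
  e2 <- s2 + (n_samples(right) - 1) / fs
  t_start <- max(s1, s2); t_end <- min(e1, e2)
  if (t_end - t_start <= 1 / fs) stop("pair_limbs: recordings do not overlap",
                                      call. = FALSE)
  if (t_end - t_start > 86400 + 1 / fs) {
    stop("pair_limbs: common span exceeds 24 h; slice into days first",
         call. = FALSE)
  }
  trim <- function(s, s0) {
    i0 <- round((t_start - s0) * fs) + 1L
    i1 <- round((t_end - s0) * fs) + 1L
    triaxial_series(s$ax[i0:i1], s$ay[i0:i1], s$az[i0:i1], fs = fs,
                    start_time = as.POSIXct(t_start, tz = "UTC",
                                            origin = "1970-01-01"))
  }
  lt <- trim(left, s1); rt <- trim(right, s2)
  n <- min(n_samples(lt), n_samples(rt))
  cut <- function(s) triaxial_series(s$ax[1:n], s$ay[1:n], s$az[1:n],
                                     fs = fs, start_time = s$start_time)
  lt <- cut(lt); rt <- cut(rt)
  tside <- test_side(meta)
  mk <- function(side, series, role) {
    structure(list(side = side, role = role, series = series),
              class = "wrist_recording")
  }
  test <- if (tside == "left") mk("left", lt, "test") else mk("right", rt, "test")
  ref  <- if (tside == "left") mk("right", rt, "reference") else mk("left", lt, "reference")
  structure(list(subject_id = meta$subject_id,
                 day_index = as.integer(day_index),
                 test = test, reference = ref),
            class = "day_pair")
}

#' @export
print.day_pair <- function(x, ...) {
  cat(sprintf("<day_pair> subject %s day %d: test=%s wrist, reference=%s wrist, %d samples @ %g Hz\n",
              x$subject_id, x$day_index, x$test$side, x$reference$side,
              n_samples(x$test$series), x$test$series$fs))
  invisible(x)
}
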