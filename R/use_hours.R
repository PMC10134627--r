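# Rational polyphase resampling: zero-stuff by p, low-pass with a
# linear-phase FIR (odd length, so the group delay is an integer number
# of upsampled samples), decimate by q. Odd-reflection padding keeps the
# FIR transient away from real samples; fftfilt keeps it fast on long
# days.
resample_pq <- function(x, p, q, taps_per_phase = 32L) {
  n <- length(x)
  if (p == q) return(x)
  pad <- min((n - 1L) %/% q * q, 40L * q)
  if (pad < q) stop("resample_pq: series too short to resample", call. = FALSE)
  xe <- c(2 * x[1] - x[(pad + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - pad)])
  up <- numeric(length(xe) * p)
  up[seq(1L, length(up), by = p)] <- xe * p
  ntaps <- 2L * taps_per_phase * max(p, q) + 1L
  h <- signal::fir1(ntaps - 1L, 1 / max(p, q), type = "low")
  yf <- signal::fftfilt(h, c(up, numeric(ntaps)))
  gd <- (ntaps - 1L) %/% 2L
  yup <- yf[(gd + 1L):(gd + length(up))]
  y <- yup[seq(1L, length(yup), by = q)]
  k <- pad * p / q
  y[(k + 1L):(k + ceiling(n * p / q))]
}

#' Resample a recording to 30 Hz
#'
#' Anti-aliased rational resampling of each axis to the activity-count
#' rate. For the native 50 Hz recordings this is up-3 / down-5 polyphase
#' resampling (a non-integer factor, so plain decimation does not apply);
#' any source rate with a rational ratio to the target is supported. The
#' duration is preserved within one sample and DC is passed within 1e-3 g.
#'
#' @param series A [triaxial_series] with integer-valued `fs`.
#' @param target_fs Target rate in Hz (default 30).
#' @return A [triaxial_series] at `target_fs`.
#' @export
resample_to_30hz <- function(series, target_fs = 30) {
  validate_triaxial_series(series)
  fs <- series$fs
  if (abs(fs - round(fs)) > 1e-9 || abs(target_fs - round(target_fs)) > 1e-9) {
    stop("resample_to_30hz: only integer source/target rates are supported",
         call. = FALSE)
  }
  fs <- as.integer(round(fs)); tfs <- as.integer(round(target_fs))
  g <- function(a, b) if (b == 0) a else g(b, a %% b)
  d <- g(fs, tfs)
  p <- tfs %/% d; q <- fs %/% d
  triaxial_series(resample_pq(series$ax, p, q),
                  resample_pq(series$ay, p, q),
                  resample_pq(series$az, p, q),
                  fs = target_fs, start_time = series$start_time)
}

#' Band-pass filter for activity counting
#'
#' Per-axis zero-phase Butterworth band-pass (default 0.25-2.5 Hz,
#' 4th order) applied to the 30 Hz signal. Removes gravity (DC) and
#' sensor noise outside the human-movement band before quantization to
#' activity counts.
#'
#' @param series A [triaxial_series] (normally at 30 Hz).
#' @param band_hz Length-2 pass band in Hz (default `c(0.25, 2.5)`).
#' @param order Butterworth order (default 4).
#' @return A filtered [triaxial_series].
#' @export
bandpass_activity <- function(series, band_hz = c(0.25, 2.5), order = 4) {
  validate_triaxial_series(series)
  if (series$fs <= 2 * band_hz[2]) {
    stop("bandpass_activity: fs must exceed twice the upper band edge",
         call. = FALSE)
  }
  bp <- signal::butter(order, band_hz / (series$fs / 2), type = "pass")
  # the 0.25 Hz edge settles slowly: pad 20 s worth of samples
  pad <- as.integer(ceiling(20 * series$fs))
  triaxial_series(zero_phase(bp, series$ax, pad),
                  zero_phase(bp, series$ay, pad),
                  zero_phase(bp, series$az, pad),
                  fs = series$fs, start_time = series$start_time)
}

#' Activity counts on 1 s epochs
#'
#' Quantizes the band-passed signal to activity counts at
#' `count_resolution_g` g per count on non-overlapping `epoch_s` windows:
#' per axis, the rectified mean of the epoch's samples divided by the
#' resolution; the epoch count is the vector magnitude across the three
#' axes (the convention of the accelerometer-count lineage the 0.001664
#' g/count constant comes from). Counts are real-valued; no flooring is
#' applied.
#'
#' @param filtered A band-passed [triaxial_series] (normally 30 Hz).
#' @param epoch_s Epoch length in seconds (default 1).
#' @param count_resolution_g Count resolution in g (default 0.001664).
#' @param axis_combine `"vector"` (Euclidean across axes, default) or
#'   `"sum"`.
#' @return An object of class `epoch_counts` with `counts` and `epoch_s`.
#' @export
epoch_counts <- function(filtered, epoch_s = 1,
                         count_resolution_g = 0.001664,
                         axis_combine = c("vector", "sum")) {
  validate_triaxial_series(filtered)
  axis_combine <- match.arg(axis_combine)
  spe <- epoch_s * filtered$fs
  if (abs(spe - round(spe)) > 1e-9 || spe < 1) {
    stop("epoch_counts: epoch_s * fs must be a positive integer", call. = FALSE)
  }
  spe <- as.integer(round(spe))
  nep <- n_samples(filtered) %/% spe
  if (nep == 0) stop("epoch_counts: series shorter than one epoch", call. = FALSE)
  per_axis <- function(a) {
    m <- matrix(abs(a[seq_len(nep * spe)]), nrow = spe)
    colMeans(m) / count_resolution_g
  }
  cx <- per_axis(filtered$ax); cy <- per_axis(filtered$ay); cz <- per_axis(filtered$az)
  counts <- if (axis_combine == "vector") sqrt(cx^2 + cy^2 + cz^2) else cx + cy + cz
  structure(list(counts = counts, epoch_s = epoch_s), class = "epoch_counts")
}

#' Daily use hours from epoch counts
#'
#' Total time, in hours, in which the limb is considered active: the
#' number of epochs whose activity count strictly exceeds the threshold,
#' times the epoch length.
#'
#' @param counts An `epoch_counts` from [epoch_counts].
#' @param threshold Count threshold; an epoch is active when
#'   `count > threshold` (strictly greater; default 2).
#' @return Hours of use, in \[0, 24\] for a day.
#' @export
use_hours <- function(counts, threshold = 2) {
  stopifnot(inherits(counts, "epoch_counts"))
  sum(counts$counts > threshold) * counts$epoch_s / 3600
}

#' Use-hours ratio
#'
#' Test-limb over reference-limb use hours (paretic/non-paretic or
#' non-dominant/dominant). Undefined (`NA`) when the reference limb has
#' zero use hours.
#'
#' @param uh_test,uh_ref Use hours (>= 0).
#' @return `uh_test / uh_ref`, or `NA` when `uh_ref == 0`.
#' @export
use_hours_ratio <- function(uh_test, uh_ref) {
  stopifnot(uh_test >= 0, uh_ref >= 0)
  if (uh_ref == 0) NA_real_ else uh_test / uh_ref
}
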