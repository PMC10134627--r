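# Zero-phase IIR filtering with odd-reflection padding. signal::filtfilt
# alone leaves large transients at the edges because it starts the filter
# from zero state; reflecting the signal (scipy-style, odd symmetry about
# the end points) lets the filter settle before it reaches real samples.
zero_phase <- function(flt, x, pad) {
  n <- length(x)
  pad <- min(as.integer(pad), n - 1L)
  if (pad < 1L) stop("zero_phase: series too short to filter", call. = FALSE)
  pre <- 2 * x[1] - x[(pad + 1L):2L]
  post <- 2 * x[n] - x[(n - 1L):(n - pad)]
  y <- signal::filtfilt(flt, c(pre, x, post))
  y[(pad + 1L):(pad + n)]
}

#' Low-pass filter a tri-axial series
#'
#' Per-axis zero-phase low-pass used to remove sensor noise before any
#' kinematic computation. Realized as a 4th-order Butterworth applied
#' forward-backward (zero phase preserves the timing of movement onsets
#' that the 0.5 s functional-use windows rely on), with odd-reflection
#' padding so constant signals pass unchanged.
#'
#' @param series A [triaxial_series] with `fs > 2 * cutoff_hz`.
#' @param cutoff_hz Cut-off frequency in Hz (default 10).
#' @param order Butterworth order of the underlying one-pass filter
#'   (default 4).
#' @return A filtered [triaxial_series] of identical length.
#' @export
lowpass_10hz <- function(series, cutoff_hz = 10, order = 4) {
  validate_triaxial_series(series)
  if (series$fs <= 2 * cutoff_hz) {
    stop("lowpass_10hz: fs must exceed twice the cutoff", call. = FALSE)
  }
  bf <- signal::butter(order, cutoff_hz / (series$fs / 2), type = "low")
  pad <- max(100L, 10L * order)
  triaxial_series(zero_phase(bf, series$ax, pad),
                  zero_phase(bf, series$ay, pad),
                  zero_phase(bf, series$az, pad),
                  fs = series$fs, start_time = series$start_time)
}

#' Euclidean norm of acceleration
#'
#' Per-sample magnitude of the acceleration vector,
#' `EN(t) = sqrt(ax^2 + ay^2 + az^2)`, in g.
#'
#' @param series A [triaxial_series].
#' @return A [scalar_series] of kind `"en_g"`.
#' @export
euclidean_norm <- function(series) {
  validate_triaxial_series(series)
  scalar_series(sqrt(series$ax^2 + series$ay^2 + series$az^2),
                fs = series$fs, kind = "en_g")
}

#' Tri-axial jerk by centered finite differences
#'
#' `J_i(t) = (a_i(t + dt) - a_i(t - dt)) / (2 dt)` per axis, in g/s, with
#' `dt = 1/fs`. The first and last samples have no centered difference
#' and are dropped (output is 2 samples shorter), so paired-limb jerk
#' series computed from time-aligned inputs share the same interior grid.
#'
#' @param series A [triaxial_series] with at least 3 samples.
#' @return An object of class `jerk_triaxial` with `jx`, `jy`, `jz`, `fs`.
#' @export
jerk_triaxial <- function(series) {
  validate_triaxial_series(series)
  n <- n_samples(series)
  if (n < 3) stop("jerk_triaxial: need at least 3 samples", call. = FALSE)
  d <- function(a) (a[3:n] - a[1:(n - 2)]) * series$fs / 2
  structure(list(jx = d(series$ax), jy = d(series$ay), jz = d(series$az),
                 fs = series$fs),
            class = "jerk_triaxial")
}

#' Jerk magnitude
#'
#' Per-sample `sqrt(jx^2 + jy^2 + jz^2)`, in g/s.
#'
#' @param j A `jerk_triaxial` from [jerk_triaxial].
#' @return A [scalar_series] of kind `"jerk_mag_g_per_s"`.
#' @export
jerk_magnitude <- function(j) {
  stopifnot(inherits(j, "jerk_triaxial"))
  scalar_series(sqrt(j$jx^2 + j$jy^2 + j$jz^2),
                fs = j$fs, kind = "jerk_mag_g_per_s")
}

#' Forearm elevation angle from gravity
#'
#' Signed elevation of the forearm axis relative to the horizontal,
#' derived from the gravity direction in the acceleration vector:
#' `alpha(t) = 90 - acos(ay(t) / EN(t))` in degrees, so `ay = 0` maps to
#' horizontal (0 deg), `ay = +EN` to +90 deg (hand up) and `ay = -EN` to
#' -90 deg (hand down). The arccos argument is clamped to \[-1, 1\] to
#' absorb rounding. Samples with `EN = 0` have no defined direction and
#' are returned as `NA` (flagged invalid; downstream windows containing
#' them are discarded).
#'
#' In quasi-static epochs this recovers the true elevation to numerical
#' precision; with moderate linear acceleration (<= 0.1 g) the error
#' stays within a few degrees.
#'
#' @param series A [triaxial_series] (normally low-pass filtered first).
#' @return A [scalar_series] of kind `"elevation_deg"`.
#' @export
elevation_angle <- function(series) {
  validate_triaxial_series(series)
  en <- sqrt(series$ax^2 + series$ay^2 + series$az^2)
  alpha <- rep(NA_real_, length(en))
  ok <- en > 0
  arg <- pmin(1, pmax(-1, series$ay[ok] / en[ok]))
  alpha[ok] <- 90 - acos(arg) * 180 / pi
  scalar_series(alpha, fs = series$fs, kind = "elevation_deg")
}
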