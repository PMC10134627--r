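#' Tri-axial acceleration series
#'
#' Container for one wrist's tri-axial accelerometer signal on a regular
#' sampling grid. Values are in g; the sensor clip range is +/- 8 g.
#' Timestamps are represented by `start_time` plus the sample index over
#' a trusted regular grid of rate `fs` (small timestamp jitter in source
#' files is ignored downstream).
#'
#' @param ax,ay,az Numeric vectors of equal length (acceleration in g).
#'   `ay` is the axis along the forearm (towards the hand), so that at
#'   elevation angle alpha the gravity component on `ay` is `sin(alpha)` g.
#' @param fs Sampling rate in Hz (> 0).
#' @param start_time Absolute time of the first sample (`POSIXct`).
#' @return An object of class `triaxial_series`.
#' @examples
#' s <- triaxial_series(ax = c(0, 0, 0), ay = c(1, 1, 1), az = c(0, 0, 0),
#'                      fs = 50)
#' n_samples(s)
#' @export
triaxial_series <- function(ax, ay, az, fs,
                            start_time = as.POSIXct("2026-01-05 00:00:00",
                                                    tz = "UTC")) {
  x <- structure(
    list(ax = as.numeric(ax), ay = as.numeric(ay), az = as.numeric(az),
         fs = as.numeric(fs), start_time = start_time),
    class = "triaxial_series"
  )
  validate_triaxial_series(x)
}

validate_triaxial_series <- function(x, clip_g = 8) {
  stopifnot(inherits(x, "triaxial_series"))
  n <- length(x$ax)
  if (length(x$ay) != n || length(x$az) != n) {
    stop("triaxial_series: ax, ay, az must have identical length", call. = FALSE)
  }
  if (n < 2) stop("triaxial_series: need at least 2 samples", call. = FALSE)
  if (!is.finite(x$fs) || x$fs <= 0) {
    stop("triaxial_series: fs must be a positive number", call. = FALSE)
  }
  vals <- c(x$ax, x$ay, x$az)
  if (!all(is.finite(vals))) {
    stop("triaxial_series: non-finite acceleration value", call. = FALSE)
  }
  bad <- which(abs(x$ax) > clip_g | abs(x$ay) > clip_g | abs(x$az) > clip_g)
  if (length(bad)) {
    stop(sprintf("triaxial_series: |acceleration| > %g g (clip range) at sample %d",
                 clip_g, bad[1]), call. = FALSE)
  }
  if (!inherits(x$start_time, "POSIXct")) {
    stop("triaxial_series: start_time must be POSIXct", call. = FALSE)
  }
  x
}

#' Number of samples in a series
#' @param x A `triaxial_series` or `scalar_series`.
#' @return Integer sample count.
#' @export
n_samples <- function(x) {
  if (inherits(x, "triaxial_series")) return(length(x$ax))
  if (inherits(x, "scalar_series")) return(length(x$values))
  stop("n_samples: unsupported type", call. = FALSE)
}

#' Duration of a series in seconds
#' @param x A `triaxial_series` or `scalar_series`.
#' @return Duration in seconds (`n / fs`).
#' @export
duration_s <- function(x) n_samples(x) / x$fs

#' @export
print.triaxial_series <- function(x, ...) {
  cat(sprintf("<triaxial_series> %d samples @ %g Hz (%.1f s) from %s\n",
              n_samples(x), x$fs, duration_s(x),
              format(x$start_time, "%Y-%m-%d %H:%M:%OS3", tz = "UTC")))
  invisible(x)
}

#' Scalar per-sample series
#'
#' Derived one-dimensional signal on the same regular grid as its source
#' series: the Euclidean norm of acceleration (`en_g`, >= 0), the jerk
#' magnitude (`jerk_mag_g_per_s`, >= 0) or the signed forearm elevation
#' angle (`elevation_deg`, in \[-90, 90\], `NA` where undefined).
#'
#' @param values Numeric vector.
#' @param fs Sampling rate in Hz.
#' @param kind One of `"en_g"`, `"jerk_mag_g_per_s"`, `"elevation_deg"`.
#' @return An object of class `scalar_series`.
#' @export
scalar_series <- function(values, fs,
                          kind = c("en_g", "jerk_mag_g_per_s", "elevation_deg")) {
  kind <- match.arg(kind)
  values <- as.numeric(values)
  if (!is.finite(fs) || fs <= 0) stop("scalar_series: fs must be > 0", call. = FALSE)
  ok <- is.finite(values)
  if (kind != "elevation_deg" && !all(ok)) {
    stop("scalar_series: non-finite value", call. = FALSE)
  }
  if (kind %in% c("en_g", "jerk_mag_g_per_s") && any(values[ok] < 0)) {
    stop("scalar_series: ", kind, " must be non-negative", call. = FALSE)
  }
  if (kind == "elevation_deg" &&
      any(values[ok] < -90 - 1e-9 | values[ok] > 90 + 1e-9)) {
    stop("scalar_series: elevation outside [-90, 90] degrees", call. = FALSE)
  }
  structure(list(values = values, fs = as.numeric(fs), kind = kind),
            class = "scalar_series")
}

#' @export
print.scalar_series <- function(x, ...) {
  cat(sprintf("<scalar_series:%s> %d samples @ %g Hz\n",
              x$kind, length(x$values), x$fs))
  invisible(x)
}
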