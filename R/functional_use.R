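#' Partition an elevation-angle series into 0.5 s windows
#'
#' Tiles the day into consecutive, non-overlapping windows of
#' `window_s` seconds (`round(window_s * fs)` samples each); a trailing
#' remainder shorter than one window is discarded.
#'
#' @param alpha A [scalar_series] of kind `"elevation_deg"`.
#' @param window_s Window length in seconds (default 0.5; `window_s * fs`
#'   must be a positive integer).
#' @return An object of class `angle_windows`: a samples-by-windows
#'   matrix `m` plus `window_s` and `fs`.
#' @export
partition_windows <- function(alpha, window_s = 0.5) {
  stopifnot(inherits(alpha, "scalar_series"), alpha$kind == "elevation_deg")
  wlen <- window_s * alpha$fs
  if (abs(wlen - round(wlen)) > 1e-9 || wlen < 1) {
    stop("partition_windows: window_s * fs must be a positive integer",
         call. = FALSE)
  }
  wlen <- as.integer(round(wlen))
  n <- length(alpha$values)
  if (n == 0) stop("partition_windows: empty series", call. = FALSE)
  nwin <- n %/% wlen
  m <- if (nwin > 0) {
    matrix(alpha$values[seq_len(nwin * wlen)], nrow = wlen)
  } else {
    matrix(numeric(0), nrow = wlen)
  }
  structure(list(m = m, window_s = window_s, fs = alpha$fs),
            class = "angle_windows")
}

# Per-window max, min and all-inside-band flags, vectorized over the
# window matrix. Windows containing any invalid (NA) sample are flagged
# invalid and never functional.
window_stats <- function(w, horiz_limit_deg = 30) {
  m <- w$m
  nwin <- ncol(m)
  if (nwin == 0) {
    return(list(range = numeric(0), inband = logical(0), valid = logical(0)))
  }
  valid <- colSums(is.na(m)) == 0
  rows <- lapply(seq_len(nrow(m)), function(i) m[i, ])
  wmax <- do.call(pmax, c(rows, list(na.rm = FALSE)))
  wmin <- do.call(pmin, c(rows, list(na.rm = FALSE)))
  inband <- colSums(abs(m) <= horiz_limit_deg) == nrow(m)
  inband[is.na(inband)] <- FALSE
  rng <- wmax - wmin
  rng[!valid] <- NA_real_
  list(range = rng, inband = inband & valid, valid = valid)
}

#' Is one elevation window a functional movement?
#'
#' A window is functional when every sample lies within
#' `+/- horiz_limit_deg` of the horizontal (to exclude walking with the
#' arm hanging) and the in-window range of motion
#' `max(alpha) - min(alpha)` is at least `rom_min_deg`. The horizontal
#' condition is enforced on every sample, the strictest consistent
#' reading. A window containing invalid (NA) samples is never functional.
#'
#' @param w Numeric vector of elevation samples (degrees) for one window.
#' @param horiz_limit_deg Half-width of the horizontal band (default 30).
#' @param rom_min_deg Minimum range of motion in degrees (default 30).
#' @return `TRUE` or `FALSE`.
#' @export
window_is_functional <- function(w, horiz_limit_deg = 30, rom_min_deg = 30) {
  if (anyNA(w)) return(FALSE)
  all(abs(w) <= horiz_limit_deg) && (max(w) - min(w)) >= rom_min_deg
}

#' Count functional movements in a day (FuncUse)
#'
#' Number of non-overlapping `window_s` windows classified functional by
#' [window_is_functional]. With the defaults (30/30) this is the daily
#' FuncUse30 count for one limb.
#'
#' @param alpha A [scalar_series] of kind `"elevation_deg"`.
#' @param window_s Window length in seconds (default 0.5).
#' @param horiz_limit_deg Horizontal band half-width (default 30).
#' @param rom_min_deg Minimum in-window range of motion (default 30).
#' @return Non-negative integer count.
#' @export
count_functional <- function(alpha, window_s = 0.5, horiz_limit_deg = 30,
                             rom_min_deg = 30) {
  w <- partition_windows(alpha, window_s)
  st <- window_stats(w, horiz_limit_deg)
  sum(st$inband & !is.na(st$range) & st$range >= rom_min_deg)
}

#' Amplitude-binned functional-use profile
#'
#' Counts, per limb and per 10-degree amplitude bin
#' `[0-10) ... [80-90)`, the windows whose in-window elevation range
#' falls in the bin and (by default) whose samples all lie within the
#' horizontal band. Under the band constraint the range cannot exceed
#' twice the band half-width, so bins at and above \[60-70) are
#' structurally empty with the default 30-degree band; pass
#' `apply_band = FALSE` to profile amplitudes without the band.
#'
#' @param alpha_test,alpha_ref Elevation [scalar_series] for the two limbs.
#' @param bin_edges_deg Increasing bin edges in degrees
#'   (default `seq(0, 90, 10)`).
#' @param window_s,horiz_limit_deg As in [count_functional].
#' @param apply_band Keep the horizontal-band condition (default `TRUE`).
#' @return A tibble with `bin_low`, `bin_high`, `count_test`,
#'   `count_ref`, `ratio` (`NA` where the reference count is 0).
#' @export
amplitude_profile <- function(alpha_test, alpha_ref,
                              bin_edges_deg = seq(0, 90, 10),
                              window_s = 0.5, horiz_limit_deg = 30,
                              apply_band = TRUE) {
  count_bins <- function(alpha) {
    w <- partition_windows(alpha, window_s)
    st <- window_stats(w, horiz_limit_deg)
    keep <- if (apply_band) st$inband else st$valid
    r <- st$range[keep]
    nb <- length(bin_edges_deg) - 1L
    idx <- findInterval(r, bin_edges_deg, rightmost.closed = FALSE)
    tabulate(idx[idx >= 1 & idx <= nb], nbins = nb)
  }
  ct <- count_bins(alpha_test)
  cr <- count_bins(alpha_ref)
  tibble::tibble(
    bin_low = head(bin_edges_deg, -1),
    bin_high = tail(bin_edges_deg, -1),
    count_test = ct,
    count_ref = cr,
    ratio = ifelse(cr > 0, ct / cr, NA_real_)
  )
}

#' Functional-use ratio
#'
#' Test-limb over reference-limb functional-movement count
#' (paretic/non-paretic, or non-dominant/dominant). Undefined (`NA`)
#' when the reference count is 0; that is a reportable value, not an
#' error.
#'
#' @param test_count,ref_count Non-negative integer daily counts.
#' @return `test_count / ref_count`, or `NA` when `ref_count == 0`.
#' @export
func_use_ratio <- function(test_count, ref_count) {
  stopifnot(test_count >= 0, ref_count >= 0)
  if (ref_count == 0) NA_real_ else test_count / ref_count
}
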