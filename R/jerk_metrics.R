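#' Per-sample jerk ratio of the two limbs
#'
#' `JR(t) = 2 |J_test(t)| / (|J_test(t)| + |J_ref(t)|)`, in \[0, 2\]:
#' 1 means an equal instantaneous contribution from both upper limbs,
#' 2 means pure test-limb (paretic / non-dominant) movement, 0 pure
#' reference-limb (non-paretic / dominant) movement. Samples where both
#' jerk magnitudes are zero carry no information and are excluded (their
#' number is reported as `n_excluded`); samples where exactly one limb's
#' jerk is zero are kept, producing the spikes at 0 and 2.
#'
#' @param test_mag,ref_mag Time-aligned [scalar_series] of kind
#'   `"jerk_mag_g_per_s"` for the test and reference limb.
#' @return An object of class `jr_series` with `values` (in \[0, 2\]) and
#'   `n_excluded`.
#' @export
jr_series <- function(test_mag, ref_mag) {
  stopifnot(inherits(test_mag, "scalar_series"),
            inherits(ref_mag, "scalar_series"))
  if (test_mag$kind != "jerk_mag_g_per_s" || ref_mag$kind != "jerk_mag_g_per_s") {
    stop("jr_series: inputs must be jerk-magnitude series", call. = FALSE)
  }
  a <- test_mag$values; b <- ref_mag$values
  if (length(a) != length(b)) stop("jr_series: length mismatch", call. = FALSE)
  if (test_mag$fs != ref_mag$fs) stop("jr_series: fs mismatch", call. = FALSE)
  denom <- a + b
  keep <- denom > 0
  structure(list(values = 2 * a[keep] / denom[keep],
                 n_excluded = sum(!keep)),
            class = "jr_series")
}

#' Normalized jerk-ratio density
#'
#' Histogram of the jerk-ratio samples over \[0, 2\], scaled so that the
#' integral (sum of density times bin width) equals 2. The bin grid is
#' symmetric about 1 (`1 / bin_width` must be an integer); samples exactly
#' equal to 1 sit on a bin edge and are split half/half between the bins
#' below and above, so identical bilateral signals yield JR50 = 1 rather
#' than 0 or 2.
#'
#' @param jr A `jr_series` from [jr_series] (non-empty).
#' @param bin_width Bin width over \[0, 2\]; default 0.02 (100 bins).
#' @return An object of class `jr_density` with `bin_edges`, `density`
#'   and the retained sample count `n`.
#' @export
jr_density <- function(jr, bin_width = 0.02) {
  stopifnot(inherits(jr, "jr_series"))
  v <- jr$values
  if (!length(v)) stop("jr_density: no samples after exclusion", call. = FALSE)
  nb <- round(2 / bin_width)
  if (abs(nb * bin_width - 2) > 1e-9 || nb %% 2 != 0) {
    stop("jr_density: bin_width must evenly divide [0,1] and [1,2]",
         call. = FALSE)
  }
  edges <- seq(0, 2, length.out = nb + 1)
  at_one <- abs(v - 1) < 1e-12
  idx <- pmin(floor(v[!at_one] / bin_width) + 1L, nb)
  counts <- tabulate(idx, nbins = nb)
  n1 <- sum(at_one)
  half <- nb %/% 2L
  counts <- as.numeric(counts)
  if (n1 > 0) {
    counts[half] <- counts[half] + n1 / 2
    counts[half + 1L] <- counts[half + 1L] + n1 / 2
  }
  dens <- counts / (length(v) * bin_width) * 2
  structure(list(bin_edges = edges, density = dens, n = length(v)),
            class = "jr_density")
}

#' JR50: jerk-ratio mass on the test-limb side
#'
#' Area under the normalized jerk-ratio density over \[1, 2\], in
#' \[0, 2\]. Values above 1 indicate preponderant use of the test
#' (paretic / non-dominant) limb, below 1 preponderant use of the
#' reference (non-paretic / dominant) limb; 1 is balanced use.
#'
#' @param density A `jr_density` from [jr_density].
#' @return JR50, a number in \[0, 2\].
#' @export
jr50 <- function(density) {
  stopifnot(inherits(density, "jr_density"))
  w <- diff(density$bin_edges)
  upper <- density$bin_edges[-length(density$bin_edges)] >= 1 - 1e-12
  sum(density$density[upper] * w[upper])
}

#' Jerk-ratio density as a two-column table
#'
#' @param density A `jr_density`.
#' @return A tibble with `bin_center` and `density`, suitable for CSV
#'   export or plotting.
#' @export
jr_density_table <- function(density) {
  stopifnot(inherits(density, "jr_density"))
  e <- density$bin_edges
  tibble::tibble(bin_center = (head(e, -1) + tail(e, -1)) / 2,
                 density = density$density)
}
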