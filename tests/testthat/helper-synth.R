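# Builders and independent oracles shared across the suite.

t0_utc <- as.POSIXct("2026-01-05 00:00:00", tz = "UTC")

# constant-acceleration series
const_series <- function(ax, ay, az, n = 200, fs = 50) {
  triaxial_series(rep(ax, n), rep(ay, n), rep(az, n), fs = fs,
                  start_time = t0_utc)
}

# single-tone series on one axis, others at a DC offset
sine_series <- function(freq_hz, dur_s = 10, fs = 50, amp = 1) {
  t <- seq(0, dur_s, by = 1 / fs)
  triaxial_series(amp * sin(2 * pi * freq_hz * t), rep(0, length(t)),
                  rep(0, length(t)), fs = fs, start_time = t0_utc)
}

# wrap raw values as a jerk-magnitude scalar series
jerk_mag_series <- function(values, fs = 50) {
  scalar_series(values, fs = fs, kind = "jerk_mag_g_per_s")
}

# elevation series straight from a prescribed angle trajectory (pure
# gravity, no noise)
gravity_series <- function(alpha_deg, fs = 50) {
  a <- alpha_deg * pi / 180
  triaxial_series(cos(a), sin(a), rep(0, length(a)), fs = fs,
                  start_time = t0_utc)
}

# squared-magnitude response of a zero-phase (forward-backward) digital
# filter at frequency f_hz -- the closed-form oracle for measured sine
# gains
zero_phase_gain <- function(flt, f_hz, fs) {
  w <- 2 * pi * f_hz / fs
  ev <- function(p) sum(p * exp(-1i * w * (seq_along(p) - 1)))
  Mod(ev(flt$b) / ev(flt$a))^2
}

# exhaustive two-sided Mann-Whitney p (tie-free data): enumerate every
# assignment of the pooled values to the two groups
mw_exact_p <- function(x, y) {
  m <- length(x); pooled <- c(x, y)
  u_of <- function(ix) {
    xx <- pooled[ix]; yy <- pooled[-ix]
    sum(outer(xx, yy, ">"))
  }
  ixs <- utils::combn(length(pooled), m, simplify = FALSE)
  u_all <- vapply(ixs, u_of, numeric(1))
  u_obs <- sum(outer(x, y, ">"))
  min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
}

# exhaustive two-sided Wilcoxon signed-rank p (no zero or tied absolute
# differences): enumerate all 2^n sign assignments
wsr_exact_p <- function(d) {
  n <- length(d)
  r <- rank(abs(d))
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.numeric(signs %*% r)
  v_obs <- sum(r[d > 0])
  min(1, 2 * min(mean(v_all <= v_obs), mean(v_all >= v_obs)))
}

# daily-variable pipeline over a list of synth_day outputs
run_synth_subject <- function(days, meta, config = actimetry_config()) {
  run_subject(lapply(days, `[[`, "pair"), meta, config)
}
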