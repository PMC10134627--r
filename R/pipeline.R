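#' Pipeline configuration
#'
#' All tunable constants of the analysis in one serializable object.
#' Defaults are the study constants: 10 Hz low-pass on the raw 50 Hz
#' signal; 0.5 s non-overlapping elevation windows with a +/-30 degree
#' horizontal band and a 30 degree minimum range of motion; 9 amplitude
#' bins of 10 degrees from 0 to 90; jerk-ratio bins of 0.02 over
#' \[0, 2\]; the 30 Hz / 0.25-2.5 Hz / 0.001664 g-per-count / count > 2
#' activity chain on 1 s epochs; midnight day boundary; Bonferroni
#' family size 3 for the independent ratio comparisons and 3 for the
#' paired within-stroke comparisons.
#'
#' @param ... Named overrides of any default listed above.
#' @return A named list of class `actimetry_config`.
#' @export
actimetry_config <- function(...) {
  cfg <- list(
    fs = 50,
    lowpass_hz = 10,
    filter_order = 4,
    window_s = 0.5,
    horiz_limit_deg = 30,
    rom_min_deg = 30,
    profile_bins_deg = seq(0, 90, 10),
    profile_apply_band = TRUE,
    jr_bin_width = 0.02,
    target_fs = 30,
    band_hz = c(0.25, 2.5),
    count_resolution_g = 0.001664,
    count_threshold = 2,
    epoch_s = 1,
    axis_combine = "vector",
    day_boundary = "00:00:00",
    min_day_s = 43200,
    m_independent = 3,
    m_paired = 3,
    seed = 1L
  )
  ov <- list(...)
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown)) {
    stop("actimetry_config: unknown option(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  cfg[names(ov)] <- ov
  structure(cfg, class = "actimetry_config")
}

#' Write / read a configuration as YAML
#'
#' Round-trippable serialization of an [actimetry_config].
#'
#' @param config An `actimetry_config`.
#' @param path YAML file path.
#' @return `write_config`: `path` invisibly; `read_config`: the config.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "actimetry_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(actimetry_config, vals)
}

#' Compute all per-day variables for one limb pair
#'
#' Runs the full per-day chain on a time-aligned [pair_limbs] /
#' [synth_day] pair: 10 Hz low-pass, jerk magnitudes, jerk-ratio density
#' and JR50; elevation angle, FuncUse30 per limb, FuncUseRatio30 and the
#' amplitude-binned profile; and the activity-count chain (resample to
#' 30 Hz, 0.25-2.5 Hz band-pass, counts, use hours and their ratio) on
#' the raw signal.
#'
#' @param pair A `day_pair`.
#' @param config An [actimetry_config].
#' @return A list with `variables` (one-row tibble: `uh_test`, `uh_ref`,
#'   `use_hours_ratio`, `func_use30_test`, `func_use30_ref`,
#'   `func_use_ratio30`, `jr50`, `jr_n_excluded`), `profile` (the
#'   amplitude profile tibble) and `jr_density`.
#' @export
compute_daily_variables <- function(pair, config = actimetry_config()) {
  stopifnot(inherits(pair, "day_pair"))
  raw_t <- pair$test$series; raw_r <- pair$reference$series
  filt_t <- lowpass_10hz(raw_t, config$lowpass_hz, config$filter_order)
  filt_r <- lowpass_10hz(raw_r, config$lowpass_hz, config$filter_order)

  jm_t <- jerk_magnitude(jerk_triaxial(filt_t))
  jm_r <- jerk_magnitude(jerk_triaxial(filt_r))
  jr <- jr_series(jm_t, jm_r)
  dens <- jr_density(jr, config$jr_bin_width)
  jr50_v <- jr50(dens)

  al_t <- elevation_angle(filt_t)
  al_r <- elevation_angle(filt_r)
  fu_t <- count_functional(al_t, config$window_s, config$horiz_limit_deg,
                           config$rom_min_deg)
  fu_r <- count_functional(al_r, config$window_s, config$horiz_limit_deg,
                           config$rom_min_deg)
  prof <- amplitude_profile(al_t, al_r, config$profile_bins_deg,
                            config$window_s, config$horiz_limit_deg,
                            config$profile_apply_band)

  uh_of <- function(raw) {
    s30 <- resample_to_30hz(raw, config$target_fs)
    bp <- bandpass_activity(s30, config$band_hz, config$filter_order)
    ec <- epoch_counts(bp, config$epoch_s, config$count_resolution_g,
                       config$axis_combine)
    use_hours(ec, config$count_threshold)
  }
  uh_t <- uh_of(raw_t); uh_r <- uh_of(raw_r)

  vars <- tibble::tibble(
    subject_id = pair$subject_id,
    day_index = pair$day_index,
    uh_test = uh_t, uh_ref = uh_r,
    use_hours_ratio = use_hours_ratio(uh_t, uh_r),
    func_use30_test = fu_t, func_use30_ref = fu_r,
    func_use_ratio30 = func_use_ratio(fu_t, fu_r),
    jr50 = jr50_v,
    jr_n_excluded = jr$n_excluded
  )
  list(variables = vars,
       profile = tibble::tibble(subject_id = pair$subject_id,
                                day_index = pair$day_index, prof),
       jr_density = dens)
}

#' Run the pipeline over one subject's days
#'
#' Computes daily variables for each day pair and collapses them to the
#' subject's 7-day medians (undefined day ratios excluded with a
#' warning). The summary row carries the group and FM-UE score from the
#' metadata.
#'
#' @param pairs List of `day_pair` objects (1-7 days).
#' @param meta The subject's [subject_meta].
#' @param config An [actimetry_config].
#' @return A list with `daily` (tibble, one row per day), `summary`
#'   (one-row tibble of medians plus `group`, `fm_ue`) and `profiles`
#'   (per-day amplitude profiles, long tibble).
#' @export
run_subject <- function(pairs, meta, config = actimetry_config()) {
  stopifnot(length(pairs) >= 1, inherits(meta, "subject_meta"))
  res <- lapply(pairs, compute_daily_variables, config = config)
  daily <- dplyr::bind_rows(lapply(res, `[[`, "variables"))
  profiles <- dplyr::bind_rows(lapply(res, `[[`, "profile"))
  summ <- subject_median(daily)
  summ$group <- meta$group
  summ$fm_ue <- meta$fm_ue
  list(daily = daily, summary = summ, profiles = profiles)
}

#' Read, slice and pair one subject's two wrist files
#'
#' Convenience ingestion: reads both wrist CSVs, slices each at the
#' configured day boundary, keeps slices at least `min_day_s` long
#' (partial first/last days below that are dropped) and pairs the limbs
#' day by day.
#'
#' @param left_path,right_path Recording CSVs for the left/right wrist.
#' @param meta The subject's [subject_meta].
#' @param config An [actimetry_config].
#' @return A list of `day_pair` objects.
#' @export
ingest_subject <- function(left_path, right_path, meta,
                           config = actimetry_config()) {
  left <- read_recording_csv(left_path, config$fs)
  right <- read_recording_csv(right_path, config$fs)
  dl <- slice_days(left, config$day_boundary)
  dr <- slice_days(right, config$day_boundary)
  keep <- function(sl) Filter(function(d) duration_s(d$series) >= config$min_day_s, sl)
  dl <- keep(dl); dr <- keep(dr)
  n <- min(length(dl), length(dr))
  if (n == 0) stop("ingest_subject: no day slice passes min_day_s", call. = FALSE)
  lapply(seq_len(n), function(k) {
    pair_limbs(dl[[k]]$series, dr[[k]]$series, meta, day_index = k)
  })
}

#' Cohort-level statistics and report tables
#'
#' Aggregates per-subject summaries and reproduces the cohort analyses:
#' Shapiro-Wilk normality per variable and group (motivating the
#' nonparametric tests); Mann-Whitney stroke-vs-healthy comparisons of
#' the absolute variables (per limb) and of the three use ratios
#' (Bonferroni `m_independent`); pairwise Wilcoxon signed-rank
#' comparisons of the three ratios within the stroke group (Bonferroni
#' `m_paired`); and linear regressions of each ratio on the FM-UE score
#' in the stroke group. Groups too small for a test are skipped with a
#' warning; an empty stroke or healthy group is an error.
#'
#' @param subject_results List of [run_subject] outputs (or a
#'   [synth_cohort] run through it).
#' @param config An [actimetry_config].
#' @return A list with `summaries`, `normality`, `comparisons`,
#'   `paired`, `regressions` and `profile_by_group` (per-group median
#'   amplitude-profile ratio per bin).
#' @export
run_cohort <- function(subject_results, config = actimetry_config()) {
  summaries <- dplyr::bind_rows(lapply(subject_results, `[[`, "summary"))
  if (!nrow(summaries) || !all(c("stroke", "healthy") %in% summaries$group)) {
    stop("run_cohort: need non-empty stroke and healthy groups", call. = FALSE)
  }
  stroke <- summaries[summaries$group == "stroke", ]
  healthy <- summaries[summaries$group == "healthy", ]

  abs_vars <- c("uh_test", "uh_ref", "func_use30_test", "func_use30_ref")
  ratio_vars <- c("jr50", "func_use_ratio30", "use_hours_ratio")

  norm_rows <- list()
  for (v in c(abs_vars, ratio_vars)) {
    for (g in c("stroke", "healthy")) {
      x <- summaries[summaries$group == g, ][[v]]
      x <- x[!is.na(x)]
      if (length(x) >= 3 && diff(range(x)) > 0) {
        r <- shapiro_normality(x, variable = paste0(v, ".", g))
        norm_rows[[length(norm_rows) + 1L]] <- r
      }
    }
  }
  normality <- dplyr::bind_rows(norm_rows)

  cmp_rows <- list()
  for (v in abs_vars) {
    cmp_rows[[length(cmp_rows) + 1L]] <-
      compare_groups(v, stroke[[v]], healthy[[v]], m = 1)
  }
  for (v in ratio_vars) {
    cmp_rows[[length(cmp_rows) + 1L]] <-
      compare_groups(v, stroke[[v]], healthy[[v]], m = config$m_independent)
  }
  comparisons <- dplyr::bind_rows(cmp_rows)

  paired_rows <- list()
  combos <- utils::combn(ratio_vars, 2, simplify = FALSE)
  for (cb in combos) {
    row <- tryCatch(
      compare_paired(paste(cb, collapse = " vs "),
                     stroke[[cb[1]]], stroke[[cb[2]]], m = config$m_paired),
      error = function(e) {
        warning("paired comparison ", paste(cb, collapse = " vs "),
                " skipped: ", conditionMessage(e), call. = FALSE)
        NULL
      })
    if (!is.null(row)) paired_rows[[length(paired_rows) + 1L]] <- row
  }
  paired <- dplyr::bind_rows(paired_rows)

  reg_rows <- list()
  for (v in ratio_vars) {
    row <- tryCatch(
      fm_regression(stroke$fm_ue, stroke[[v]], variable = v),
      error = function(e) {
        warning("regression of ", v, " skipped: ", conditionMessage(e),
                call. = FALSE)
        NULL
      })
    if (!is.null(row)) reg_rows[[length(reg_rows) + 1L]] <- row
  }
  regressions <- dplyr::bind_rows(reg_rows)

  profiles <- dplyr::bind_rows(lapply(subject_results, `[[`, "profiles"))
  groups <- summaries[, c("subject_id", "group")]
  prof_subj <- dplyr::summarise(
    dplyr::group_by(profiles, .data$subject_id, .data$bin_low, .data$bin_high),
    ratio = median(.data$ratio, na.rm = TRUE), .groups = "drop")
  prof_subj <- dplyr::left_join(prof_subj, groups, by = "subject_id")
  profile_by_group <- dplyr::summarise(
    dplyr::group_by(prof_subj, .data$group, .data$bin_low, .data$bin_high),
    median_ratio = median(.data$ratio, na.rm = TRUE), .groups = "drop")

  list(summaries = summaries, normality = normality,
       comparisons = comparisons, paired = paired,
       regressions = regressions, profile_by_group = profile_by_group)
}

#' Write the cohort report as CSV tables
#'
#' Emits `summaries.csv`, `normality.csv`, `comparisons.csv`,
#' `paired.csv`, `regressions.csv` and `profile_by_group.csv` under
#' `dir`. Output bytes are a deterministic function of the input tables.
#'
#' @param cohort Output of [run_cohort].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in c("summaries", "normality", "comparisons", "paired",
               "regressions", "profile_by_group")) {
    path <- file.path(dir, paste0(nm, ".csv"))
    if (ncol(cohort[[nm]]) == 0) {
      # table empty because every test in this family was skipped
      file.create(path)
    } else {
      data.table::fwrite(cohort[[nm]], path, eol = "\n")
    }
  }
  invisible(dir)
}
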