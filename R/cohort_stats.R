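#' Subject-level medians of daily variables
#'
#' Collapses the per-day variables of one subject (up to 7 rows) to one
#' row of medians, the unit of all cohort statistics. Undefined ratios
#' (reference count or use hours equal to 0 on a day) are excluded from
#' that variable's median with a warning.
#'
#' @param daily A tibble of daily variables for a single subject, as
#'   produced by [compute_daily_variables] / [run_subject].
#' @return A one-row tibble of per-variable medians (plus `subject_id`
#'   and `n_days`).
#' @export
subject_median <- function(daily) {
  stopifnot(is.data.frame(daily), nrow(daily) >= 1)
  if (length(unique(daily$subject_id)) != 1) {
    stop("subject_median: expected days of a single subject", call. = FALSE)
  }
  vars <- setdiff(names(daily), c("subject_id", "day_index"))
  med <- function(v) {
    x <- daily[[v]]
    if (anyNA(x)) {
      warning(sprintf("subject %s: %d undefined day value(s) of %s excluded from the median",
                      daily$subject_id[1], sum(is.na(x)), v), call. = FALSE)
      x <- x[!is.na(x)]
    }
    if (!length(x)) NA_real_ else median(x)
  }
  out <- tibble::tibble(subject_id = daily$subject_id[1],
                        n_days = nrow(daily))
  for (v in vars) out[[v]] <- med(v)
  out
}

comparison_result <- function(variable, test, statistic, p_raw, m,
                              n1, n2 = NA_integer_,
                              median1 = NA_real_, iqr1 = NA_real_,
                              median2 = NA_real_, iqr2 = NA_real_) {
  tibble::tibble(variable = variable, test = test,
                 statistic = unname(statistic),
                 p_raw = p_raw, m = m,
                 p_adjusted = min(1, m * p_raw),
                 n1 = n1, n2 = n2,
                 median1 = median1, iqr1 = iqr1,
                 median2 = median2, iqr2 = iqr2)
}

#' Shapiro-Wilk normality check
#'
#' Used to justify the choice of nonparametric tests in the cohort
#' report; a low p indicates departure from normality.
#'
#' @param values Numeric vector, `n >= 3`, non-constant.
#' @param variable Label carried into the result row.
#' @return A one-row tibble (`variable`, `test`, `statistic`, `p_raw`, ...).
#' @export
shapiro_normality <- function(values, variable = "value") {
  values <- values[!is.na(values)]
  if (length(values) < 3) stop("shapiro_normality: need n >= 3", call. = FALSE)
  if (diff(range(values)) == 0) {
    stop("shapiro_normality: sample is constant (degenerate)", call. = FALSE)
  }
  st <- shapiro.test(values)
  comparison_result(variable, "Shapiro-Wilk", st$statistic, st$p.value,
                    m = 1, n1 = length(values))
}

iqr_of <- function(x) unname(diff(quantile(x, c(0.25, 0.75), na.rm = TRUE)))

#' Mann-Whitney comparison of two independent groups
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test of a subject-median
#' variable between the stroke and healthy groups, Bonferroni-adjusted
#' for `m` simultaneous comparisons. The exact distribution is used when
#' both groups have at most 25 subjects and there are no ties; the
#' normal approximation with continuity and tie correction otherwise.
#' Undefined subject values (`NA`) are dropped.
#'
#' @param variable Label carried into the result row.
#' @param stroke,healthy Numeric vectors of subject medians.
#' @param m Bonferroni family size (default 1).
#' @return A one-row tibble with statistic, raw and adjusted p, group
#'   sizes, medians and IQRs.
#' @export
compare_groups <- function(variable, stroke, healthy, m = 1) {
  x <- stroke[!is.na(stroke)]; y <- healthy[!is.na(healthy)]
  if (!length(x) || !length(y)) stop("compare_groups: empty group", call. = FALSE)
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- length(x) <= 25 && length(y) <= 25 && !ties
  wt <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = TRUE))
  comparison_result(variable, "Mann-Whitney", wt$statistic, wt$p.value, m,
                    n1 = length(x), n2 = length(y),
                    median1 = median(x), iqr1 = iqr_of(x),
                    median2 = median(y), iqr2 = iqr_of(y))
}

#' Wilcoxon signed-rank comparison of two paired variables
#'
#' Two-sided Wilcoxon signed-rank test of two variables measured on the
#' same subjects (e.g., two use ratios within the stroke group),
#' Bonferroni-adjusted for `m`. Pairs with an undefined member are
#' excluded pairwise; all-zero differences are degenerate and rejected.
#'
#' @param variable Label carried into the result row.
#' @param a,b Equal-length paired numeric vectors (`n >= 5` after
#'   pairwise exclusion).
#' @param m Bonferroni family size (default 1).
#' @return A one-row tibble as in [compare_groups].
#' @export
compare_paired <- function(variable, a, b, m = 1) {
  stopifnot(length(a) == length(b))
  keep <- !is.na(a) & !is.na(b)
  n_excl <- sum(!keep)
  if (n_excl) {
    warning(sprintf("compare_paired: %d pair(s) with undefined values excluded",
                    n_excl), call. = FALSE)
  }
  a <- a[keep]; b <- b[keep]
  if (length(a) < 5) stop("compare_paired: need n >= 5 pairs", call. = FALSE)
  d <- a - b
  if (all(d == 0)) stop("compare_paired: all differences are zero (degenerate)",
                        call. = FALSE)
  ties <- anyDuplicated(abs(d[d != 0])) > 0 || any(d == 0)
  exact <- length(d) <= 25 && !ties
  wt <- suppressWarnings(wilcox.test(a, b, paired = TRUE, exact = exact,
                                     correct = TRUE))
  comparison_result(variable, "Wilcoxon signed-rank", wt$statistic,
                    wt$p.value, m,
                    n1 = length(a), n2 = length(b),
                    median1 = median(a), iqr1 = iqr_of(a),
                    median2 = median(b), iqr2 = iqr_of(b))
}

#' Linear regression of a use ratio on the Fugl-Meyer score
#'
#' Ordinary least squares of a subject-median ratio on the FM-UE score
#' within the stroke group: the slope quantifies how much the ratio
#' recovers per FM point, and r-squared its sensitivity to the clinical
#' score.
#'
#' @param fm_ue Numeric FM-UE scores (0-66).
#' @param ratio Numeric subject-median ratios (same length).
#' @param variable Label carried into the result row.
#' @return A one-row tibble with `variable`, `slope`, `intercept`,
#'   `r_squared`, `n`.
#' @export
fm_regression <- function(fm_ue, ratio, variable = "ratio") {
  keep <- !is.na(fm_ue) & !is.na(ratio)
  fm_ue <- fm_ue[keep]; ratio <- ratio[keep]
  if (length(fm_ue) < 3) stop("fm_regression: need n >= 3", call. = FALSE)
  if (diff(range(fm_ue)) == 0) stop("fm_regression: constant FM score",
                                    call. = FALSE)
  fit <- lm(ratio ~ fm_ue)
  tibble::tibble(variable = variable,
                 slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = summary(fit)$r.squared,
                 n = length(fm_ue))
}
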