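#' Coefficient of variation, in percent
#'
#' `100 * sd(x) / mean(x)` with the sample (n-1) standard deviation, computed
#' on linear-scale intensities. This is the precision metric used throughout:
#' per-day, multi-day and per-dilution-point CVs are all this quantity over
#' different observation sets.
#'
#' @param values Numeric vector of at least two positive values.
#' @return CV as a percentage.
#' @export
#' @examples
#' cv_percent(c(90, 100, 110)) # 10
cv_percent <- function(values) {
  if (length(values) < 2) {
    stop("cv_percent needs at least 2 values", call. = FALSE)
  }
  if (any(is.na(values)) || any(values <= 0)) {
    stop("cv_percent requires positive, non-missing values", call. = FALSE)
  }
  100 * stats::sd(values) / mean(values)
}

# Vectorized internal variant: NA when gate not met, no error.
cv_percent_or_na <- function(values) {
  if (length(values) < 2 || any(values <= 0)) return(NA_real_)
  100 * stats::sd(values) / mean(values)
}

#' Intra-day and multi-day precision per analyte
#'
#' For every analyte, counts detections on each design day and computes:
#' \describe{
#'   \item{intra-day CVs}{the CV of that day's detected normalized
#'     intensities, defined only when the day passes the detection gate
#'     (at least `min_detections_per_day` of the day's replicates, 3 of 5 by
#'     default);}
#'   \item{multi-day CV}{the CV over all detected observations pooled across
#'     days, defined only when every day passes the gate. When a gate fails
#'     the CV is undefined (`NA`), never zero.}
#' }
#' The pooled multi-day CV captures both replicate and day-to-day variation
#' in one number; `multi_day_method = "mean_daily"` instead averages the
#' defined daily CVs, which isolates within-day scatter.
#'
#' @param records Normalized record tibble (needs `normalized_intensity`).
#' @param design A reproducibility [study_design][reproducibility_design()].
#' @param thresholds A [qc_thresholds()] object.
#' @param multi_day_method `"pooled"` (default) or `"mean_daily"`.
#' @return Tibble with one row per analyte: key columns,
#'   `detections_per_day` and `intra_day_cv_pct` (list columns of length
#'   `n_days`), `multi_day_cv_pct`, `n_total_observations`.
#' @export
compute_precision <- function(records, design, thresholds = qc_thresholds(),
                              multi_day_method = c("pooled", "mean_daily")) {
  stop_if_not_design(design, "reproducibility")
  multi_day_method <- match.arg(multi_day_method)
  if (!"normalized_intensity" %in% names(records)) {
    stop("records must be TIC-normalized first (see tic_normalize())",
         call. = FALSE)
  }
  gate <- thresholds$min_detections_per_day
  days <- seq_len(design$n_days)

  per_day <- records %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(c("analyte_id", analyte_key_cols))),
                    .data$day) %>%
    dplyr::summarise(
      n_detected = dplyr::n(),
      day_cv = cv_percent_or_na(.data$normalized_intensity),
      .groups = "drop"
    )

  keys <- per_day %>%
    dplyr::distinct(dplyr::across(dplyr::all_of(c("analyte_id", analyte_key_cols))))

  # complete to the full design grid so absent days count as 0 detections
  full <- keys %>%
    tidyr::expand_grid(day = days) %>%
    dplyr::left_join(per_day, by = c("analyte_id", analyte_key_cols, "day")) %>%
    dplyr::mutate(
      n_detected = dplyr::coalesce(.data$n_detected, 0L),
      day_cv = dplyr::if_else(.data$n_detected >= gate, .data$day_cv, NA_real_)
    ) %>%
    dplyr::arrange(.data$analyte_id, .data$day)

  pooled <- records %>%
    dplyr::group_by(.data$analyte_id) %>%
    dplyr::summarise(
      pooled_cv = cv_percent_or_na(.data$normalized_intensity),
      .groups = "drop"
    )

  res <- full %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(c("analyte_id", analyte_key_cols)))) %>%
    dplyr::summarise(
      detections_per_day = list(.data$n_detected),
      intra_day_cv_pct = list(.data$day_cv),
      n_total_observations = sum(.data$n_detected),
      gate_all_days = all(.data$n_detected >= gate),
      mean_daily_cv = mean(.data$day_cv),
      .groups = "drop"
    ) %>%
    dplyr::left_join(pooled, by = "analyte_id") %>%
    dplyr::mutate(
      multi_day_cv_pct = dplyr::case_when(
        !.data$gate_all_days ~ NA_real_,
        multi_day_method == "pooled" ~ .data$pooled_cv,
        TRUE ~ .data$mean_daily_cv
      )
    ) %>%
    dplyr::select(-"gate_all_days", -"mean_daily_cv", -"pooled_cv") %>%
    dplyr::arrange(.data$analyte_id)
  res
}

#' Empirical cumulative frequency of CVs
#'
#' The empirical CDF over defined CVs, as plotted in cumulative-frequency
#' precision curves: for each distinct CV value, the fraction of analytes at
#' or below it.
#'
#' @param cvs Numeric vector; `NA`s (undefined CVs) are dropped.
#' @return Tibble with columns `cv_pct` (ascending) and `cumulative_fraction`
#'   (non-decreasing, ending at 1).
#' @export
cv_cumulative_frequency <- function(cvs) {
  cvs <- cvs[!is.na(cvs)]
  if (length(cvs) == 0) {
    stop("no defined CVs to summarize", call. = FALSE)
  }
  cvs <- sort(cvs)
  tibble::tibble(
    cv_pct = unique(cvs),
    cumulative_fraction = vapply(
      unique(cvs), function(c) mean(cvs <= c), numeric(1)
    )
  )
}

#' CV attained by a given fraction of analytes
#'
#' The smallest CV value `c` such that at least `fraction` of the defined CVs
#' are `<= c` — the nearest-rank empirical quantile. The published precision
#' figures mark this at `fraction = 0.8` ("the CV for 80% of peptides").
#'
#' @param cvs Numeric vector; `NA`s are dropped.
#' @param fraction Fraction in (0, 1].
#' @return A single CV value (percent).
#' @export
#' @examples
#' cv_at_fraction(c(10, 20, 30, 40, 50), 0.8) # 40
cv_at_fraction <- function(cvs, fraction) {
  if (!is.numeric(fraction) || length(fraction) != 1 ||
      is.na(fraction) || fraction <= 0 || fraction > 1) {
    stop("`fraction` must be a single number in (0, 1]", call. = FALSE)
  }
  cvs <- cvs[!is.na(cvs)]
  if (length(cvs) == 0) stop("no defined CVs", call. = FALSE)
  sort(cvs)[ceiling(fraction * length(cvs))]
}

#' Percentage of CVs strictly below a threshold
#'
#' `100 * #(cv < threshold) / #(defined CVs)`. The comparison is strict,
#' matching the published "CV < 30%" convention; the denominator is the set
#' of analytes with a defined CV.
#'
#' @param cvs Numeric vector; `NA`s are dropped.
#' @param threshold_pct CV threshold in percent.
#' @return Percentage in [0, 100].
#' @export
#' @examples
#' fraction_below_threshold(c(10, 20, 40), 30) # 66.67
fraction_below_threshold <- function(cvs, threshold_pct) {
  cvs <- cvs[!is.na(cvs)]
  if (length(cvs) == 0) stop("no defined CVs", call. = FALSE)
  100 * mean(cvs < threshold_pct)
}
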