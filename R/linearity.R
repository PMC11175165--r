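#' Summarize a dilution series into per-load points
#'
#' For each analyte and on-column load of a linearity design, collects the
#' detected replicate intensities, counts detections and computes the
#' per-load CV (defined once two replicates are detected). These points are
#' the unit the dilution fit, LLOD and LLOQ rules all consume.
#'
#' @param records Record tibble from a linearity study. LLOD/LLOQ rules are
#'   defined on unnormalized intensities, so the default `intensity_col` is
#'   `"intensity"`.
#' @param design A linearity [study_design][linearity_design()].
#' @param intensity_col Column to use as the response.
#' @return Tibble with one row per analyte-by-load: key columns, `load_ng`,
#'   `n_detected`, `mean_intensity`, `point_cv_pct`, `intensities` (list).
#' @export
build_dilution_points <- function(records, design, intensity_col = "intensity") {
  stop_if_not_design(design, "linearity")
  keys <- records %>%
    dplyr::distinct(dplyr::across(dplyr::all_of(c("analyte_id", analyte_key_cols))))
  per_load <- records %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(c("analyte_id", analyte_key_cols))),
                    .data$load_ng) %>%
    dplyr::summarise(
      n_detected = dplyr::n(),
      mean_intensity = mean(.data[[intensity_col]]),
      point_cv_pct = cv_percent_or_na(.data[[intensity_col]]),
      intensities = list(.data[[intensity_col]]),
      .groups = "drop"
    )
  keys %>%
    tidyr::expand_grid(load_ng = design$dilution_loads_ng) %>%
    dplyr::left_join(per_load,
                     by = c("analyte_id", analyte_key_cols, "load_ng")) %>%
    dplyr::mutate(
      n_detected = dplyr::coalesce(.data$n_detected, 0L),
      intensities = purrr::map2(.data$intensities, .data$n_detected,
                                ~ if (.y == 0) numeric(0) else .x)
    ) %>%
    dplyr::arrange(.data$analyte_id, .data$load_ng)
}

#' Fit a dilution curve by ordinary least squares
#'
#' Fits `mean detected intensity ~ load` with an intercept over the loads
#' that pass the per-load detection gate (at least `min_detections` detected
#' replicates), optionally restricted to a load range. Fitting on per-load
#' means rather than pooled replicates keeps unbalanced detection from giving
#' some loads extra leverage; `fit_on = "replicates"` pools them instead.
#' `r_squared` is the squared Pearson correlation of the fitted points; a
#' flat (zero-variance) response gets `r_squared = 0` by convention, which
#' correctly fails the linearity gate.
#'
#' @param points Per-analyte dilution points (one analyte) from
#'   [build_dilution_points()].
#' @param load_range Optional `c(min, max)` load restriction (ng).
#' @param min_detections Detection gate per load (default 2).
#' @param min_loads Minimum qualifying loads required to fit (default 3).
#' @param fit_on `"load_means"` (default) or `"replicates"`.
#' @return List: `slope`, `intercept`, `r_squared`, `fit_loads`, `n_loads`.
#'   `NULL` if fewer than `min_loads` loads qualify.
#' @export
fit_dilution_curve <- function(points, load_range = NULL, min_detections = 2,
                               min_loads = 3,
                               fit_on = c("load_means", "replicates")) {
  fit_on <- match.arg(fit_on)
  ok <- points$n_detected >= min_detections
  if (!is.null(load_range)) {
    ok <- ok & points$load_ng >= load_range[1] & points$load_ng <= load_range[2]
  }
  pts <- points[ok, , drop = FALSE]
  if (nrow(pts) < min_loads) return(NULL)

  if (fit_on == "load_means") {
    x <- pts$load_ng
    y <- pts$mean_intensity
  } else {
    x <- rep(pts$load_ng, lengths(pts$intensities))
    y <- unlist(pts$intensities)
  }
  fit <- stats::lm(y ~ x)
  co <- stats::coef(fit)
  r <- suppressWarnings(stats::cor(x, y))
  list(
    slope = unname(co[2]),
    intercept = unname(co[1]),
    r_squared = if (is.na(r)) 0 else r^2,
    fit_loads = pts$load_ng,
    n_loads = nrow(pts)
  )
}

#' Back-calculated accuracy of an observed intensity
#'
#' Inverts the dilution fit to estimate the load that would produce the
#' observed intensity and reports the fractional deviation from the nominal
#' load: `|((intensity - intercept)/slope - nominal) / nominal|`. Deviation
#' 0.2 means the back-calculated load misses the nominal load by 20%.
#'
#' @param intensity Observed intensity (vectorized).
#' @param slope,intercept Dilution fit coefficients (`slope != 0`).
#' @param nominal_load Nominal on-column load (ng).
#' @return Fractional deviation(s), `>= 0`.
#' @export
#' @examples
#' back_calculated_deviation(300, slope = 2, intercept = 0, nominal_load = 125)
back_calculated_deviation <- function(intensity, slope, intercept, nominal_load) {
  if (is.na(slope) || slope == 0) {
    stop("degenerate fit: slope is zero or undefined", call. = FALSE)
  }
  abs((intensity - intercept) / slope - nominal_load) / nominal_load
}

#' Lower limit of detection from a dilution series
#'
#' Scans the loads in ascending order and returns the first where the analyte
#' was detected in at least `min_detections_per_load` replicates (2 of 3)
#' with a per-load CV strictly below `cv_limit_pct` (20%), computed on
#' unnormalized intensities. Returns `NA` when no load qualifies — an
#' undefined LLOD is a valid outcome, not an error.
#'
#' @param points Dilution points for one analyte (unnormalized intensities).
#' @param thresholds A [qc_thresholds()] object.
#' @return The LLOD load in ng, or `NA_real_`.
#' @export
determine_llod <- function(points, thresholds = qc_thresholds()) {
  points <- points[order(points$load_ng), , drop = FALSE]
  pass <- points$n_detected >= thresholds$min_detections_per_load &
    !is.na(points$point_cv_pct) &
    points$point_cv_pct < thresholds$cv_limit_pct
  if (!any(pass)) return(NA_real_)
  points$load_ng[which(pass)[1]]
}

#' Lower limit of quantification from a dilution series
#'
#' Requires the analyte's dilution fit to have `r_squared` strictly above
#' `r2_min` (0.8); if not, the LLOQ is undefined regardless of per-load
#' behavior. Otherwise scans loads ascending and returns the first that
#' passes the detection gate, the CV limit, and the back-calculated accuracy
#' test (mean fractional deviation over detected replicates `<=`
#' `deviation_max`).
#'
#' @param points Dilution points for one analyte.
#' @param fit Fit list from [fit_dilution_curve()] (or `NULL`).
#' @param thresholds A [qc_thresholds()] object.
#' @return The LLOQ load in ng, or `NA_real_`.
#' @export
determine_lloq <- function(points, fit, thresholds = qc_thresholds()) {
  if (is.null(fit) || is.na(fit$r_squared) ||
      fit$r_squared <= thresholds$r2_min) {
    return(NA_real_)
  }
  if (is.na(fit$slope) || fit$slope == 0) return(NA_real_)
  points <- points[order(points$load_ng), , drop = FALSE]
  for (i in seq_len(nrow(points))) {
    if (points$n_detected[i] < thresholds$min_detections_per_load) next
    if (is.na(points$point_cv_pct[i]) ||
        points$point_cv_pct[i] >= thresholds$cv_limit_pct) next
    dev <- mean(back_calculated_deviation(
      points$intensities[[i]], fit$slope, fit$intercept, points$load_ng[i]
    ))
    dev_pass <- if (thresholds$deviation_greater_is_pass) {
      dev > thresholds$deviation_max
    } else {
      dev <= thresholds$deviation_max
    }
    if (dev_pass) return(points$load_ng[i])
  }
  NA_real_
}

#' Per-analyte linearity assessment
#'
#' Runs the full dilution-curve characterization for every analyte in a
#' linearity study: per-load points, least-squares fit, back-calculated
#' deviations, LLOD and LLOQ. Unnormalized intensities are the default
#' response, matching the published limit rules; set
#' `intensity_col = "normalized_intensity"` on normalized records to change
#' that.
#'
#' @param records Record tibble from a linearity study.
#' @param design A linearity [study_design][linearity_design()].
#' @param thresholds A [qc_thresholds()] object.
#' @param intensity_col Response column (default `"intensity"`).
#' @param load_range Optional fit restriction, `c(min, max)` ng.
#' @param fit_on `"load_means"` (default) or `"replicates"`; see
#'   [fit_dilution_curve()].
#' @return Tibble with one row per analyte: key columns, `slope`,
#'   `intercept`, `r_squared`, `n_loads_fit`, `llod_ng`, `lloq_ng`,
#'   `assessed` (had >= 2 observations at >= 1 load), and nested `points`.
#' @export
assess_linearity <- function(records, design, thresholds = qc_thresholds(),
                             intensity_col = "intensity", load_range = NULL,
                             fit_on = c("load_means", "replicates")) {
  fit_on <- match.arg(fit_on)
  points <- build_dilution_points(records, design, intensity_col)
  nested <- points %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(c("analyte_id", analyte_key_cols)))) %>%
    tidyr::nest(points = -dplyr::all_of(c("analyte_id", analyte_key_cols))) %>%
    dplyr::ungroup()

  assess_one <- function(pts) {
    fit <- fit_dilution_curve(
      pts, load_range = load_range,
      min_detections = thresholds$min_detections_per_load, fit_on = fit_on
    )
    llod <- determine_llod(pts, thresholds)
    lloq <- determine_lloq(pts, fit, thresholds)
    tibble::tibble(
      slope = if (is.null(fit)) NA_real_ else fit$slope,
      intercept = if (is.null(fit)) NA_real_ else fit$intercept,
      r_squared = if (is.null(fit)) NA_real_ else fit$r_squared,
      n_loads_fit = if (is.null(fit)) 0L else fit$n_loads,
      llod_ng = llod,
      lloq_ng = lloq,
      assessed = any(pts$n_detected >= thresholds$min_detections_per_load)
    )
  }

  nested %>%
    dplyr::mutate(stats = purrr::map(.data$points, assess_one)) %>%
    tidyr::unnest("stats") %>%
    dplyr::arrange(.data$analyte_id)
}

#' Count analytes with a determined LLOD / LLOQ
#'
#' Summarizes a linearity assessment the way limit-of-detection figures are
#' reported: the assessed universe is every analyte with two or more
#' observations in at least one loading condition; within it, the number of
#' analytes for which an LLOD, respectively LLOQ, was determined.
#'
#' @param linearity Output of [assess_linearity()].
#' @return One-row tibble: `n_assessed`, `n_with_llod`, `n_with_lloq`.
#' @export
summarize_llod_lloq <- function(linearity) {
  tibble::tibble(
    n_assessed = sum(linearity$assessed),
    n_with_llod = sum(linearity$assessed & !is.na(linearity$llod_ng)),
    n_with_lloq = sum(linearity$assessed & !is.na(linearity$lloq_ng))
  )
}

#' Total MS2 signal versus on-column load
#'
#' Sums all detected intensities within each run and averages the run totals
#' over the replicate injections at each load, giving the total-signal
#' response curve of the assay across the dilution series.
#'
#' @param records Record tibble from a linearity study.
#' @return Tibble ordered by load: `load_ng`, `total_intensity` (mean of
#'   replicate run sums), `sd_total_intensity`, `n_runs`.
#' @export
total_signal_curve <- function(records) {
  records %>%
    dplyr::group_by(.data$load_ng, .data$run_id) %>%
    dplyr::summarise(run_total = sum(.data$intensity), .groups = "drop") %>%
    dplyr::group_by(.data$load_ng) %>%
    dplyr::summarise(
      total_intensity = mean(.data$run_total),
      sd_total_intensity = if (dplyr::n() > 1) stats::sd(.data$run_total) else NA_real_,
      n_runs = dplyr::n(),
      .groups = "drop"
    ) %>%
    dplyr::arrange(.data$load_ng)
}
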