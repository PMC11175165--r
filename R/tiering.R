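#' Ordered proteome tier levels
#'
#' The four nested stringency tiers (plus `none`), ordered: an analyte's tier
#' is the highest whose criteria all hold, and every higher tier implies all
#' lower ones.
#' @return Character vector of tier names, lowest first.
#' @export
tier_levels <- function() {
  c("none", "observable", "reliable", "reproducible", "quantifiable")
}

as_tier <- function(x) factor(x, levels = tier_levels(), ordered = TRUE)

#' Classify analytes into proteome tiers
#'
#' Applies the nested four-tier definitions to each analyte's precision
#' result, joined by analyte identity to its dilution-curve fit:
#' \describe{
#'   \item{observable}{detected at least once in any run on any day;}
#'   \item{reliable}{detected at least `min_detections_per_day` times (3 of
#'     5) on every day;}
#'   \item{reproducible}{reliable, with multi-day CV strictly below
#'     `cv_reproducible_pct` (30%);}
#'   \item{quantifiable}{reproducible, with dilution-fit `r_squared` strictly
#'     above `r2_min` (0.8) from the linearity experiment.}
#' }
#' Analytes absent from the linearity experiment (or without a fit) cannot
#' exceed reproducible.
#'
#' @param precision Per-analyte output of [compute_precision()].
#' @param linearity Optional per-analyte output of [assess_linearity()] from
#'   the matching dilution study; joined by analyte identity.
#' @param thresholds A [qc_thresholds()] object.
#' @return Tibble: key columns, ordered factor `tier`, and the basis columns
#'   `n_total_observations`, `min_daily_detections`, `multi_day_cv_pct`,
#'   `r_squared`.
#' @export
classify_analytes <- function(precision, linearity = NULL,
                              thresholds = qc_thresholds()) {
  res <- precision %>%
    dplyr::mutate(
      min_daily_detections = vapply(.data$detections_per_day, min, integer(1))
    )
  if (!is.null(linearity)) {
    res <- res %>%
      dplyr::left_join(
        dplyr::select(linearity, dplyr::all_of(c("analyte_id", "r_squared"))),
        by = "analyte_id"
      )
  } else {
    res$r_squared <- NA_real_
  }
  res %>%
    dplyr::mutate(
      reliable = .data$min_daily_detections >= thresholds$min_detections_per_day,
      reproducible = .data$reliable &
        !is.na(.data$multi_day_cv_pct) &
        .data$multi_day_cv_pct < thresholds$cv_reproducible_pct,
      quantifiable = .data$reproducible &
        !is.na(.data$r_squared) &
        .data$r_squared > thresholds$r2_min,
      tier = as_tier(dplyr::case_when(
        .data$quantifiable ~ "quantifiable",
        .data$reproducible ~ "reproducible",
        .data$reliable ~ "reliable",
        .data$n_total_observations >= 1 ~ "observable",
        TRUE ~ "none"
      ))
    ) %>%
    dplyr::select(dplyr::all_of(c(
      "analyte_id", analyte_key_cols, "tier", "n_total_observations",
      "min_daily_detections", "multi_day_cv_pct", "r_squared"
    )))
}

#' Per-day tier counts
#'
#' Evaluates each preparation day independently, the basis of the
#' "mean per day" summary rows: on day `d` an analyte is observable if
#' detected at least once that day, reliable if detected at least
#' `min_detections_per_day` times that day, reproducible if additionally its
#' intra-day CV is strictly below the reproducible bound, and quantifiable
#' if additionally its dilution fit passes `r_squared > r2_min`.
#'
#' @inheritParams classify_analytes
#' @return Tibble with one row per day and cumulative counts per tier
#'   (`observable`, `reliable`, `reproducible`, `quantifiable`).
#' @export
per_day_tier_counts <- function(precision, linearity = NULL,
                                thresholds = qc_thresholds()) {
  n_days <- length(precision$detections_per_day[[1]])
  r2 <- rep(NA_real_, nrow(precision))
  if (!is.null(linearity)) {
    idx <- match(precision$analyte_id, linearity$analyte_id)
    r2 <- linearity$r_squared[idx]
  }
  r2_pass <- !is.na(r2) & r2 > thresholds$r2_min
  purrr::map_dfr(seq_len(n_days), function(d) {
    det <- vapply(precision$detections_per_day, `[`, integer(1), d)
    cv <- vapply(precision$intra_day_cv_pct, `[`, numeric(1), d)
    is_reliable <- det >= thresholds$min_detections_per_day
    is_reproducible <- is_reliable & !is.na(cv) &
      cv < thresholds$cv_reproducible_pct
    tibble::tibble(
      day = d,
      observable = sum(det >= 1),
      reliable = sum(is_reliable),
      reproducible = sum(is_reproducible),
      quantifiable = sum(is_reproducible & r2_pass)
    )
  })
}

#' Tier summary in the published table shape
#'
#' Collapses tier assignments into cumulative multi-day counts (an analyte in
#' a tier counts toward that tier and every tier below it) and, when per-day
#' counts are supplied, the mean and sample SD of the daily counts per tier.
#'
#' @param assignments Output of [classify_analytes()].
#' @param per_day Optional output of [per_day_tier_counts()].
#' @return Tibble with one row per tier: `tier`, `multi_day`, and (if
#'   `per_day` given) `mean_per_day`, `sd_per_day`.
#' @export
summarize_tiers <- function(assignments, per_day = NULL) {
  tiers <- tier_levels()[-1]
  out <- tibble::tibble(
    tier = as_tier(tiers),
    multi_day = vapply(
      tiers, function(t) sum(assignments$tier >= as_tier(t)), integer(1),
      USE.NAMES = FALSE
    )
  )
  if (!is.null(per_day)) {
    out$mean_per_day <- vapply(tiers, function(t) mean(per_day[[t]]),
                               numeric(1), USE.NAMES = FALSE)
    out$sd_per_day <- vapply(
      tiers,
      function(t) if (nrow(per_day) > 1) stats::sd(per_day[[t]]) else NA_real_,
      numeric(1), USE.NAMES = FALSE
    )
  }
  out
}

#' Combine per-biofluid analyte lists into a non-redundant union
#'
#' Builds the non-redundant union of analyte lists (e.g. the reliable
#' proteomes of naive and depleted plasma) keyed by analyte identity, with a
#' logical membership column per source supporting Venn-style comparisons
#' and combined-matrix counts.
#'
#' @param lists Named list (length >= 2) of tibbles that carry the analyte
#'   key columns; all at the same level (protein or peptide).
#' @return Tibble: key columns plus one `in_<name>` logical column per
#'   source, one row per distinct analyte.
#' @export
combine_nonredundant <- function(lists) {
  stopifnot(is.list(lists), length(lists) >= 2, !is.null(names(lists)),
            all(names(lists) != ""))
  levels_seen <- unique(unlist(lapply(lists, function(x) unique(x$level))))
  if (length(levels_seen) > 1) {
    stop("all lists must be at the same level (protein or peptide); got: ",
         paste(levels_seen, collapse = ", "), call. = FALSE)
  }
  keyed <- lapply(lists, function(x) {
    dplyr::distinct(x, dplyr::across(dplyr::all_of(c("analyte_id", analyte_key_cols))))
  })
  union_keys <- dplyr::distinct(dplyr::bind_rows(keyed))
  for (nm in names(keyed)) {
    union_keys[[paste0("in_", nm)]] <- union_keys$analyte_id %in% keyed[[nm]]$analyte_id
  }
  dplyr::arrange(union_keys, .data$analyte_id)
}

#' Rank reliable analytes by multi-day mean intensity
#'
#' Orders reliable-or-better analytes by the mean of their TIC-normalized
#' intensities over all detected observations, descending (the ordering used
#' in ranked-abundance displays of the reliable proteome), with the sample
#' SD as the spread. Ties are broken by analyte identifier.
#'
#' @param assignments Output of [classify_analytes()].
#' @param records Normalized record tibble (needs `normalized_intensity`).
#' @return Tibble ordered by descending `mean_intensity`: key columns,
#'   `tier`, `mean_intensity`, `sd_intensity`, `n_observations`, `rank`.
#' @export
rank_by_multiday_mean <- function(assignments, records) {
  eligible <- assignments %>%
    dplyr::filter(.data$tier >= as_tier("reliable"))
  records %>%
    dplyr::semi_join(eligible, by = "analyte_id") %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(c("analyte_id", analyte_key_cols)))) %>%
    dplyr::summarise(
      mean_intensity = mean(.data$normalized_intensity),
      sd_intensity = if (dplyr::n() > 1) stats::sd(.data$normalized_intensity) else NA_real_,
      n_observations = dplyr::n(),
      .groups = "drop"
    ) %>%
    dplyr::left_join(
      dplyr::select(eligible, dplyr::all_of(c("analyte_id", "tier"))),
      by = "analyte_id"
    ) %>%
    dplyr::arrange(dplyr::desc(.data$mean_intensity), .data$analyte_id) %>%
    dplyr::mutate(rank = dplyr::row_number())
}
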