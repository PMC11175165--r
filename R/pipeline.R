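#' Pipeline configuration
#'
#' Bundles the inputs, designs, thresholds and options of a full
#' assay-characterization run. Every published gate value enters the pipeline
#' through `thresholds` only, so one override propagates to every stage.
#'
#' @param output_dir Directory for all output tables, the manifest and
#'   figures (created if absent).
#' @param reproducibility_report Path to a reproducibility-study report CSV,
#'   or a `quant_report` from [read_report()] / a generator.
#' @param linearity_report Optional path or `quant_report` for the matching
#'   dilution study; without it the quantifiable tier is unreachable.
#' @param reproducibility_design,linearity_design Study designs; required
#'   when the corresponding report is given as a path.
#' @param thresholds A [qc_thresholds()] object.
#' @param normalization_reference Passed to [tic_normalize()].
#' @param rollup_method Passed to [rollup_protein()].
#' @param collapse_charges Passed to [read_report()].
#' @param cv_marker_fraction Fraction marked on the CV cumulative-frequency
#'   figure (default 0.8).
#' @param make_plots Write figure files (default `TRUE`); plotting failures
#'   never affect the data outputs.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(output_dir,
                            reproducibility_report,
                            linearity_report = NULL,
                            reproducibility_design = NULL,
                            linearity_design = NULL,
                            thresholds = qc_thresholds(),
                            normalization_reference = "median_tic",
                            rollup_method = "sum",
                            collapse_charges = FALSE,
                            cv_marker_fraction = 0.8,
                            make_plots = TRUE) {
  structure(
    list(
      output_dir = output_dir,
      reproducibility_report = reproducibility_report,
      linearity_report = linearity_report,
      reproducibility_design = reproducibility_design,
      linearity_design = linearity_design,
      thresholds = thresholds,
      normalization_reference = normalization_reference,
      rollup_method = rollup_method,
      collapse_charges = collapse_charges,
      cv_marker_fraction = cv_marker_fraction,
      make_plots = isTRUE(make_plots)
    ),
    class = "pipeline_config"
  )
}

resolve_report <- function(input, design, collapse_charges) {
  if (inherits(input, "quant_report") ||
      (is.list(input) && all(c("records", "runs", "design") %in% names(input)))) {
    return(list(report = input, path = NA_character_))
  }
  if (is.character(input) && length(input) == 1) {
    if (is.null(design)) {
      stop("a study design must accompany a report given as a path",
           call. = FALSE)
    }
    return(list(
      report = read_report(input, design, collapse_charges = collapse_charges),
      path = input
    ))
  }
  stop("report input must be a path or a quant_report", call. = FALSE)
}

pipeline_log <- function(stage, ...) {
  message(sprintf("[proteotier] %-12s %s", stage, sprintf(...)))
}

#' Run the full assay-characterization pipeline
#'
#' Orchestrates normalize -> protein roll-up -> precision -> linearity ->
#' tiering -> summaries for each biofluid-by-workflow batch present in the
#' reproducibility report, at both peptide and protein level, and writes all
#' result tables as CSV plus a JSON run manifest (configuration echo,
#' package version, input checksums) to `output_dir`. Undefined values are
#' written as empty CSV fields and JSON nulls, never as zero. Outputs are
#' deterministic: rerunning with the same config and inputs yields
#' byte-identical files.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a named list of the in-memory results (one entry per
#'   batch and level, plus the manifest).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  th <- config$thresholds

  repro <- resolve_report(config$reproducibility_report,
                          config$reproducibility_design,
                          config$collapse_charges)
  lin <- NULL
  if (!is.null(config$linearity_report)) {
    lin <- resolve_report(config$linearity_report, config$linearity_design,
                          config$collapse_charges)
  }
  pipeline_log("read", "%d reproducibility records, %d runs",
               nrow(repro$report$records), nrow(repro$report$runs))

  batches <- dplyr::distinct(repro$report$records, .data$biofluid, .data$workflow)
  results <- list()
  for (b in seq_len(nrow(batches))) {
    bf <- batches$biofluid[b]
    wf <- batches$workflow[b]
    batch_tag <- paste(bf, wf, sep = "_")
    for (level in c("peptide", "protein")) {
      res <- run_batch(repro$report, lin$report, bf, wf, level, config)
      results[[paste(batch_tag, level, sep = "_")]] <- res
      write_batch_outputs(res, config, batch_tag, level)
    }
  }

  manifest <- list(
    package = "proteotier",
    version = as.character(utils::packageVersion("proteotier")),
    thresholds = unclass(th),
    normalization_reference = config$normalization_reference,
    rollup_method = config$rollup_method,
    collapse_charges = config$collapse_charges,
    inputs = list(
      reproducibility = manifest_input(repro),
      linearity = if (is.null(lin)) NULL else manifest_input(lin)
    ),
    batches = paste(batches$biofluid, batches$workflow, sep = "_")
  )
  jsonlite::write_json(manifest, file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null",
                       digits = NA)
  pipeline_log("done", "outputs in %s", config$output_dir)
  invisible(c(results, list(manifest = manifest)))
}

manifest_input <- function(resolved) {
  list(
    path = if (is.na(resolved$path)) NULL else resolved$path,
    md5 = if (is.na(resolved$path)) NULL else unname(tools::md5sum(resolved$path)),
    n_records = nrow(resolved$report$records),
    n_runs = nrow(resolved$report$runs)
  )
}

subset_batch <- function(report, bf, wf) {
  records <- dplyr::filter(report$records,
                           .data$biofluid == bf, .data$workflow == wf)
  runs <- dplyr::filter(report$runs, .data$biofluid == bf, .data$workflow == wf)
  list(records = records, runs = runs, design = report$design)
}

run_batch <- function(repro_report, lin_report, bf, wf, level, config) {
  th <- config$thresholds
  batch <- subset_batch(repro_report, bf, wf)
  records <- batch$records
  if (level == "protein") records <- rollup_protein(records, config$rollup_method)
  normalized <- tic_normalize(records, batch$runs,
                              reference = config$normalization_reference)
  precision <- compute_precision(normalized, batch$design, th)
  pipeline_log("precision", "%s/%s %s: %d analytes",
               bf, wf, level, nrow(precision))

  linearity <- NULL
  total_signal <- NULL
  llod_lloq <- NULL
  if (!is.null(lin_report)) {
    lbatch <- subset_batch(lin_report, bf, wf)
    if (nrow(lbatch$records) > 0) {
      lrecords <- lbatch$records
      if (level == "protein") lrecords <- rollup_protein(lrecords, config$rollup_method)
      linearity <- assess_linearity(lrecords, lbatch$design, th)
      total_signal <- total_signal_curve(lrecords)
      llod_lloq <- summarize_llod_lloq(linearity)
      pipeline_log("linearity", "%s/%s %s: %d assessed, %d LLOD, %d LLOQ",
                   bf, wf, level, llod_lloq$n_assessed,
                   llod_lloq$n_with_llod, llod_lloq$n_with_lloq)
    }
  }

  assignments <- classify_analytes(precision, linearity, th)
  per_day <- per_day_tier_counts(precision, linearity, th)
  tier_summary <- summarize_tiers(assignments, per_day)
  ranked <- rank_by_multiday_mean(assignments, normalized)
  cv_curve <- tryCatch(
    cv_cumulative_frequency(precision$multi_day_cv_pct),
    error = function(e) NULL
  )
  list(
    biofluid = bf, workflow = wf, level = level,
    precision = precision, linearity = linearity,
    assignments = assignments, per_day = per_day,
    tier_summary = tier_summary, llod_lloq = llod_lloq,
    total_signal = total_signal, ranked = ranked, cv_curve = cv_curve
  )
}

flatten_precision <- function(precision) {
  n_days <- length(precision$detections_per_day[[1]])
  out <- dplyr::select(precision, -"detections_per_day", -"intra_day_cv_pct")
  for (d in seq_len(n_days)) {
    out[[sprintf("detections_day%d", d)]] <-
      vapply(precision$detections_per_day, `[`, integer(1), d)
    out[[sprintf("cv_day%d_pct", d)]] <-
      vapply(precision$intra_day_cv_pct, `[`, numeric(1), d)
  }
  out
}

write_batch_outputs <- function(res, config, batch_tag, level) {
  out <- function(name) {
    file.path(config$output_dir, sprintf("%s_%s_%s.csv", batch_tag, level, name))
  }
  readr::write_csv(flatten_precision(res$precision), out("precision"), na = "")
  readr::write_csv(
    dplyr::select(res$assignments, -dplyr::any_of("basis")),
    out("tier_assignments"), na = ""
  )
  readr::write_csv(res$tier_summary, out("tier_summary"), na = "")
  readr::write_csv(res$per_day, out("per_day_tier_counts"), na = "")
  readr::write_csv(res$ranked, out("ranked_intensity"), na = "")
  if (!is.null(res$cv_curve)) {
    readr::write_csv(res$cv_curve, out("cv_cumulative"), na = "")
  }
  if (!is.null(res$linearity)) {
    readr::write_csv(dplyr::select(res$linearity, -"points"),
                     out("linearity"), na = "")
    readr::write_csv(res$llod_lloq, out("llod_lloq_summary"), na = "")
    readr::write_csv(res$total_signal, out("total_signal"), na = "")
  }
  if (config$make_plots) {
    tryCatch(
      save_batch_plots(res, config, batch_tag, level),
      error = function(e) warning("plotting failed: ", conditionMessage(e))
    )
  }
  invisible(NULL)
}

save_batch_plots <- function(res, config, batch_tag, level) {
  fig <- function(name) {
    file.path(config$output_dir, sprintf("%s_%s_%s.png", batch_tag, level, name))
  }
  cvs <- res$precision$multi_day_cv_pct
  if (any(!is.na(cvs))) {
    ggplot2::ggsave(fig("cv_cumulative"),
                    plot_cv_frequency(cvs, config$cv_marker_fraction),
                    width = 5, height = 4, dpi = 150)
  } else {
    warning("no defined multi-day CVs; CV figure skipped")
  }
  if (!is.null(res$total_signal)) {
    ggplot2::ggsave(fig("total_signal"), plot_total_signal(res$total_signal),
                    width = 5, height = 4, dpi = 150)
  }
  if (nrow(res$ranked) > 0) {
    ggplot2::ggsave(fig("ranked_intensity"), plot_ranked_intensity(res$ranked),
                    width = 5, height = 4, dpi = 150)
  }
  invisible(NULL)
}

#' CV cumulative-frequency figure
#'
#' Empirical cumulative frequency of the defined CVs with a vertical line at
#' the CV attained by `fraction` of analytes (see [cv_at_fraction()]).
#'
#' @param cvs Numeric CV vector (percent); `NA`s dropped.
#' @param fraction Marker fraction (default 0.8).
#' @return A ggplot object.
#' @export
plot_cv_frequency <- function(cvs, fraction = 0.8) {
  curve <- cv_cumulative_frequency(cvs)
  marker <- cv_at_fraction(cvs, fraction)
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$cv_pct,
                                      y = .data$cumulative_fraction)) +
    ggplot2::geom_step() +
    ggplot2::geom_vline(xintercept = marker, linetype = "dashed") +
    ggplot2::labs(
      x = "CV (%)", y = "Cumulative fraction of analytes",
      title = sprintf("CV for %d%% of analytes: %.1f%%",
                      round(100 * fraction), marker)
    ) +
    ggplot2::theme_minimal()
}

#' Total-signal response figure
#'
#' @param total_signal Output of [total_signal_curve()].
#' @return A ggplot object.
#' @export
plot_total_signal <- function(total_signal) {
  ggplot2::ggplot(total_signal, ggplot2::aes(x = .data$load_ng,
                                             y = .data$total_intensity)) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "On-column load (ng)", y = "Total MS2 signal") +
    ggplot2::theme_minimal()
}

#' Ranked-abundance figure of the reliable proteome
#'
#' @param ranked Output of [rank_by_multiday_mean()].
#' @return A ggplot object.
#' @export
plot_ranked_intensity <- function(ranked) {
  ggplot2::ggplot(ranked, ggplot2::aes(x = .data$rank,
                                       y = .data$mean_intensity)) +
    ggplot2::geom_pointrange(
      ggplot2::aes(
        ymin = pmax(.data$mean_intensity - dplyr::coalesce(.data$sd_intensity, 0),
                    .Machine$double.xmin),
        ymax = .data$mean_intensity + dplyr::coalesce(.data$sd_intensity, 0)
      ),
      size = 0.1
    ) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Abundance rank", y = "Multi-day mean intensity") +
    ggplot2::theme_minimal()
}
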