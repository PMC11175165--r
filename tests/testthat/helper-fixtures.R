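# Fixture builders used across test files. All fixtures are built in code.

# Reproducibility-study report from a named list of per-day intensity
# vectors: values[[analyte]][[day]] is a numeric vector of length
# n_replicates_per_day with NA for undetected replicates. Constant TIC by
# default so normalized intensities equal raw ones.
mk_repro_report <- function(values, design = reproducibility_design(),
                            tic = 1e9, biofluid = "naive_plasma",
                            workflow = "high_throughput") {
  rows <- list()
  for (analyte in names(values)) {
    for (d in seq_along(values[[analyte]])) {
      vals <- values[[analyte]][[d]]
      for (r in seq_along(vals)) {
        if (is.na(vals[r])) next
        rows[[length(rows) + 1]] <- tibble::tibble(
          protein_accession = paste0("PROT_", analyte),
          peptide_sequence = paste0("PEPSEQ", analyte, "K"),
          charge = 2L,
          biofluid = biofluid, workflow = workflow,
          run_id = sprintf("d%d_r%d", d, r),
          day = d, replicate = r, load_ng = 250,
          intensity = vals[r]
        )
      }
    }
  }
  records <- dplyr::bind_rows(rows)
  n_days <- design$n_days
  n_rep <- design$n_replicates_per_day
  runs <- tidyr::expand_grid(day = seq_len(n_days), replicate = seq_len(n_rep))
  runs <- dplyr::mutate(runs,
    run_id = sprintf("d%d_r%d", day, replicate),
    biofluid = biofluid, workflow = workflow, load_ng = 250, ms2_tic = tic
  )
  records <- dplyr::left_join(records,
                              dplyr::select(runs, run_id, ms2_tic),
                              by = "run_id")
  records <- proteotier:::finalize_records(records)
  list(records = records, runs = runs, design = design)
}

# Dilution points tibble for a single analyte from a list of replicate
# intensity vectors per load (numeric(0) = nothing detected at that load).
mk_points <- function(loads, intensities_by_load) {
  tibble::tibble(
    analyte_id = "peptide|P1|PEPK|2",
    level = "peptide", protein_accession = "P1",
    peptide_sequence = "PEPK", charge = 2L,
    load_ng = loads,
    n_detected = lengths(intensities_by_load),
    mean_intensity = vapply(intensities_by_load,
                            function(v) if (length(v)) mean(v) else NA_real_,
                            numeric(1)),
    point_cv_pct = vapply(intensities_by_load, function(v) {
      if (length(v) >= 2 && all(v > 0)) 100 * stats::sd(v) / mean(v) else NA_real_
    }, numeric(1)),
    intensities = intensities_by_load
  )
}

# Hand-built precision rows for classification tests.
mk_precision_row <- function(id, detections, intra_cv, multi_cv, level = "peptide") {
  tibble::tibble(
    analyte_id = id, level = level,
    protein_accession = strsplit(id, "|", fixed = TRUE)[[1]][2],
    peptide_sequence = if (level == "peptide") "PEPK" else "",
    charge = if (level == "peptide") 2L else NA_integer_,
    detections_per_day = list(as.integer(detections)),
    intra_day_cv_pct = list(as.numeric(intra_cv)),
    n_total_observations = sum(detections),
    multi_day_cv_pct = multi_cv
  )
}

mk_linearity_row <- function(id, r_squared, level = "peptide") {
  tibble::tibble(analyte_id = id, level = level, r_squared = r_squared)
}
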