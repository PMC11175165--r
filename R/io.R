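#' @importFrom rlang .data
#' @importFrom dplyr %>%
NULL

report_columns <- c(
  "protein_accession", "peptide_sequence", "charge", "biofluid", "workflow",
  "run_id", "day", "replicate", "load_ng", "intensity", "ms2_tic"
)

#' Build the canonical analyte identifier
#'
#' Analyte identity is `(level, protein_accession, peptide_sequence, charge)`:
#' protein-level analytes carry an empty peptide sequence and no charge;
#' peptide-level analytes are precursor-resolved when a charge is present.
#' The string form is used for joins, ordering and tie-breaking throughout.
#'
#' @param level `"peptide"` or `"protein"`.
#' @param protein_accession Protein accession string.
#' @param peptide_sequence Peptide sequence (empty for protein level).
#' @param charge Integer precursor charge or `NA`.
#' @return Character vector of identifiers.
#' @keywords internal
make_analyte_id <- function(level, protein_accession, peptide_sequence, charge) {
  chg <- ifelse(is.na(charge), "", as.character(charge))
  seq <- ifelse(is.na(peptide_sequence), "", peptide_sequence)
  paste(level, protein_accession, seq, chg, sep = "|")
}

analyte_key_cols <- c("level", "protein_accession", "peptide_sequence", "charge")

# Attach level + analyte_id derived from the raw report columns.
finalize_records <- function(records) {
  records %>%
    dplyr::mutate(
      peptide_sequence = dplyr::coalesce(.data$peptide_sequence, ""),
      level = ifelse(.data$peptide_sequence == "", "protein", "peptide"),
      analyte_id = make_analyte_id(
        .data$level, .data$protein_accession, .data$peptide_sequence, .data$charge
      )
    ) %>%
    dplyr::relocate("analyte_id", "level")
}

#' Read a long-format quantification report
#'
#' Reads a comma- or tab-separated report with one row per analyte
#' observation per run and validates it against a declared [study design]
#' [reproducibility_design()]. Rows whose intensity is empty, `NA` or zero
#' mean "not detected" and yield no record: missing values are represented by
#' absence, never by zeroes, so they cannot leak into CVs. Run metadata
#' (`ms2_tic`, day, replicate, load) is deduplicated by `run_id`.
#'
#' Required columns: `protein_accession, peptide_sequence, charge, biofluid,
#' workflow, run_id, day, replicate, load_ng, intensity, ms2_tic`. Protein-
#' level rows leave `peptide_sequence` empty.
#'
#' @param path Path to a CSV/TSV file (delimiter sniffed from the extension;
#'   `.tsv`/`.txt` read as tab-separated).
#' @param design A [study_design][reproducibility_design()] the report must
#'   conform to (day/replicate/load bounds).
#' @param collapse_charges If `TRUE`, precursor charges of one peptide are
#'   summed per run so peptide identity is the stripped sequence. Default
#'   `FALSE` (precursor-resolved when charges are present).
#' @return A list with class `quant_report`: `records` (one row per detected
#'   observation), `runs` (one row per run) and `design`.
#' @export
read_report <- function(path, design, collapse_charges = FALSE) {
  stop_if_not_design(design)
  if (!file.exists(path)) stop("report file not found: ", path, call. = FALSE)
  delim <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  raw <- readr::read_delim(
    path, delim = delim,
    col_types = readr::cols(
      protein_accession = readr::col_character(),
      peptide_sequence = readr::col_character(),
      charge = readr::col_integer(),
      biofluid = readr::col_character(),
      workflow = readr::col_character(),
      run_id = readr::col_character(),
      day = readr::col_integer(),
      replicate = readr::col_integer(),
      load_ng = readr::col_double(),
      intensity = readr::col_double(),
      ms2_tic = readr::col_double()
    ),
    na = c("", "NA"), progress = FALSE, show_col_types = FALSE
  )
  missing_cols <- setdiff(report_columns, names(raw))
  if (length(missing_cols) > 0) {
    stop("report is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  validate_report_rows(raw, design)

  runs <- raw %>%
    dplyr::distinct(
      .data$run_id, .data$biofluid, .data$workflow, .data$day,
      .data$replicate, .data$load_ng, .data$ms2_tic
    )
  dup_runs <- runs$run_id[duplicated(runs$run_id)]
  if (length(dup_runs) > 0) {
    stop("run(s) with conflicting metadata: ",
         paste(unique(dup_runs), collapse = ", "), call. = FALSE)
  }

  records <- raw %>%
    dplyr::filter(!is.na(.data$intensity), .data$intensity > 0) %>%
    finalize_records()

  dup <- records %>%
    dplyr::count(.data$analyte_id, .data$run_id) %>%
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop(sprintf("duplicate (analyte, run) observation(s), e.g. %s in %s",
                 dup$analyte_id[1], dup$run_id[1]), call. = FALSE)
  }

  if (collapse_charges) {
    records <- records %>%
      dplyr::mutate(charge = NA_integer_) %>%
      dplyr::group_by(dplyr::across(dplyr::all_of(c(
        analyte_key_cols, "biofluid", "workflow", "run_id", "day",
        "replicate", "load_ng", "ms2_tic"
      )))) %>%
      dplyr::summarise(intensity = sum(.data$intensity), .groups = "drop") %>%
      finalize_records()
  }

  new_quant_report(records, runs, design)
}

validate_report_rows <- function(raw, design) {
  bad_int <- which(!is.na(raw$intensity) & raw$intensity < 0)
  if (length(bad_int) > 0) {
    stop("negative intensity at row ", bad_int[1], call. = FALSE)
  }
  if (any(is.na(raw$protein_accession) | raw$protein_accession == "")) {
    stop("empty protein_accession", call. = FALSE)
  }
  if (design$kind == "reproducibility") {
    bad_day <- which(is.na(raw$day) | raw$day < 1 | raw$day > design$n_days)
    if (length(bad_day) > 0) {
      stop(sprintf("day out of bounds [1, %d] at row %d",
                   design$n_days, bad_day[1]), call. = FALSE)
    }
    bad_rep <- which(is.na(raw$replicate) | raw$replicate < 1 |
                       raw$replicate > design$n_replicates_per_day)
    if (length(bad_rep) > 0) {
      stop(sprintf("replicate out of bounds [1, %d] at row %d",
                   design$n_replicates_per_day, bad_rep[1]), call. = FALSE)
    }
  } else {
    bad_load <- which(!(raw$load_ng %in% design$dilution_loads_ng))
    if (length(bad_load) > 0) {
      stop(sprintf("load_ng %g at row %d is not a design dilution point",
                   raw$load_ng[bad_load[1]], bad_load[1]), call. = FALSE)
    }
    bad_rep <- which(is.na(raw$replicate) | raw$replicate < 1 |
                       raw$replicate > design$n_replicates_per_load)
    if (length(bad_rep) > 0) {
      stop(sprintf("replicate out of bounds [1, %d] at row %d",
                   design$n_replicates_per_load, bad_rep[1]), call. = FALSE)
    }
  }
  invisible(NULL)
}

new_quant_report <- function(records, runs, design) {
  structure(list(records = records, runs = runs, design = design),
            class = "quant_report")
}

#' @export
print.quant_report <- function(x, ...) {
  cat(sprintf("<quant_report> %d detected observations, %d analytes, %d runs\n",
              nrow(x$records), dplyr::n_distinct(x$records$analyte_id),
              nrow(x$runs)))
  print(x$design)
  invisible(x)
}

#' Write a quantification report
#'
#' Serializes records plus run metadata back to the long CSV dialect read by
#' [read_report()]. Output is deterministic: columns in the canonical order,
#' rows sorted by analyte then run, so identical inputs give byte-identical
#' files. Runs without any detected record cannot be represented in the
#' single-table dialect and are dropped with a warning.
#'
#' @param report A `quant_report` (or a list with `records` and `runs`).
#' @param path Output file path (`.csv`).
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  records <- report$records
  runs <- report$runs
  orphan <- setdiff(records$run_id, runs$run_id)
  if (length(orphan) > 0) {
    stop("records reference unknown run(s): ",
         paste(orphan, collapse = ", "), call. = FALSE)
  }
  unseen <- setdiff(runs$run_id, records$run_id)
  if (length(unseen) > 0 && nrow(records) > 0) {
    warning("run(s) without detected records are not representable: ",
            paste(unseen, collapse = ", "))
  }
  out <- records %>%
    dplyr::arrange(.data$analyte_id, .data$run_id) %>%
    dplyr::select(dplyr::all_of(report_columns))
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Roll peptide intensities up to protein level
#'
#' Aggregates detected peptide intensities of one protein within each run into
#' a single protein-level record. A protein counts as detected in a run iff at
#' least one constituent peptide is detected there. The default aggregate is
#' the sum, the common label-free convention; mean and median are offered
#' because search engines differ and the appropriate roll-up is assay policy,
#' not a property of the data.
#'
#' @param records Peptide-level record tibble (from a `quant_report`).
#' @param method `"sum"` (default), `"mean"` or `"median"`.
#' @return Protein-level record tibble in the same shape.
#' @export
rollup_protein <- function(records, method = c("sum", "mean", "median")) {
  method <- match.arg(method)
  if (nrow(records) > 0 && any(records$level != "peptide")) {
    stop("rollup_protein expects peptide-level records only", call. = FALSE)
  }
  agg <- switch(method, sum = sum, mean = mean, median = stats::median)
  records %>%
    dplyr::group_by(
      .data$protein_accession, .data$biofluid, .data$workflow, .data$run_id,
      .data$day, .data$replicate, .data$load_ng, .data$ms2_tic
    ) %>%
    dplyr::summarise(intensity = agg(.data$intensity), .groups = "drop") %>%
    dplyr::mutate(peptide_sequence = "", charge = NA_integer_) %>%
    finalize_records() %>%
    dplyr::arrange(.data$analyte_id, .data$run_id)
}
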