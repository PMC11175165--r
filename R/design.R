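#' Declare a replicate/day reproducibility design
#'
#' A reproducibility study digests `n_replicates_per_day` replicate samples of
#' one biofluid on each of `n_days` consecutive days and acquires one DIA-MS
#' run per replicate. Detection-count gates (at least 3 of 5 observations per
#' day, on every day) are evaluated against this declared structure, not
#' against the runs that happen to appear in a report.
#'
#' @param n_days Number of preparation days (default 3).
#' @param n_replicates_per_day Replicate digests per day (default 5).
#' @return A `study_design` object of kind `"reproducibility"`.
#' @seealso [linearity_design()]
#' @export
#' @examples
#' reproducibility_design()
reproducibility_design <- function(n_days = 3, n_replicates_per_day = 5) {
  stopifnot(n_days >= 1, n_replicates_per_day >= 2)
  structure(
    list(
      kind = "reproducibility",
      n_days = as.integer(n_days),
      n_replicates_per_day = as.integer(n_replicates_per_day),
      dilution_loads_ng = numeric(0),
      n_replicates_per_load = NA_integer_
    ),
    class = "study_design"
  )
}

#' Declare a dilution-series linearity design
#'
#' A linearity study acquires `n_replicates_per_load` replicate injections at
#' each on-column load of a serial dilution curve, all on one day. The default
#' load series are 2-fold reconstructions spanning the printed ranges of the
#' two workflows; see [ht_dilution_loads()] and [mt_dilution_loads()].
#'
#' @param dilution_loads_ng Strictly increasing vector of on-column loads in
#'   nanograms.
#' @param n_replicates_per_load Replicate injections per load (default 3).
#' @return A `study_design` object of kind `"linearity"`.
#' @export
#' @examples
#' linearity_design(ht_dilution_loads())
linearity_design <- function(dilution_loads_ng, n_replicates_per_load = 3) {
  stopifnot(
    length(dilution_loads_ng) >= 2,
    all(dilution_loads_ng > 0),
    !is.unsorted(dilution_loads_ng, strictly = TRUE),
    n_replicates_per_load >= 2
  )
  structure(
    list(
      kind = "linearity",
      n_days = 1L,
      n_replicates_per_day = NA_integer_,
      dilution_loads_ng = as.numeric(dilution_loads_ng),
      n_replicates_per_load = as.integer(n_replicates_per_load)
    ),
    class = "study_design"
  )
}

#' Default dilution-curve loads
#'
#' Six-point (high-throughput, 31.25--1000 ng) and seven-point
#' (mid-throughput, 39--2500 ng) 2-fold dilution series. The intermediate
#' points are a reconstruction between the published endpoints and can be
#' overridden in [linearity_design()].
#'
#' @return Numeric vector of on-column loads (ng).
#' @export
ht_dilution_loads <- function() c(31.25, 62.5, 125, 250, 500, 1000)

#' @rdname ht_dilution_loads
#' @export
mt_dilution_loads <- function() c(39, 78, 156, 312.5, 625, 1250, 2500)

#' @export
print.study_design <- function(x, ...) {
  if (x$kind == "reproducibility") {
    cat(sprintf(
      "<study_design> reproducibility: %d replicates/day x %d days (%d runs)\n",
      x$n_replicates_per_day, x$n_days, x$n_replicates_per_day * x$n_days
    ))
  } else {
    cat(sprintf(
      "<study_design> linearity: %d loads (%s ng) x %d replicates\n",
      length(x$dilution_loads_ng),
      paste0(min(x$dilution_loads_ng), "-", max(x$dilution_loads_ng)),
      x$n_replicates_per_load
    ))
  }
  invisible(x)
}

is_study_design <- function(x) inherits(x, "study_design")

#' Read a study design from a YAML or JSON configuration file
#'
#' The file declares `kind` (`"reproducibility"` or `"linearity"`) plus the
#' fields of the corresponding constructor, e.g.
#' `{"kind": "linearity", "dilution_loads_ng": [31.25, 62.5, 125], ...}`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `study_design` object.
#' @export
read_study_design <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (is.null(cfg$kind)) stop("design config must declare `kind`", call. = FALSE)
  if (cfg$kind == "reproducibility") {
    reproducibility_design(
      n_days = cfg$n_days %||% 3,
      n_replicates_per_day = cfg$n_replicates_per_day %||% 5
    )
  } else if (cfg$kind == "linearity") {
    if (is.null(cfg$dilution_loads_ng)) {
      stop("linearity design config must declare `dilution_loads_ng`",
           call. = FALSE)
    }
    linearity_design(
      dilution_loads_ng = as.numeric(cfg$dilution_loads_ng),
      n_replicates_per_load = cfg$n_replicates_per_load %||% 3
    )
  } else {
    stop("unknown design kind: ", cfg$kind, call. = FALSE)
  }
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_if_not_design <- function(design, kind = NULL) {
  if (!is_study_design(design)) {
    stop("`design` must be a study_design object", call. = FALSE)
  }
  if (!is.null(kind) && design$kind != kind) {
    stop(sprintf("this operation requires a %s design, got %s", kind, design$kind),
         call. = FALSE)
  }
  invisible(design)
}

#' Assay-characterization decision thresholds
#'
#' All printed gate values used by the precision, linearity and tiering stages
#' live in this one object so that a single override propagates everywhere.
#' Comparisons against `cv_reproducible_pct` and `cv_limit_pct` are strict
#' (`<`), matching the published rules; the back-calculation accuracy test is
#' `deviation <= deviation_max` by default (set `deviation_greater_is_pass`
#' to take deviations above the bound as passing instead).
#'
#' @param cv_reproducible_pct Multi-day/intra-day CV bound (percent) for the
#'   reproducible tier. Default 30.
#' @param cv_limit_pct Per-load CV bound (percent) in the LLOD/LLOQ rules.
#'   Default 20.
#' @param min_detections_per_day Detections required each day for an analyte
#'   to enter CV computation (the 3-of-5 gate). Default 3.
#' @param min_detections_per_load Detections required at a load in the
#'   LLOD/LLOQ scans (the 2-of-3 gate). Default 2.
#' @param r2_min Minimum squared correlation of the dilution fit for the
#'   quantifiable tier and the LLOQ. Default 0.8 (strict `>`).
#' @param deviation_max Back-calculated accuracy bound (fractional). Default
#'   0.2.
#' @param deviation_greater_is_pass If `TRUE`, a load passes the accuracy test
#'   when its deviation exceeds `deviation_max` (the literal published
#'   wording); default `FALSE`.
#' @return A named list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(cv_reproducible_pct = 30,
                          cv_limit_pct = 20,
                          min_detections_per_day = 3,
                          min_detections_per_load = 2,
                          r2_min = 0.8,
                          deviation_max = 0.2,
                          deviation_greater_is_pass = FALSE) {
  stopifnot(
    cv_reproducible_pct > 0, cv_limit_pct > 0,
    min_detections_per_day >= 2, min_detections_per_load >= 2,
    r2_min >= 0, r2_min <= 1, deviation_max >= 0
  )
  structure(
    list(
      cv_reproducible_pct = cv_reproducible_pct,
      cv_limit_pct = cv_limit_pct,
      min_detections_per_day = as.integer(min_detections_per_day),
      min_detections_per_load = as.integer(min_detections_per_load),
      r2_min = r2_min,
      deviation_max = deviation_max,
      deviation_greater_is_pass = isTRUE(deviation_greater_is_pass)
    ),
    class = "qc_thresholds"
  )
}
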