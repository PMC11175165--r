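#' MS2 total-ion-current normalization
#'
#' Scales each detected intensity by `reference_tic / run_tic`, where the
#' run's `ms2_tic` is the summed fragment-level ion current of that
#' acquisition and the reference is the median run TIC by default. Dividing
#' by the run TIC removes run-to-run differences in total signal (injection,
#' spray, gradient drift) while preserving within-run intensity ratios
#' exactly; the choice of reference is a common factor across runs, so CVs
#' computed downstream are identical for `median_tic`, `mean_tic` and `unit`.
#'
#' Normalization is intended to be applied within one biofluid-by-workflow
#' batch at a time, mirroring how each matrix is analyzed separately.
#'
#' @param records Record tibble (detected observations).
#' @param runs Run metadata tibble with `run_id` and `ms2_tic`.
#' @param reference `"median_tic"` (default), `"mean_tic"`, or `"unit"`
#'   (reference TIC of 1, i.e. plain division by the run TIC).
#' @return `records` with a `normalized_intensity` column appended.
#' @export
#' @examples
#' runs <- tibble::tibble(run_id = c("a", "b"), ms2_tic = c(1e9, 2e9))
#' recs <- tibble::tibble(run_id = c("a", "b"), intensity = c(100, 100))
#' tic_normalize(recs, runs)$normalized_intensity
tic_normalize <- function(records, runs,
                          reference = c("median_tic", "mean_tic", "unit")) {
  reference <- match.arg(reference)
  used <- unique(records$run_id)
  run_tics <- runs[runs$run_id %in% used, , drop = FALSE]
  bad <- run_tics$run_id[is.na(run_tics$ms2_tic) | run_tics$ms2_tic <= 0]
  if (length(bad) > 0) {
    stop("run(s) with detected records but missing/non-positive ms2_tic: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  orphan <- setdiff(used, runs$run_id)
  if (length(orphan) > 0) {
    stop("records reference run(s) without metadata: ",
         paste(orphan, collapse = ", "), call. = FALSE)
  }
  reference_tic <- switch(reference,
    median_tic = stats::median(run_tics$ms2_tic),
    mean_tic = mean(run_tics$ms2_tic),
    unit = 1
  )
  tic_of <- stats::setNames(run_tics$ms2_tic, run_tics$run_id)
  dplyr::mutate(
    records,
    normalized_intensity = .data$intensity * reference_tic / unname(tic_of[.data$run_id])
  )
}
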