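#' Configuration for the synthetic report generator
#'
#' Describes a synthetic DIA-MS cohort with known ground truth. Each peptide
#' gets a base intensity (log10-uniform over `log10_mean_intensity_range`,
#' interpreted at the reference on-column load `load_ng`), a replicate CV
#' drawn from a two-component mixture (`cv_low` with probability
#' `1 - fraction_high_cv`, else `cv_high`), a shared-within-day multiplicative
#' log-normal day effect of log-SD `day_effect_sd`, and abundance-dependent
#' detection: the probability of observing an analyte in a run is logistic in
#' the log10 expected intensity, centered at `dropout_midpoint` with slope
#' `dropout_slope` (set `dropout_midpoint = -Inf` to disable dropout).
#'
#' Replicate noise is log-normal with `sdlog = sqrt(log(1 + cv^2))` and mean
#' 1, so its linear-scale CV equals the configured CV exactly and intensities
#' stay positive.
#'
#' For linearity designs the expected intensity at load `L` is
#' `base_intensity * min(L, saturation_load) / load_ng`, i.e. proportional
#' response through the origin with optional saturation; a fraction
#' `fraction_saturating` of analytes saturates at `saturation_load` ng.
#' `noise_floor` adds half-normal additive noise of that scale.
#'
#' @param seed Integer seed; identical configs give byte-identical reports.
#' @param design A [study_design][reproducibility_design()].
#' @param n_proteins,peptides_per_protein Cohort size (default 200 x 5).
#' @param log10_mean_intensity_range Base-intensity range, log10 units.
#' @param cv_low,cv_high,fraction_high_cv Replicate-CV mixture (proportions,
#'   not percent).
#' @param day_effect_sd Log-SD of the per-analyte, per-day factor.
#' @param dropout_midpoint,dropout_slope Logistic detection model (log10
#'   intensity units).
#' @param load_ng Reference on-column load (ng) at which base intensities are
#'   defined; also the load of every reproducibility run.
#' @param biofluid,workflow Labels stamped on all records.
#' @param tic_background Constant added to each run's summed detected
#'   intensity to form its `ms2_tic`.
#' @param fraction_saturating,saturation_load,noise_floor Linearity-specific
#'   options (see above).
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(seed,
                              design,
                              n_proteins = 200,
                              peptides_per_protein = 5,
                              log10_mean_intensity_range = c(3, 8),
                              cv_low = 0.10,
                              cv_high = 0.45,
                              fraction_high_cv = 0.2,
                              day_effect_sd = 0.10,
                              dropout_midpoint = 3.0,
                              dropout_slope = 3.0,
                              load_ng = 250,
                              biofluid = "naive_plasma",
                              workflow = "high_throughput",
                              tic_background = 1e6,
                              fraction_saturating = 0,
                              saturation_load = NULL,
                              noise_floor = 0) {
  stop_if_not_design(design)
  stopifnot(
    n_proteins >= 1, peptides_per_protein >= 1,
    length(log10_mean_intensity_range) == 2,
    diff(log10_mean_intensity_range) >= 0,
    cv_low >= 0, cv_high >= 0,
    fraction_high_cv >= 0, fraction_high_cv <= 1,
    day_effect_sd >= 0, dropout_slope >= 0,
    load_ng > 0, tic_background >= 0,
    fraction_saturating >= 0, fraction_saturating <= 1,
    noise_floor >= 0
  )
  structure(
    list(
      seed = as.integer(seed), design = design,
      n_proteins = as.integer(n_proteins),
      peptides_per_protein = as.integer(peptides_per_protein),
      log10_mean_intensity_range = log10_mean_intensity_range,
      cv_low = cv_low, cv_high = cv_high, fraction_high_cv = fraction_high_cv,
      day_effect_sd = day_effect_sd,
      dropout_midpoint = dropout_midpoint, dropout_slope = dropout_slope,
      load_ng = load_ng, biofluid = biofluid, workflow = workflow,
      tic_background = tic_background,
      fraction_saturating = fraction_saturating,
      saturation_load = saturation_load,
      noise_floor = noise_floor
    ),
    class = "simulation_config"
  )
}

cv_to_sdlog <- function(cv) sqrt(log(1 + cv^2))

detect_prob <- function(expected_intensity, config) {
  if (identical(config$dropout_midpoint, -Inf)) {
    return(rep(1, length(expected_intensity)))
  }
  stats::plogis(
    config$dropout_slope * (log10(expected_intensity) - config$dropout_midpoint)
  )
}

random_peptide <- function(n, min_len = 8, max_len = 15) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  vapply(seq_len(n), function(i) {
    paste(sample(aa, sample(min_len:max_len, 1), replace = TRUE), collapse = "")
  }, character(1))
}

# Per-analyte ground-truth parameters; drawn deterministically from the seed
# so reproducibility and dilution studies built from one config share them.
generate_analytes <- function(config) {
  n <- config$n_proteins * config$peptides_per_protein
  acc <- rep(sprintf("P%05d", seq_len(config$n_proteins)),
             each = config$peptides_per_protein)
  seqs <- random_peptide(n)
  rng <- config$log10_mean_intensity_range
  base <- 10^stats::runif(n, rng[1], rng[2])
  cv <- ifelse(stats::runif(n) < config$fraction_high_cv,
               config$cv_high, config$cv_low)
  charge <- sample(2:3, n, replace = TRUE)
  sat <- rep(NA_real_, n)
  if (config$fraction_saturating > 0 && !is.null(config$saturation_load)) {
    sat[stats::runif(n) < config$fraction_saturating] <- config$saturation_load
  }
  tibble::tibble(
    protein_accession = acc,
    peptide_sequence = seqs,
    charge = as.integer(charge),
    level = "peptide",
    analyte_id = make_analyte_id("peptide", acc, seqs, charge),
    base_intensity = base,
    true_cv = cv,
    saturation_load = sat
  )
}

# Designed tier of an analyte under the published gates, from its true
# parameters. Labels are confident only when parameters are far from the
# gates; marginal detection gets "observable".
designed_tiers <- function(analytes, config, thresholds = qc_thresholds()) {
  p_base <- detect_prob(analytes$base_intensity, config)
  sd_total <- sqrt(cv_to_sdlog(analytes$true_cv)^2 + config$day_effect_sd^2)
  total_cv <- sqrt(exp(sd_total^2) - 1)
  lin_ok <- designed_r2_ok(analytes, config, thresholds)
  tier <- dplyr::case_when(
    p_base >= 0.99 & 100 * total_cv < thresholds$cv_reproducible_pct & lin_ok ~
      "quantifiable",
    p_base >= 0.99 & 100 * total_cv < thresholds$cv_reproducible_pct ~
      "reproducible",
    p_base >= 0.99 ~ "reliable",
    p_base <= 0.001 ~ "none",
    TRUE ~ "observable"
  )
  tibble::tibble(
    p_detect_base = p_base,
    true_total_cv = total_cv,
    designed_tier = as_tier(tier)
  )
}

# Whether the designed dilution response should pass the r2 > 0.8 gate:
# detectable at >= 3 loads, not saturating inside the curve, low noise.
designed_r2_ok <- function(analytes, config, thresholds) {
  loads <- config$design$dilution_loads_ng
  if (length(loads) == 0) return(rep(FALSE, nrow(analytes)))
  n_good <- vapply(seq_len(nrow(analytes)), function(i) {
    expd <- analytes$base_intensity[i] *
      pmin(loads, analytes$saturation_load[i] %|na|% Inf) / config$load_ng
    sum(detect_prob(expd, config) >= 0.99)
  }, numeric(1))
  sat_ok <- is.na(analytes$saturation_load) |
    analytes$saturation_load >= max(loads)
  n_good >= 3 & sat_ok & analytes$true_cv <= 0.2
}

`%|na|%` <- function(x, y) ifelse(is.na(x), y, x)

#' Generate a synthetic replicate/day reproducibility study
#'
#' Simulates the 5-replicates-per-day, 3-day reproducibility design: each
#' analyte's run intensity is `base x day_factor(day) x replicate_noise`,
#' detection is sampled from the logistic dropout model on the expected run
#' intensity, and each run's `ms2_tic` is its summed detected intensity plus
#' a background constant. The returned ground truth records every analyte's
#' true replicate CV, total (replicate + day) CV, base detection probability
#' and designed tier under the published gates.
#'
#' @param config A [simulation_config()] whose design has kind
#'   `"reproducibility"`.
#' @return List: `records`, `runs`, `design`, `ground_truth`.
#' @export
generate_reproducibility_study <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  stop_if_not_design(config$design, "reproducibility")
  set.seed(config$seed)
  analytes <- generate_analytes(config)
  design <- config$design
  grid <- tidyr::expand_grid(
    analytes,
    day = seq_len(design$n_days),
    replicate = seq_len(design$n_replicates_per_day)
  )
  day_fac <- matrix(
    stats::rlnorm(nrow(analytes) * design$n_days,
                  meanlog = -config$day_effect_sd^2 / 2,
                  sdlog = config$day_effect_sd),
    nrow = nrow(analytes)
  )
  idx <- match(grid$analyte_id, analytes$analyte_id)
  mu <- grid$base_intensity * day_fac[cbind(idx, grid$day)]
  s <- cv_to_sdlog(grid$true_cv)
  intensity <- mu * stats::rlnorm(nrow(grid), meanlog = -s^2 / 2, sdlog = s)
  detected <- stats::runif(nrow(grid)) < detect_prob(mu, config)

  grid <- grid %>%
    dplyr::mutate(
      run_id = sprintf("d%d_r%d", .data$day, .data$replicate),
      biofluid = config$biofluid, workflow = config$workflow,
      load_ng = config$load_ng,
      intensity = intensity, detected = detected
    )
  records <- grid %>%
    dplyr::filter(.data$detected) %>%
    dplyr::select(dplyr::all_of(c(
      "analyte_id", analyte_key_cols, "biofluid", "workflow", "run_id",
      "day", "replicate", "load_ng", "intensity"
    )))
  runs <- tidyr::expand_grid(
    day = seq_len(design$n_days),
    replicate = seq_len(design$n_replicates_per_day)
  ) %>%
    dplyr::mutate(
      run_id = sprintf("d%d_r%d", .data$day, .data$replicate),
      biofluid = config$biofluid, workflow = config$workflow,
      load_ng = config$load_ng
    ) %>%
    dplyr::left_join(
      records %>% dplyr::group_by(.data$run_id) %>%
        dplyr::summarise(total = sum(.data$intensity), .groups = "drop"),
      by = "run_id"
    ) %>%
    dplyr::mutate(
      ms2_tic = dplyr::coalesce(.data$total, 0) + config$tic_background
    ) %>%
    dplyr::select(dplyr::all_of(c(
      "run_id", "biofluid", "workflow", "day", "replicate", "load_ng", "ms2_tic"
    )))
  records <- records %>%
    dplyr::left_join(dplyr::select(runs, "run_id", "ms2_tic"), by = "run_id") %>%
    dplyr::arrange(.data$analyte_id, .data$run_id)

  ground_truth <- dplyr::bind_cols(
    analytes, designed_tiers(analytes, config)
  )
  list(records = records, runs = runs, design = design,
       ground_truth = ground_truth)
}

#' Generate a synthetic dilution (linearity) study
#'
#' Simulates triplicate injections across the design's dilution loads. Each
#' analyte responds proportionally through the origin — expected intensity
#' `base x min(load, saturation_load) / reference load` — observed with its
#' multiplicative replicate noise plus optional half-normal additive noise,
#' and detection from the logistic dropout model on the expected intensity.
#' The ground truth includes the designed LLOD (lowest load with detection
#' probability >= 0.99 and CV below the limit) and designed LLOQ (same, when
#' the designed response passes the linearity gate).
#'
#' @param config A [simulation_config()] whose design has kind `"linearity"`.
#' @return List: `records`, `runs`, `design`, `ground_truth`.
#' @export
generate_dilution_study <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  stop_if_not_design(config$design, "linearity")
  set.seed(config$seed)
  analytes <- generate_analytes(config)
  design <- config$design
  loads <- design$dilution_loads_ng
  thresholds <- qc_thresholds()

  grid <- tidyr::expand_grid(
    analytes,
    load_ng = loads,
    replicate = seq_len(design$n_replicates_per_load)
  )
  eff_load <- pmin(grid$load_ng, grid$saturation_load %|na|% Inf)
  mu <- grid$base_intensity * eff_load / config$load_ng
  s <- cv_to_sdlog(grid$true_cv)
  intensity <- mu * stats::rlnorm(nrow(grid), meanlog = -s^2 / 2, sdlog = s)
  if (config$noise_floor > 0) {
    intensity <- intensity + abs(stats::rnorm(nrow(grid), 0, config$noise_floor))
  }
  detected <- stats::runif(nrow(grid)) < detect_prob(mu, config)

  grid <- grid %>%
    dplyr::mutate(
      run_id = sprintf("L%g_r%d", .data$load_ng, .data$replicate),
      biofluid = config$biofluid, workflow = config$workflow,
      day = 1L, intensity = intensity, detected = detected
    )
  records <- grid %>%
    dplyr::filter(.data$detected) %>%
    dplyr::select(dplyr::all_of(c(
      "analyte_id", analyte_key_cols, "biofluid", "workflow", "run_id",
      "day", "replicate", "load_ng", "intensity"
    )))
  runs <- tidyr::expand_grid(
    load_ng = loads, replicate = seq_len(design$n_replicates_per_load)
  ) %>%
    dplyr::mutate(
      run_id = sprintf("L%g_r%d", .data$load_ng, .data$replicate),
      biofluid = config$biofluid, workflow = config$workflow, day = 1L
    ) %>%
    dplyr::left_join(
      records %>% dplyr::group_by(.data$run_id) %>%
        dplyr::summarise(total = sum(.data$intensity), .groups = "drop"),
      by = "run_id"
    ) %>%
    dplyr::mutate(
      ms2_tic = dplyr::coalesce(.data$total, 0) + config$tic_background
    ) %>%
    dplyr::select(dplyr::all_of(c(
      "run_id", "biofluid", "workflow", "day", "replicate", "load_ng", "ms2_tic"
    )))
  records <- records %>%
    dplyr::left_join(dplyr::select(runs, "run_id", "ms2_tic"), by = "run_id") %>%
    dplyr::arrange(.data$analyte_id, .data$run_id)

  lin_ok <- designed_r2_ok(analytes, config, thresholds)
  designed_llod <- vapply(seq_len(nrow(analytes)), function(i) {
    expd <- analytes$base_intensity[i] *
      pmin(loads, analytes$saturation_load[i] %|na|% Inf) / config$load_ng
    p <- detect_prob(expd, config)
    ok <- p >= 0.99 & 100 * analytes$true_cv[i] < thresholds$cv_limit_pct
    if (any(ok)) loads[which(ok)[1]] else NA_real_
  }, numeric(1))
  ground_truth <- analytes %>%
    dplyr::mutate(
      designed_r2_pass = lin_ok,
      designed_llod = designed_llod,
      designed_lloq = ifelse(lin_ok, designed_llod, NA_real_)
    )
  list(records = records, runs = runs, design = design,
       ground_truth = ground_truth)
}

#' Write the ground-truth sidecar table
#'
#' @param ground_truth Ground-truth tibble from a generator.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(ground_truth, path) {
  readr::write_csv(ground_truth, path, na = "")
  invisible(path)
}
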