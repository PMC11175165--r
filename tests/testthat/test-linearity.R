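ht_loads <- c(31.25, 62.5, 125, 250, 500, 1000)

test_that("exact proportional means give slope, zero intercept, r2 = 1", {
  pts <- mk_points(ht_loads[1:3], list(
    rep(62.5, 3), rep(125, 3), rep(250, 3)
  ))
  fit <- fit_dilution_curve(pts)
  expect_equal(fit$slope, 2, tolerance = 1e-9)
  expect_equal(fit$intercept, 0, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
})

test_that("a flat response gets r2 = 0 by convention", {
  pts <- mk_points(ht_loads[1:4], rep(list(rep(500, 3)), 4))
  fit <- fit_dilution_curve(pts)
  expect_equal(fit$r_squared, 0)
})

test_that("fewer than 3 qualifying loads means no fit", {
  pts <- mk_points(ht_loads[1:4], list(
    rep(10, 3), c(20), c(40), numeric(0)
  ))
  expect_null(fit_dilution_curve(pts))
})

test_that("fit matches the normal-equations oracle on noisy series", {
  set.seed(77)
  for (i in 1:50) {
    vals <- lapply(ht_loads, function(L) L * 3 * rlnorm(3, 0, 0.2))
    pts <- mk_points(ht_loads, vals)
    fit <- fit_dilution_curve(pts)
    orc <- oracle_ols(ht_loads, vapply(vals, mean, numeric(1)))
    expect_equal(fit$slope, orc$slope, tolerance = 1e-9)
    expect_equal(fit$intercept, orc$intercept, tolerance = 1e-9)
    expect_equal(fit$r_squared, orc$r_squared, tolerance = 1e-9)
    # pooled-replicate fit agrees with the oracle on the pooled points
    fitp <- fit_dilution_curve(pts, fit_on = "replicates")
    orcp <- oracle_ols(rep(ht_loads, each = 3), unlist(vals))
    expect_equal(fitp$slope, orcp$slope, tolerance = 1e-9)
    expect_equal(fitp$r_squared, orcp$r_squared, tolerance = 1e-9)
  }
})

test_that("back-calculated deviation matches hand computation", {
  expect_equal(back_calculated_deviation(250, 2, 0, 125), 0)
  expect_equal(back_calculated_deviation(300, 2, 0, 125), 0.2)
  # invariant to rescaling intensity and slope together
  expect_equal(back_calculated_deviation(300 * 7, 2 * 7, 0, 125), 0.2)
  expect_error(back_calculated_deviation(1, 0, 0, 10), "degenerate")
})

test_that("LLOD scan follows the 2-of-3 + CV<20 rule in load order", {
  # detections [1/3, 3/3 CV 25%, 3/3 CV 15%, ...] -> third load
  pts <- mk_points(ht_loads[1:4], list(
    c(30),
    c(75, 100, 125),          # CV 25%
    c(212.5, 250, 287.5),     # CV 15%
    c(480, 500, 520)
  ))
  expect_equal(determine_llod(pts), 125)
  # all loads clean -> lowest load
  clean <- mk_points(ht_loads[1:3], list(rep(10, 3), rep(20, 3), rep(40, 3)))
  expect_equal(determine_llod(clean), 31.25)
  # never >= 2 detections -> undefined
  sparse <- mk_points(ht_loads[1:3], list(c(1), numeric(0), c(4)))
  expect_true(is.na(determine_llod(sparse)))
})

test_that("LLOQ requires the analyte-level r2 gate before any load passes", {
  pts <- mk_points(ht_loads[1:4], list(
    rep(62.5, 3), rep(125, 3), rep(250, 3), rep(500, 3)
  ))
  fit <- fit_dilution_curve(pts)
  expect_equal(determine_lloq(pts, fit), 31.25)
  # failing r2 leaves LLOQ undefined regardless of per-load behavior
  bad_fit <- fit
  bad_fit$r_squared <- 0.75
  expect_true(is.na(determine_lloq(pts, bad_fit)))
  # boundary: r2 exactly at the threshold does not pass (strict >)
  edge_fit <- fit
  edge_fit$r_squared <- 0.8
  expect_true(is.na(determine_lloq(pts, edge_fit)))
})

test_that("LLOQ skips loads failing the deviation test", {
  # slope 2, intercept 0; load 125 deviates 30%, load 250 deviates 10%
  pts <- mk_points(c(125, 250, 500), list(
    rep(2 * 125 * 1.3, 3),   # back-calculated 162.5 -> deviation 0.3
    rep(2 * 250 * 1.1, 3),   # deviation 0.1
    rep(2 * 500, 3)
  ))
  fit <- list(slope = 2, intercept = 0, r_squared = 0.95,
              fit_loads = c(125, 250, 500), n_loads = 3)
  expect_equal(determine_lloq(pts, fit), 250)
})

test_that("LLOD and LLOQ scans match the brute-force oracle on random inputs", {
  set.seed(41)
  for (i in 1:150) {
    n_loads <- sample(4:7, 1)
    loads <- sort(10 * 2^(seq_len(n_loads)))
    vals <- lapply(loads, function(L) {
      k <- sample(0:3, 1)
      if (k == 0) numeric(0) else L * 2 * rlnorm(k, 0, runif(1, 0.02, 0.4))
    })
    pts <- mk_points(loads, vals)
    fit <- fit_dilution_curve(pts)
    llod <- determine_llod(pts)
    expect_identical(llod, oracle_llod(loads, vals))
    if (!is.null(fit)) {
      lloq <- determine_lloq(pts, fit)
      expect_identical(
        lloq,
        oracle_lloq(loads, vals, fit$slope, fit$intercept, fit$r_squared)
      )
    }
  }
})

test_that("LLOQ is never below LLOD on synthetic dilution studies", {
  cfg <- simulation_config(seed = 23, design = linearity_design(ht_loads),
                           n_proteins = 60, peptides_per_protein = 2,
                           dropout_midpoint = 4)
  st <- generate_dilution_study(cfg)
  lin <- assess_linearity(st$records, st$design)
  both <- !is.na(lin$llod_ng) & !is.na(lin$lloq_ng)
  expect_gt(sum(both), 0)
  expect_true(all(lin$lloq_ng[both] >= lin$llod_ng[both]))
})

test_that("limit summary counts the assessed universe correctly", {
  cfg <- simulation_config(seed = 29, design = linearity_design(ht_loads),
                           n_proteins = 40, peptides_per_protein = 2,
                           dropout_midpoint = 4.2)
  st <- generate_dilution_study(cfg)
  lin <- assess_linearity(st$records, st$design)
  s <- summarize_llod_lloq(lin)
  # brute-force recount from the raw records
  counts <- table(st$records$analyte_id,
                  factor(st$records$load_ng, levels = ht_loads))
  n_assessed <- sum(apply(counts >= 2, 1, any))
  expect_equal(s$n_assessed, n_assessed)
  expect_lte(s$n_with_lloq, s$n_with_llod)
  expect_lte(s$n_with_llod, s$n_assessed)
})

test_that("an analyte observed once at a single load is not assessed", {
  one <- mk_points(ht_loads[1:3], list(c(100), numeric(0), numeric(0)))
  lin <- tibble::tibble(
    assessed = any(one$n_detected >= 2),
    llod_ng = determine_llod(one),
    lloq_ng = NA_real_
  )
  s <- summarize_llod_lloq(lin)
  expect_equal(s$n_assessed, 0)
  expect_equal(s$n_with_llod, 0)
})

test_that("total signal equals hand-summed per-load means", {
  recs <- tibble::tibble(
    analyte_id = rep(c("a", "b", "c"), each = 2),
    load_ng = rep(c(100, 200), 3),
    run_id = rep(c("L100_r1", "L200_r1"), 3),
    intensity = c(10, 20, 1, 2, 5, 10)
  )
  ts <- total_signal_curve(recs)
  expect_equal(ts$load_ng, c(100, 200))
  expect_equal(ts$total_intensity, c(16, 32))
  # proportional analytes -> proportional totals
  expect_equal(ts$total_intensity[2] / ts$total_intensity[1], 2)
})

test_that("saturation pulls the top of the total-signal curve down", {
  cfg <- simulation_config(seed = 13, design = linearity_design(ht_loads),
                           n_proteins = 40, peptides_per_protein = 2,
                           cv_low = 0, fraction_high_cv = 0,
                           dropout_midpoint = -Inf,
                           fraction_saturating = 1, saturation_load = 250)
  st <- generate_dilution_study(cfg)
  ts <- total_signal_curve(st$records)
  ratio <- ts$total_intensity / ts$load_ng
  expect_lt(ratio[length(ratio)], ratio[1] * 0.5)
})
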