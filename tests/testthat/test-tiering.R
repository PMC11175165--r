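test_that("tier gates follow the published definitions on boundary cases", {
  prec <- dplyr::bind_rows(
    mk_precision_row("peptide|P1|PEPK|2", c(5, 4, 3), c(10, 11, 12), 12),
    mk_precision_row("peptide|P2|PEPK|2", c(3, 3, 2), c(10, 10, NA), NA),
    mk_precision_row("peptide|P3|PEPK|2", c(5, 5, 5), c(40, 42, 41), 45),
    mk_precision_row("peptide|P4|PEPK|2", c(5, 5, 5), c(24, 25, 26), 25),
    mk_precision_row("peptide|P5|PEPK|2", c(5, 5, 5), c(28, 29, 30), 30),
    mk_precision_row("peptide|P6|PEPK|2", c(0, 0, 0), c(NA, NA, NA), NA)
  )
  lin <- dplyr::bind_rows(
    mk_linearity_row("peptide|P1|PEPK|2", 0.93),
    mk_linearity_row("peptide|P4|PEPK|2", 0.75),
    mk_linearity_row("peptide|P5|PEPK|2", 0.99)
  )
  tiers <- classify_analytes(prec, lin)
  got <- setNames(as.character(tiers$tier), tiers$protein_accession)
  expect_equal(got[["P1"]], "quantifiable")   # [5,4,3], CV 12, r2 0.93
  expect_equal(got[["P2"]], "observable")     # [3,3,2]: day-3 gate fails
  expect_equal(got[["P3"]], "reliable")       # CV 45 >= 30
  expect_equal(got[["P4"]], "reproducible")   # CV 25 but r2 0.75 <= 0.8
  expect_equal(got[["P5"]], "reliable")       # CV exactly 30: strict <
  expect_equal(got[["P6"]], "none")
})

test_that("analytes absent from the linearity study cap at reproducible", {
  prec <- mk_precision_row("peptide|P1|PEPK|2", c(5, 5, 5), c(5, 5, 5), 6)
  no_lin <- classify_analytes(prec, NULL)
  expect_equal(as.character(no_lin$tier), "reproducible")
  other_lin <- mk_linearity_row("peptide|OTHER|PEPK|2", 0.99)
  expect_equal(as.character(classify_analytes(prec, other_lin)$tier),
               "reproducible")
})

test_that("threshold overrides flow through classification", {
  prec <- mk_precision_row("peptide|P1|PEPK|2", c(5, 5, 5), c(24, 25, 26), 25)
  lin <- mk_linearity_row("peptide|P1|PEPK|2", 0.93)
  default <- classify_analytes(prec, lin)
  expect_equal(as.character(default$tier), "quantifiable")
  strict_cv <- classify_analytes(prec, lin, qc_thresholds(cv_reproducible_pct = 20))
  expect_equal(as.character(strict_cv$tier), "reliable")
  strict_r2 <- classify_analytes(prec, lin, qc_thresholds(r2_min = 0.95))
  expect_equal(as.character(strict_r2$tier), "reproducible")
  strict_det <- classify_analytes(
    prec, lin, qc_thresholds(min_detections_per_day = 5)
  )
  expect_equal(as.character(strict_det$tier), "quantifiable")
  prec2 <- mk_precision_row("peptide|P1|PEPK|2", c(5, 4, 5), c(5, 5, 5), 6)
  expect_equal(
    as.character(classify_analytes(prec2, lin,
                                   qc_thresholds(min_detections_per_day = 5))$tier),
    "observable"
  )
})

test_that("per-day counts match hand computation and SD of daily counts", {
  # three analytes; day-level detections and intra-day CVs chosen by hand
  prec <- dplyr::bind_rows(
    mk_precision_row("peptide|A|PEPK|2", c(5, 5, 1), c(10, 10, NA), NA),
    mk_precision_row("peptide|B|PEPK|2", c(3, 0, 3), c(40, NA, 10), NA),
    mk_precision_row("peptide|C|PEPK|2", c(5, 5, 5), c(10, 10, 10), 10)
  )
  lin <- mk_linearity_row("peptide|C|PEPK|2", 0.95)
  pd <- per_day_tier_counts(prec, lin)
  expect_equal(pd$observable, c(3, 2, 3))
  expect_equal(pd$reliable, c(3, 2, 2))
  expect_equal(pd$reproducible, c(2, 2, 2)) # B day1 CV 40 fails
  expect_equal(pd$quantifiable, c(1, 1, 1))
  s <- summarize_tiers(classify_analytes(prec, lin), pd)
  expect_equal(s$mean_per_day[s$tier == "observable"], mean(c(3, 2, 3)))
  expect_equal(s$sd_per_day[s$tier == "observable"], sd(c(3, 2, 3)))
})

test_that("daily counts {213,214,219} summarize to mean 215.3, SD 3.2", {
  pd <- tibble::tibble(day = 1:3, observable = c(213, 214, 219),
                       reliable = 0, reproducible = 0, quantifiable = 0)
  asg <- classify_analytes(
    mk_precision_row("peptide|A|PEPK|2", c(5, 5, 5), c(1, 1, 1), 1), NULL
  )
  s <- summarize_tiers(asg, pd)
  expect_equal(s$mean_per_day[s$tier == "observable"], 215.3333, tolerance = 1e-4)
  expect_equal(s$sd_per_day[s$tier == "observable"], 3.214550, tolerance = 1e-5)
})

test_that("tier summary counts are cumulative and permutation-invariant", {
  prec <- dplyr::bind_rows(
    mk_precision_row("peptide|A|PEPK|2", c(1, 0, 0), c(NA, NA, NA), NA),
    mk_precision_row("peptide|B|PEPK|2", c(5, 5, 5), c(50, 50, 50), 50),
    mk_precision_row("peptide|C|PEPK|2", c(5, 5, 5), c(5, 5, 5), 6)
  )
  lin <- mk_linearity_row("peptide|C|PEPK|2", 0.95)
  asg <- classify_analytes(prec, lin)
  s <- summarize_tiers(asg)
  expect_equal(s$multi_day, c(3L, 2L, 1L, 1L))
  shuffled <- summarize_tiers(asg[c(3, 1, 2), ])
  expect_equal(shuffled$multi_day, s$multi_day)
  empty <- summarize_tiers(asg[0, ])
  expect_equal(empty$multi_day, rep(0L, 4))
})

test_that("non-redundant union tracks per-source membership", {
  mk_list <- function(accs) {
    tibble::tibble(
      analyte_id = paste0("protein|", accs, "||"),
      level = "protein", protein_accession = accs,
      peptide_sequence = "", charge = NA_integer_
    )
  }
  u <- combine_nonredundant(list(
    naive = mk_list(c("A", "B", "C")),
    depleted = mk_list(c("B", "C", "D"))
  ))
  expect_equal(nrow(u), 4)
  expect_equal(sum(u$in_naive & u$in_depleted), 2)
  expect_equal(nrow(combine_nonredundant(list(a = mk_list("A"), b = mk_list("A")))), 1)
  expect_error(
    combine_nonredundant(list(
      a = mk_list("A"),
      b = tibble::tibble(analyte_id = "peptide|A|SEQ|2", level = "peptide",
                         protein_accession = "A", peptide_sequence = "SEQ",
                         charge = 2L)
    )),
    "same level"
  )
})

test_that("union size obeys inclusion-exclusion against a brute-force count", {
  set.seed(90)
  mk_list <- function(accs) {
    tibble::tibble(
      analyte_id = paste0("protein|", accs, "||"),
      level = "protein", protein_accession = accs,
      peptide_sequence = "", charge = NA_integer_
    )
  }
  for (i in 1:30) {
    a <- sample(sprintf("P%02d", 1:30), sample(5:20, 1))
    b <- sample(sprintf("P%02d", 1:30), sample(5:20, 1))
    u <- combine_nonredundant(list(x = mk_list(a), y = mk_list(b)))
    expect_equal(nrow(u), oracle_union_size(a, b))
    expect_gte(nrow(u), max(length(a), length(b)))
    expect_lte(nrow(u), length(a) + length(b))
  }
})

test_that("ranking orders reliable analytes by mean intensity with id tie-break", {
  vals <- list(
    A = list(rep(10, 5), rep(10, 5), rep(10, 5)),
    B = list(rep(1000, 5), rep(1000, 5), rep(1000, 5)),
    C = list(rep(10, 5), rep(10, 5), rep(10, 5)),
    D = list(c(5, NA, NA, NA, NA), c(NA, NA, NA, NA, NA), c(NA, NA, NA, NA, NA))
  )
  rep <- mk_repro_report(vals)
  norm <- tic_normalize(rep$records, rep$runs)
  prec <- compute_precision(norm, rep$design)
  asg <- classify_analytes(prec, NULL)
  ranked <- rank_by_multiday_mean(asg, norm)
  expect_equal(nrow(ranked), 3) # D is only observable
  expect_equal(ranked$protein_accession, c("PROT_B", "PROT_A", "PROT_C"))
  expect_equal(ranked$rank, 1:3)
  # means/SDs match a brute-force recomputation
  for (i in seq_len(nrow(ranked))) {
    v <- norm$normalized_intensity[norm$analyte_id == ranked$analyte_id[i]]
    expect_equal(ranked$mean_intensity[i], mean(v), tolerance = 1e-12)
    expect_equal(ranked$sd_intensity[i], sd(v), tolerance = 1e-12)
  }
})
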