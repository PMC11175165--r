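---
title: "Characterizing DIA-MS assay performance: precision, linearity and proteome tiers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing DIA-MS assay performance: precision, linearity and proteome tiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proteotier)
```

## The analysis model

`proteotier` takes long-format DIA-MS quantification reports — one row per
analyte observation per run, with the design coordinates (biofluid,
workflow, day, replicate, on-column load) and the run's MS2 total ion
current — and characterizes each peptide and protein on two axes:

1. **Precision.** From a reproducibility design (by default 5 replicate
   digests per day on 3 consecutive days), per-day detection counts,
   intra-day CVs and a multi-day CV are computed on TIC-normalized,
   linear-scale intensities. A CV is only meaningful when enough
   observations back it: the intra-day CV requires at least 3 of the 5
   replicates detected that day, and the multi-day CV requires that gate on
   *every* day. Failing a gate yields an undefined CV (`NA`), never zero —
   a zero would masquerade as perfect precision.
2. **Linearity.** From a dilution design (triplicates across a 6- or
   7-point serial dilution), each analyte gets an ordinary least-squares fit
   of per-load mean intensity against load, an *r*² (squared Pearson
   correlation), per-load back-calculated accuracy, and the LLOD/LLOQ
   scans described below.

The two axes combine into four nested tiers — observable, reliable,
reproducible, quantifiable — assigned per biofluid × workflow at both
peptide and protein level. The tier vocabulary makes assay capability
explicit: "observable" only claims the analyte was seen; "quantifiable"
claims its relative intensity is precise (multi-day CV < 30%) *and* tracks
input amount linearly (*r*² > 0.8).

Key modeling assumptions: intensities are strictly positive when detected;
missingness is abundance-related but otherwise uninformative for CV
computation (detected intensities of a gated analyte are treated as an
unbiased sample); and the dilution response is locally linear in load over
the fitted range.

## Decision thresholds and their defaults

All gates live in one `qc_thresholds()` object:

| parameter | default | units | role |
|---|---|---|---|
| `cv_reproducible_pct` | 30 | % | multi-day (and per-day) CV bound for the reproducible tier |
| `cv_limit_pct` | 20 | % | per-load CV bound in the LLOD/LLOQ scans |
| `min_detections_per_day` | 3 | count (of 5) | detection gate per day |
| `min_detections_per_load` | 2 | count (of 3) | detection gate per dilution point |
| `r2_min` | 0.8 | — | linear-response bound (strict `>`) |
| `deviation_max` | 0.2 | fraction | back-calculated accuracy bound |

The CV comparisons are strict (`< 30`, `< 20`), and `r2_min` is a strict
lower bound, matching the printed conventions of assay-validation practice:
a CV of exactly 30% is *not* reproducible. Every stage receives thresholds
only through this object, which a test exercises by overriding each field
and observing the effect.

## Design choices where the convention is genuinely open

* **Multi-day CV = pooled CV.** The multi-day CV pools all qualifying
  observations (9–15 values) into one CV rather than averaging the three
  daily CVs. Pooling makes the statistic sensitive to day-to-day intensity
  shifts — which is precisely what distinguishes inter-day from intra-day
  precision. `multi_day_method = "mean_daily"` provides the alternative.
* **Protein roll-up = sum of detected peptide intensities per run.** Summing
  is the common label-free convention and conserves total signal; mean and
  median are available via `rollup_protein(method=)` because search engines
  differ. A protein is detected in a run iff at least one peptide is.
* **Peptide identity is precursor-resolved** (accession, sequence, charge)
  when charges are present; `collapse_charges = TRUE` sums charge states
  per run for stripped-sequence accounting. Reports in the wild use both
  conventions.
* **Normalization reference = median run TIC** within one biofluid ×
  workflow batch. Any TIC-derived reference is a common factor across the
  batch, so downstream CVs are provably identical for median, mean or unit
  references (a property test asserts this); the median merely keeps
  normalized values on a familiar scale when one run's TIC is aberrant.
* **LLOD/LLOQ on unnormalized intensities.** Detection limits describe what
  the instrument sees at a given load; normalizing by a TIC that itself
  scales with load would distort exactly the signal the limit rules
  interrogate. The linearity fit and *r*² use unnormalized intensities for
  consistency (`intensity_col` switches this).
* **Back-calculated accuracy passes at deviation ≤ 0.2.** An accuracy
  criterion bounds the deviation from above; the comparison direction is
  configurable (`deviation_greater_is_pass`) for users who want the
  opposite literal reading.
* **Quantifiable joins the two experiments by analyte identity.** An
  analyte never seen in the dilution study (or without a valid fit) caps at
  reproducible rather than being guessed at.
* **Per-day tiers** reuse the same gates within a single day: observable =
  detected that day, reliable = ≥ 3 detections that day, reproducible adds
  intra-day CV < 30%, quantifiable adds the (day-independent) *r*² gate.
  Per-day counts are definitionally independent of the multi-day counts —
  neither bounds the other — and both are reported.
* **Combined biofluids** (e.g. naive + depleted plasma) are the
  non-redundant union of the per-biofluid tier sets keyed by analyte
  identity, not a re-gating of pooled data: pooling runs from different
  matrices would mix incomparable TIC scales.
* **Dilution loads.** The default 6-point (31.25–1000 ng) and 7-point
  (39–2500 ng) series are 2-fold ladders spanning the workflows' published
  load ranges; the intermediate points are a reconstruction, and any
  strictly increasing series can be declared in `linearity_design()`.

## What the synthetic generator emulates

`generate_reproducibility_study()` and `generate_dilution_study()` draw a
shared analyte cohort (same seed ⇒ same analytes in both studies) and
simulate:

* **base abundance**: log10-uniform over `log10_mean_intensity_range`
  (default 3–8), spanning the dynamic range typical of blood-matrix DIA
  reports;
* **replicate noise**: multiplicative log-normal with
  `sdlog = sqrt(log(1 + CV²))` and mean 1, so the linear-scale CV equals
  the configured value exactly and intensities stay positive. The default
  mixture (80% of analytes at CV 10%, 20% at CV 45%) produces both clearly
  reproducible and clearly non-reproducible populations;
* **day effects**: a per-analyte, per-day log-normal factor
  (`day_effect_sd`, default 0.1 on the log scale) shared by the five
  replicates of that day. Because the factor is analyte-specific it
  survives TIC normalization and produces the expected intra-day < multi-day
  CV ordering; a factor shared across all analytes would be removed exactly
  by normalization;
* **dropout**: detection probability logistic in log10 expected intensity
  (`dropout_midpoint` = 3.0, `dropout_slope` = 3.0 by default), the simplest
  abundance-dependent missingness mechanism consistent with dilution-series
  detection behavior; `dropout_midpoint = -Inf` disables it;
* **dilution response**: proportional through the origin at the analyte's
  abundance per reference load, optionally clipped at a saturation load for
  a configurable fraction of analytes, plus optional half-normal additive
  noise (`noise_floor`);
* **run TIC**: the run's summed detected intensity plus a background
  constant, so normalization has real work to do.

Ground truth records each analyte's true CVs, detection probability,
designed tier and designed LLOD/LLOQ. The generator does **not** simulate
retention time, interference, co-elution, search-engine identification
error, or correlated peptide behavior within a protein; passing tests
demonstrate that the *rules* are implemented correctly and recoverable
under the stated noise model, not that any particular instrument will
achieve these numbers.

## Numerical choices and degenerate inputs

* CVs use the sample (n−1) standard deviation on linear-scale intensities;
  fewer than 2 values, or any non-positive value, is an error at the
  user-facing `cv_percent()` and an `NA` in the gated pipeline paths.
* A flat dilution response has zero variance and an undefined Pearson
  correlation; its *r*² is set to 0 by convention, which correctly fails
  the linearity gate rather than erroring.
* A zero or undefined fit slope makes back-calculation degenerate; LLOQ is
  undefined for such analytes and `back_calculated_deviation()` errors
  explicitly.
* `cv_at_fraction()` is the nearest-rank quantile (the `ceil(f·n)`-th order
  statistic): it always returns an attained CV value, matching how a
  threshold line is drawn on an empirical cumulative-frequency curve.
* Ranking ties on mean intensity break lexicographically by analyte
  identifier, making orderings deterministic.
* Undefined values serialize as empty CSV fields and JSON `null`, never 0.
* Fits use `stats::lm`; equality with the closed-form normal-equations
  solution is asserted to 1e-9 relative tolerance in the tests.

## Problem sizes

The test suite validates invariants on cohorts of 1000 analytes across 20
seeds (nesting), 3 seeds of 1000 analytes for designed-tier recovery, and
more than 1000 randomized small cases for oracle equivalence; the
acceptance script uses one 1200-peptide × 300-protein cohort per seed.
These sizes give stable statistics for population-level checks while
keeping a full run in the minutes range on a laptop.

## Known limitations

* The single-table report dialect cannot represent a run in which nothing
  was detected; such runs drop out of a written report (a warning is
  raised) though they are honored when passed in memory.
* Protein-level results inherit whatever biases the roll-up convention
  carries; summing detected peptides makes protein intensity depend on
  detection breadth at low abundance.
* The LLOD/LLOQ rules are scan rules on replicate detection, not model-based
  limit estimation (no limit-of-blank, no weighted calibration); they match
  the assay-characterization convention the package implements, and their
  resolution is bounded by the dilution-point spacing.
* CVs are reported without outlier rejection or variance decomposition;
  a mixed-model treatment of day and replicate variance is out of scope.
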