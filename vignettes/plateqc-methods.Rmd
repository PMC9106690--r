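---
title: "QC and repeatability analysis of targeted-metabolomics kit plates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{QC and repeatability analysis of targeted-metabolomics kit plates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plateqc)
```

## The problem

Commercial targeted-metabolomics kits report hundreds of compounds per
96-well plate, measured by two complementary acquisitions: liquid
chromatography–mass spectrometry (LC–MS, integrated peak areas) for amino
acids and biogenic amines, and flow-injection analysis (FIA–MS, peak
intensities) for lipid classes and the combined hexose signal. When such a
kit — validated for plasma or serum — is applied to dilute matrices like
adherent-cell lysates, most analytes fall below the vendor's lowest
calibration standard. The vendor software then refuses to quantify them,
even though the signals are clearly visible above background and perfectly
usable for *relative* quantification.

`plateqc` implements the data-processing cascade needed to work in that
regime, starting from exported area/intensity tables:

1. **Limit of detection (LOD)** per compound: three times the median signal
   of the PBS blank injections, with a hard noise floor of 20,000 counts
   (cps). A value survives only if it *strictly exceeds* the LOD — "above
   the LOD" is read literally, so a value equal to the LOD is rejected.
2. **Detection rule**: within a condition a compound is valid only if
   detected in at least 60% of the replicates present (normally 3 of 5).
3. **Internal-standard (IS) normalization**: each compound value is divided
   by the signal of its isotopically labelled internal standard in the same
   injection, correcting injection-to-injection variation.
4. **Whole-sample outlier rejection**: per condition, and separately for
   the LC and FIA blocks, each replicate's normalized values are summed;
   replicates outside `median ± 2.5 × MAD` of these sums are flagged. The
   MAD is *unscaled* (`median(|s − median(s)|)`, no 1.4826 normality
   constant). At most one replicate of five may be removed — a minimum of
   4 of 5 replicates is always retained — with the most extreme removed
   first and any surplus flags logged but not acted on.
5. **Detection re-check**: the 60% rule is re-evaluated against the
   replicates that survived outlier removal, so the denominator reflects
   what is actually there (configurable; on by default).
6. **Sparse-cell discard**: any compound/condition cell with fewer than 3
   surviving values is dropped.

Every removed value appears exactly once in an audit trail with the rule
that removed it (`lod`, `detection_60pct`, `istd_missing`, `outlier_mad`,
`sparse_lt3`); conservation (retained + rejected = non-missing input) is
enforced by construction and verified by the test suite at every stage.

Missing values are never imputed anywhere: they are excluded from sums,
counts, and RSDs. An empty cell in an input table is missingness; a zero is
a measured zero and goes through the LOD filter like any other value.

## Repeatability and condition comparison

Repeatability is summarized as the relative standard deviation,
RSD = 100·sd/mean (sample standard deviation, n−1), computed per compound
and condition on the retained normalized values. The reporting surface
follows the conventions of kit-evaluation studies: detected-compound counts
per class × condition, median RSD per measurement type and per class, and
the fraction of detected compounds with RSD strictly below a 15%
threshold, rendered as `"n/N (pct%)"` with percentages rounded
half-away-from-zero.

Conditions are compared non-parametrically. For each compound the
conditions are ranked by the metric (RSD, or a detected-count metric),
lowest = rank 1, ties averaged; this prevents compounds with huge absolute
RSDs from dominating. The per-condition rank samples are then tested with a
Kruskal–Wallis test and a Tukey–Kramer all-pairs post-hoc comparison on the
pooled ranks:

* `H = 12/(N(N+1)) · Σ nᵢ(R̄ᵢ − (N+1)/2)²`, divided by the tie correction
  `1 − Σ(t³−t)/(N³−N)`; p from χ² with k−1 degrees of freedom, or from
  exhaustive enumeration of group assignments for small pooled sizes
  (`p_method = "exact"`).
* Tukey–Kramer pair statistic
  `q = |R̄ᵢ−R̄ⱼ| / sqrt((N(N+1)/12)(1/nᵢ+1/nⱼ)/2)` against the
  studentized-range distribution with infinite degrees of freedom; with two
  groups this reduces exactly to the large-sample rank-sum comparison
  (`q = √2·z`), which the tests verify numerically.

Two behaviors are deliberately configurable because the underlying
procedure can be read either way:

* **Missing cells in the ranking** are ignored by default; an optional
  `missing = "worst_rank"` mode assigns them the bottom category instead,
  a sensitivity variant that markedly sharpens differences when
  non-detection is itself informative.
* The Tukey–Kramer test defaults to pooled-rank means (the standard
  post-Kruskal–Wallis construction); a raw-value variant is available via
  `compare_conditions(rank_based = FALSE)`.

No gating of the post-hoc test on the global p-value is enforced; the two
are reported side by side and the sequential reading is left to the
analyst.

## Dilution-series assessment

To establish where relative quantification is trustworthy, the
least-diluted calibration standard is serially diluted
(1:1.2, 1:1.4, 1:1.6, 1:1.8, 1:2, 1:3, 1:5, 1:7.5, 1:10, 1:15, 1:20, 1:30,
1:50, 1:100 — fourteen levels, three injections each). The criterion for a
usable range is deliberately simple: over the surviving levels, an
increasing concentration must be reflected by an increasing response.
Concretely, per compound:

* injections are LOD-filtered individually; a level survives if ≥ 2 of its
  injections do (a single survivor is too little to estimate a level mean,
  so such levels are dropped rather than estimated);
* the linear range is the longest contiguous run of levels, anchored at the
  least-diluted surviving level, over which level means strictly increase
  with concentration and the least-squares fit of mean response on relative
  concentration keeps R² ≥ 0.9 (both thresholds configurable);
* verdicts: `QUANTIFIABLE_RELATIVE` when the range spans the whole design
  ladder, `PARTIAL_RANGE` when any level is lost (to the LOD or to
  non-linearity), `EXCLUDED_BELOW_LOD` when everything fails the LOD or
  fewer than four levels survive.

The numeric R² criterion is a reconstruction: kit-evaluation practice
states the monotonicity aim but no formula, so the threshold is exposed in
the API and the verdict logic is pinned down by exact tests instead. The
Spearman correlation of level means versus relative concentration is
reported alongside as a scale-free monotonicity summary. Note that the FIA
compounds of this kit come with single-point calibration only, so
dilution-based verification is structurally limited to the LC panel in
kit-standard workflows; the assessment itself runs on any compound given
dilution records.

## The synthetic plate generator

Real plate exports from the motivating study design are not publicly
deposited, so the package carries a generator that emulates the statistical
structure the cascade assumes, giving every stage a ground truth:

* **Panel**: 408 compounds in 11 classes (amino acids 21, biogenic amines
  21, hexose 1, acylcarnitines 55, cholesteryl esters 14, diglycerides 18,
  triglycerides 42, phosphatidylcholines 172, lysophosphatidylcholines 24,
  sphingomyelins 31, ceramides 9; LC 42 / FIA 366). Amino acids and
  biogenic amines carry their standard names; the lipid species, which are
  not publicly enumerated for this kit, get systematic per-class names.
  One internal standard is shared per class — the real compound-to-standard
  map is proprietary, and normalization only needs a deterministic mapping.
* **Design**: six conditions (cell mass × loading volume combinations) with
  5 biological replicates, 3 PBS blanks, and 5 pooled QC injections per
  plate by default.
* **Signal model**: log-normal, parameterized so the *arithmetic* CV equals
  the configured `cv` (`sdlog² = log(1+cv²)`), giving strictly positive
  intensities and CV-faithful parameter recovery. Default signal 2×10⁵
  counts and CV 10%, both overridable per compound, class, or condition.
* **Blanks**: log-normal with median 2,000 counts (CV 50%). Blank signal
  distributions are not characterized in the literature for this kit; the
  default is a modelling choice, set so the 20,000-count floor binds by
  default while the 3×median rule can be made binding per scenario (the
  committed toy plate exercises both branches).
* **Planted pathologies**: whole-sample outliers (one scale factor applied
  to every compound of a chosen injection), compounds parked below the
  noise floor, and a global plate sensitivity multiplier that reproduces
  the "present in one run, filtered in the next" behavior of compounds
  sitting just above the noise threshold.
* **Determinism**: one seed, one stream, documented draw order (blanks,
  then samples by condition and replicate, then pooled QC; within an
  injection compounds in panel order, then internal standards). Identical
  seeds give bit-identical datasets.

What the generator does **not** emulate: chromatographic peak shapes,
batch-to-batch drift beyond the single sensitivity scalar, heteroscedastic
class-correlated matrix effects, or missingness mechanisms other than
falling below the LOD. Passing tests therefore demonstrate that the
cascade implements its rules correctly under a plausible noise model — not
that the rules are optimal for any particular real matrix.

## Numerical choices and degenerate inputs

* LOD combination is `max(3 × blank median, 20000)`: the floor applies
  whenever the blank-derived LOD is lower, and alone when no blank value
  exists (logged as `floor_only`).
* The LOD comparison is strict (`value > LOD` survives).
* MAD is unscaled; bounds are strict (a sum exactly on a bound is kept).
  When all replicate sums are equal the MAD is 0 and the bounds collapse
  onto the median: values equal to the median are inside, so nothing is
  flagged.
* Outlier-removal cap: `replicates − min_retained_replicates` per
  condition and measurement-type block, most-extreme-first, deterministic
  tie-break by replicate number.
* Kruskal–Wallis with all pooled values identical returns H = 0, p = 1 by
  convention (the tie correction degenerates to 0).
* RSD of a cell whose mean is non-positive is undefined and reported
  missing.
* Percent cells round half away from zero, reproducing the printed-table
  convention (22/27 → 81%, 158/366 → 43%, 183/408 → 45%).

## Known limitations, measured

Two properties of the published rules deserve emphasis, because the test
suite quantifies them rather than hiding them:

* **Small-sample RSD bias.** With n = 5 replicates the sample RSD is
  biased low: the median of 100·sd/mean over log-normal draws with true CV
  15% is ≈ 13.8%, and ≈ 22.2% at true CV 25% (about 0.92 × CV). The
  generator is CV-faithful; the estimator is not median-unbiased at n = 5.
  Tests that check parameter recovery therefore freeze Monte-Carlo oracle
  values of the estimator's sampling distribution, and recovery to within
  one percentage point of the *nominal* CV holds only for CVs up to ~10%.
* **MAD flagging at n = 5 is aggressive.** For five replicates the
  unscaled MAD of the sums is the third-smallest absolute deviation, and
  the probability that at least one clean replicate falls outside
  `median ± 2.5 × MAD` is ≈ 0.57 per block under the generator's model —
  which is precisely why the cascade caps removals at one of five. The
  cap, not the bound, is what keeps the rule safe; users comparing flag
  counts across conditions should treat flags as a screening signal, not
  as evidence of contamination.

Problem sizes used by the test suite and the acceptance script — 2,000
simulated conditions per CV level for recovery, 500 seeded plates for
outlier sensitivity, 200 randomized plates for the conservation and
monotonicity invariants, exhaustive enumeration for pooled sizes ≤ 8 —
were chosen so the whole suite runs comfortably on a laptop while keeping
Monte-Carlo error well inside the asserted tolerances.

## A worked run

```{r example, eval = FALSE}
library(plateqc)

panel <- load_panel("p400")
sim <- simulate_plate(scenario_config(
  panel = panel,
  outlier_samples = tibble::tibble(condition = "25mg_20uL",
                                   replicate = 2L, scale_factor = 10),
  below_floor_compounds = c("Carnosine", "Spermine"),
  seed = 1
))

qc <- run_qc(sim$plate)
qc
summary <- summarize_repeatability(qc)
summary$below_threshold

comparison <- compare_conditions(summary)
glance(comparison)
tidy(comparison)

autoplot(summary)       # RSD boxplots per condition
autoplot(qc)            # audit overview

dil <- simulate_dilution_series(scenario_config(panel = panel,
                                                true_mean = 2e6, seed = 2))
assessment <- assess_dilution(dil, compute_lod(sim$plate))
glance(assessment)
```
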