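# plateqc

Quality control, repeatability analysis and relative-quantification
assessment for targeted-metabolomics kit plates measured by LC–MS and
FIA–MS.

## Who this is for

Commercial targeted-metabolomics kits (408 compounds across 11 metabolite
classes in the panel modelled here: amino acids and biogenic amines by
liquid chromatography, lipid classes and hexose by flow-injection analysis)
are validated for plasma and serum. Applied to dilute matrices such as
adherent-cell lysates, most analytes fall below the kit's lowest
calibration standard: the vendor software declares them unquantifiable even
though their signals are well above background and perfectly usable for
*relative* quantification. `plateqc` is for analysts who work in that
regime and need a defensible, fully audited filter cascade from exported
area/intensity tables to condition-level repeatability statistics.

## What it computes

Starting from a wide plate export (one row per injection, one column per
compound or internal-standard signal), the pipeline applies, in order:

1. **LOD filter** — per compound, LOD = max(3 × median PBS-blank signal,
   20,000 counts); a value survives only if strictly above its LOD.
2. **Detection rule** — a compound is valid in a condition only if detected
   in ≥ 60% of the replicates present (normally 3 of 5).
3. **Internal-standard normalization** — value / signal of the mapped
   isotopically labelled standard in the same injection.
4. **Whole-sample outlier rejection** — per condition and per measurement
   block (LC, FIA), replicate sums of normalized values outside
   median ± 2.5 × MAD (unscaled) are flagged; at most 1 of 5 replicates is
   removed (minimum 4 of 5 retained), most extreme first.
5. **Detection re-check** on the surviving replicates, then **discard** of
   compound/condition cells with < 3 values.

On the retained values it reports repeatability as RSD = 100·sd/x̄ per
compound and condition, detected-compound counts per class, median RSD and
the fraction of compounds with RSD < 15% per measurement type, and compares
conditions with the rank-based procedure: per-compound ranks across
conditions (ties averaged, missing ignored or assigned a worst-rank
category), Kruskal–Wallis

> H = [12 / N(N+1)] Σ nᵢ (R̄ᵢ − (N+1)/2)² / [1 − Σ(t³−t)/(N³−N)]

with χ²-based or exact-enumeration p-values, followed by a Tukey–Kramer
all-pairs test on pooled rank means against the studentized-range
distribution. A serial-dilution module judges, per compound, over which
part of a 14-level 1:1.2…1:100 ladder the response still tracks
concentration (Spearman ρ, strict monotonicity of level means, R² ≥ 0.9),
issuing `QUANTIFIABLE_RELATIVE` / `PARTIAL_RANGE` / `EXCLUDED_BELOW_LOD`
verdicts.

A synthetic plate generator (`simulate_plate()`, log-normal signals with
CV-faithful parameterization, planted outliers, below-floor compounds, a
plate sensitivity multiplier, PBS blanks and pooled QCs) provides ground
truth for every stage; see the methods vignette
(`vignettes/plateqc-methods.Rmd`) for the model and its limits.

## Worked example

```r
library(plateqc)

panel <- load_panel("p400")                 # 408 compounds, 11 classes
sim <- simulate_plate(scenario_config(
  panel = panel,
  outlier_samples = tibble::tibble(condition = "25mg_20uL",
                                   replicate = 2L, scale_factor = 10),
  below_floor_compounds = c("Carnosine", "Spermine"),
  seed = 1
))

qc <- run_qc(sim$plate)
qc
#> <qc_result: 10882 of 12240 values retained; 1358 rejected (8 outlier injections); 406 compounds detected>
```

The two planted below-floor compounds are gone (406 of 408 detected), and
the planted whole-sample outlier is flagged in both measurement blocks —
its FIA replicate sum is 7440 against bounds [718, 771]:

```r
dplyr::filter(qc$outlier_flags, flagged & condition == "25mg_20uL")
#>   condition measurement_type replicate sum_norm center    mad lower upper flagged removed
#> 1 25mg_20uL FIA                      2   7440.   744.  10.7   718.  771.  TRUE    TRUE
#> 2 25mg_20uL LC                       2    813.    80.6  0.950  78.2  83.0  TRUE    TRUE
```

Repeatability, in the `"n/N (pct%)"` style of kit-evaluation reports
(n compounds with RSD < 15% out of N detected):

```r
summary <- summarize_repeatability(qc)
summary$below_threshold
#>    measurement_type condition n_below n_detected label
#>  1 FIA              15mg_10uL     322        366 322/366 (88%)
#>  ...
#> 10 LC               25mg_20uL      38         40 38/40 (95%)
```

Rank-based condition comparison (Kruskal–Wallis on per-compound RSD ranks,
then Tukey–Kramer pairs):

```r
glance(compare_conditions(summary))
#>   statistic    df    p.value n_pairs_significant alpha
#> 1      32.9     5 0.00000397                   3  0.05
```

Every removed value is in `qc_audit(qc)` with its rule (`lod`,
`detection_60pct`, `istd_missing`, `outlier_mad`, `sparse_lt3`), and
`write_report()` emits the normalized matrix, the class × condition
detected-count table, the RSD summary and a machine-readable audit JSON.
`autoplot()` methods draw the RSD boxplots, dilution response curves and
audit overview.

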