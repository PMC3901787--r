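---
title: "The marker-ratio method: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The marker-ratio method: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(markerdig)
```

## The problem

Apparent dry-matter digestibility (DMD) of a forage is classically measured
*in vivo* by total fecal collection: weigh everything an animal eats and
everything it excretes over a collection window. That is accurate but
labor-intensive, which limits how many animals and forages can be screened.
The marker-ratio technique replaces the fecal weighing with chemistry: an
*internal marker* is a dietary constituent assumed indigestible and fully
recovered in feces, so its concentration must rise from feed to feces in
exact proportion to how much of the diet disappeared. `markerdig`
implements this technique for trials with three candidate markers —
acid-detergent lignin (ADL), alkaline-peroxide lignin (APL) and
acid-detergent insoluble ash (ADIA) — and validates it against
total collection.

## The model

All masses are grams of dry matter (DM) and all concentrations g/kg DM.
For one animal-period ("cell"), with hay offered $Q_{of}$ at marker
concentration $M_{of}$, orts (refusals) $Q_{or}$ at concentration
$M_{or}$, fecal DM output $FO$ and fecal marker concentration $M_{fc}$:

* consumed-marker concentration
  $M_{fd} = (M_{of}Q_{of} - M_{or}Q_{or}) / \mathrm{DMI}$, with
  $\mathrm{DMI} = Q_{of} - Q_{or}$ (`consumed_marker_conc()`);
* fecal recovery
  $R = M_{fc}\,FO / (M_{of}Q_{of} - M_{or}Q_{or})$ (`marker_recovery()`);
* marker-based digestibility
  $\mathrm{DMD} = 1000\,(1 - M_{fd}/M_{fc})$ (`dmd_estimate()`);
* marker-based fecal output
  $FO = \mathrm{DMI}\, M_{fd}/M_{fc}$ (`fo_estimate()`).

Two consequences are load-bearing and are enforced as tested invariants.
First, the DMD and FO estimators are two views of one quantity:
`dmd_estimate(m_fd, m_fc)` equals
`observed_dmd(dmi, fo_estimate(dmi, m_fd, m_fc))` identically. To keep
that identity exact, the DMI in the denominator of $M_{fd}$ is always the
one computed from the same intake records, never an independently supplied
value. Second, if the true recovery is $R$ and assays are noise-free, the
method's bias has closed form: the FO estimate is $FO_{true}/R$ and the
DMD estimate is $1000 - (1000 - \mathrm{DMD}_{true})/R$. A marker is
unbiased exactly when $R = 1$; an over-recovered marker such as ADL
($R \approx 1.16$ on bermudagrass) must underestimate FO by
$100\,(1 - 1/R) \approx 13\%$ and overestimate DMD correspondingly. The
simulator plus `marker_estimates()` reproduce both facts to 1e-9.

Assay-side arithmetic is included for the two gravimetric fractions
(`adia_fraction()`: residual ash over initial sample mass;
`apl_fraction()`: ash-corrected lignin residue over initial sample mass)
and for the laboratory QC rule: duplicates are accepted as their mean when
the coefficient of variation is at most 5%, otherwise rerun
(`duplicate_cv_check()`). Proximate derivations are
hemicellulose = NDF − ADF and organic matter = 1000 − total ash
(`proximate_derive()`).

## Data model and units

A trial is five CSV-backed tables (`read_trial()`/`write_trial()`): diet
composition, the design, daily intake, daily fecal output and
replicate-level assays. Design decisions worth stating:

* Everything is stored on a DM basis in grams; `as_fed_to_dm()` converts
  field records at ingest. Daily rows are kept in the files but summed to
  animal × period totals before any ratio is computed — a 5-d collection
  is one observation per cow-period.
* A missing ort row means nothing was refused: $Q_{or} = 0$ and the ort
  term drops out. Restricted feeding is designed to minimize refusal, so
  zero orts is a normal case, not missing data.
* Assay materials are keyed as `hay:<animal>:<period>`,
  `ort:<animal>:<period>`, `feces:<animal>:<period>`, with a pooled
  `diet:<diet_id>` key also accepted for offered hay. Whether ort and hay
  samples are assayed per cell or pooled is a lab choice; the schema
  supports both, and resolution prefers the per-cell assay.
* A negative consumed-marker concentration (arithmetically possible when
  the ort assay exceeds the offered assay enough) is an error, not a
  clamp: it indicates inconsistent assays and should stop the analysis.
* Fecal output at or above DMI is physiologically implausible but can
  arise from recording slips; it warns rather than fails.

## The simulator

`simulate_trial()` generates trials with known ground truth so that every
stage of the pipeline is testable without animal data. The default
configuration is the reference trial layout: 8 cows in 2 weight blocks,
4 bermudagrass-hay diets (L/ML/MH/H, 79–164 g CP/kg), 3 periods with 2
diet replicates per period, 5 collection days. `make_youden_design()`
builds the assignment from randomized rows of a cyclic Latin square per
block, which guarantees the two design invariants (equal diet replication
within each period; no animal repeats a diet) by construction for any
seed.

Quantitative defaults, chosen once:

* body weight ~ Normal(594, 35.5) kg, drawn once per animal and held
  across periods;
* hay offered at 20 g DM per kg body weight per day. (Field practice
  quotes the feeding rate as-fed; carrying it on a DM basis keeps the
  generator in the units the equations consume and changes nothing
  structurally.)
* diet true DMD {504, 550, 538, 564} g/kg and offered-hay marker
  concentrations per diet taken from the reference trial's consumed-hay
  table; true recoveries ADL 1.16, APL 1.06, ADIA 1.03;
* refusal fraction ~ Normal(0.05, 0.02) truncated to [0, 0.9] per
  animal-period, with non-selective refusal (ort concentration = offered
  concentration) by default — ort composition is rarely reported, so
  selectivity is an exposed knob, not a fitted value;
* duplicate assays carry independent multiplicative Gaussian noise with
  CV 2.5% (half the QC limit), truncated at zero, and pairs failing the
  5% CV rule are redrawn, mimicking the rerun procedure.

Truth is exact by construction: true FO = DMI × (1 − DMD/1000), so
digested mass plus FO balances DMI; the true fecal concentration is
$R \times$ (marker consumed)/FO, so noise enters only through assays.
One integer seed makes output byte-identical across runs. Draw order is
documented (design, body weights, refusals, then assays cell-by-cell),
but seeds are portable only at the statistical level across
implementations.

What the generator does **not** emulate: passage-rate kinetics and
marker digestion dynamics (recovery is imposed, not mechanistic),
adaptation-period carryover, soil contamination of ADIA, day-to-day
intake variation within a period, and animal-level variation in recovery.
Passing tests therefore show that the estimators invert the generative
model they assume — they do not certify any marker's behavior on real
feces.

## Summaries and inference

`recovery_table()` and `estimates_table()` aggregate per-cell estimates
into the conventional diet × method tables, with total collection (TC) as
the reference row; `bias_summary()` reports each marker's method mean as
a percent deviation from TC. Cells are carried at full precision;
report-style rounding (half-up; recoveries to 2 decimals, DMD to 1 g/kg,
FO to 10 g for method means and 1 g for diet means, as such tables are
conventionally printed) is applied only at display time, because printed
tables are rounded model-adjusted means and cannot serve as internal
precision standards. `summary_table()` accepts externally reported row
means alongside cells for exactly that reason: in the reference trial the
ADL FO method mean (3,660) is not the arithmetic mean of its printed
cells (3,655), a least-squares-means artifact, so reproductions from
printed cells treat only the arithmetically consistent aggregates as
recomputable.

Two inferential choices replace the original SAS mixed-model machinery,
deliberately:

* **Adjusted means.** `fit_adjusted_means()` uses fixed-effects OLS
  (diet + period + block) with `emmeans` for the adjusted means, instead
  of REML with random block and period. With 2 blocks and 3 periods,
  random-effect variances are essentially unidentifiable; on balanced
  data the OLS adjusted means coincide with both the arithmetic means and
  the REML LSMEANS, and under imbalance they still remove additive
  period/block effects (tested with an injected period effect).
  Pairwise-comparison letters are not reproduced.
* **Recovery ≠ 1.** `recovery_vs_one_test()` is a percentile bootstrap of
  the mean per-cell recovery with a two-sided p-value, replacing the
  F-protected t-test. It is deterministic given a seed, assumption-light,
  and its size was verified by simulation: at a true recovery of 1 with
  2.5% assay CV, the rejection rate at $\alpha = 0.05$ over 500 simulated
  trials falls within [0.03, 0.07]. With only 24 cells the percentile
  bootstrap runs slightly liberal (~0.06); that is accepted rather than
  corrected, since the test's role here is descriptive.

## Numerical and degenerate-input policy

Division guards are errors with condition classes
(`markerdig_validation_error`, `markerdig_reference_error`,
`markerdig_schema_error`): zero consumption, zero fecal concentration,
zero marker intake, fewer than 2 assay replicates. Negative DMD estimates
are allowed (a failing marker can produce them) but warn. Bootstrap edge
case: identical recoveries give a degenerate CI at the point value with
p ∈ {0, 1}. CSV round-trips preserve numerics to better than 1e-9
(shortest round-trip double formatting). Half-up rounding adds a 1e-9
epsilon before truncation so exact-decimal ties round up as intended.

## Problem sizes

The verification suite uses the trial's own dimensions (24 cells,
3 markers) for exact checks; simulation-based calibration uses 200 trials
for parameter recovery (configured recoveries re-estimated to within 2
Monte-Carlo standard errors) and 500 trials × 1000 resamples for the
bootstrap size check. These sizes put the Monte-Carlo standard error of a
recovery mean near 4e-4 and of the rejection rate near 0.01, small enough
to make the pass bands meaningful.

## Worked example

```{r example, eval = FALSE}
trial <- simulate_trial(sim_config(seed = 42))
res <- analyze_trial(trial, seed = 42)
res$recovery   # diet x marker recovery table
res$bias       # FO/DMD bias of each marker vs total collection
res$tests      # bootstrap tests of recovery = 1
```

The same pipeline runs from a shell:

```sh
markerdig simulate --seed 42 --out trial/
markerdig analyze --in trial/ --out results/ --seed 42
markerdig report --in trial/ --out report.md
```
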