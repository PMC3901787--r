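# markerdig

Internal-marker estimation of fecal output and dry-matter digestibility
in cattle feeding trials.

## The problem

Apparent dry-matter digestibility (DMD) is the reference quantity of
forage evaluation, classically measured by *total fecal collection*:
weigh all feed offered, all orts (refusals) and all feces over a
collection window. That is accurate but too laborious to screen many
animals or forages. The *marker-ratio technique* instead tracks an
internal marker — an indigestible dietary constituent such as
acid-detergent lignin (ADL), alkaline-peroxide lignin (APL) or
acid-detergent insoluble ash (ADIA) — whose concentration rises from
feed to feces in proportion to the DM that disappeared. `markerdig` is
for ruminant-nutrition researchers who run such trials: it computes the
marker estimates, quantifies each marker's fecal recovery, and validates
markers against total collection on replicated Youden-square (incomplete
Latin square) crossover designs.

## The method

All masses in g DM, concentrations in g/kg DM. For one animal-period,
with hay offered Q_of at marker concentration M_of, orts Q_or at M_or,
fecal output FO at fecal concentration M_fc, and DMI = Q_of − Q_or:

    M_fd = (M_of·Q_of − M_or·Q_or) / DMI        marker in consumed forage
    R    = M_fc·FO / (M_of·Q_of − M_or·Q_or)    fecal recovery
    DMD  = 1000·(1 − M_fd / M_fc)               marker-based digestibility
    FO   = DMI·M_fd / M_fc                      marker-based fecal output

An ideal marker has R = 1. With true recovery R and noise-free assays the
bias is closed-form: the FO estimate is FO/R and the DMD estimate is
1000 − (1000 − DMD)/R — so an over-recovered marker (ADL, R ≈ 1.16 on
bermudagrass) underestimates FO by ~13% and overestimates DMD by ~11%.
The package also provides assay arithmetic (gravimetric ADIA/APL
fractions, the 5% duplicate-CV QC rule), proximate derivations
(hemicellulose = NDF − ADF, OM = 1000 − ash), validated CSV I/O for trial
records, a seeded trial simulator with known ground truth, diet × method
summary tables with bootstrap inference on recovery, and a CLI.

## Worked example

```r
library(markerdig)
trial <- simulate_trial(sim_config(seed = 42))  # 8 cows x 3 periods x 4 diets
res <- analyze_trial(trial, seed = 42)
res$recovery
#> <summary_table: recovery, rounding = none>
#>      item       L      ML      MH       H    mean
#> 1    ADIA 1.04566 1.03649 1.03951 1.01513 1.03420
#> 2     ADL 1.16090 1.16697 1.16597 1.14252 1.15909
#> 3     APL 1.05324 1.06082 1.05926 1.05554 1.05721
#> 4 Average 1.08660 1.08809 1.08825 1.07106      NA
res$bias
#>   method fo_bias_pct dmd_bias_pct
#> 1 ADIA         -3.30         2.81
#> 2 ADL         -13.7         11.7
#> 3 APL          -5.34         4.58
res$tests
#>   marker_name mean_recovery ci_low ci_high p_two_sided     n
#> 1 ADIA                 1.03   1.02    1.05           0    24
#> 2 ADL                  1.16   1.15    1.17           0    24
#> 3 APL                  1.06   1.05    1.07           0    24
```

Reading the output: the simulated trial was configured with true
recoveries ADL 1.16, APL 1.06, ADIA 1.03 and 2.5% assay noise; the
pipeline re-estimates those recoveries from the generated records
(`res$recovery`, row means 1.159/1.057/1.034). The bias table shows the
consequence — ADL's over-recovery makes it underestimate FO by ~14% and
overestimate DMD by ~12% relative to total collection, while APL and
ADIA stay within ~5% — and the bootstrap tests reject recovery = 1 for
every marker at these settings.

The same pipeline runs from a shell via the installed script:

```sh
markerdig simulate --seed 42 --out trial/
markerdig analyze --in trial/ --out results/ --seed 42
markerdig report --in trial/ --out report.md
```

See `vignettes/marker-digestibility.Rmd` for the model's assumptions,
the simulator's defaults and what they emulate, and the package's
statistical design choices.

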