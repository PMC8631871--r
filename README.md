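# rosettecast

Top-view rosette phenotyping from tray image to yield proxy: `rosettecast`
implements a complete, testable analysis pipeline for high-throughput
phenotyping (HTPP) of rosette plants such as *Arabidopsis* — tray-image
preprocessing with fiducial markers, trainable semantic segmentation and its
evaluation metrics, shape-feature extraction, stage-windowed multi-horizon
forecasting of projected area, and allometric fresh-weight estimation chained
onto the forecasts. Because real HTPP imagery is rarely shareable, the package
includes a first-class synthetic-data generator that reproduces the
statistical structure every downstream stage assumes, so the whole pipeline
runs and is verified without any external data.

It is aimed at plant-phenotyping researchers and image-analysis developers who
want a reference implementation of this pipeline whose every stage is covered
by property-based tests.

## The analysis

**Time model.** Plants are imaged hourly during the photoperiod only: 12
captures per day from 08:00, over 10–23 days after sowing (DAS), giving a
165-step grid. Decimal DAS appends the clock hour over 24 (22 DAS at 17:00 →
22.71). One measured step ≡ one daylight hour, so 12 steps ≡ 1 day.

**Segmentation metrics and losses.** With per-pixel confusion counts TP, FP,
FN between predicted mask A and ground truth B:

    IoU  = |A ∩ B| / |A ∪ B|
    P    = TP / (TP + FP),  R = TP / (TP + FN)
    Fβ   = (1 + β²) P R / (β² P + R)

Training uses the combined loss `L = L_dice + L_focal`, where
`L_dice = 1 − soft-Fβ` on predicted probabilities and
`L_focal = mean( −α_t (1 − p_t)^γ log p_t )` with α = 0.25, γ = 2.

**Forecasting.** For each plant and each horizon h ∈ {1, 6, 12, 24, 36, 42,
48} measured hours, a direct model (gradient-boosted trees by default, OLS as
a baseline) maps the most recent lagged shape features (PA, convex hull area,
compactness; lookback 48 steps, capped per window) to PA at t + h. Six
training windows over the early pre-flowering stage (T1–T4 ending at step
140 ≈ 21 DAS, T5–T6 ending at step 127 ≈ 20 DAS) are compared on the late
pre-flowering test period by MAE and RMSE, with global errors averaged over
plants and horizons.

**Fresh weight.** An OLS allometry FW ~ PA fitted on destructive harvests at
14/17/20 DAS converts late-stage PA forecasts into predicted fresh weight,
scored by Spearman rank correlation against held-out harvests.

**Validation.** At the final checkpoint step the per-window predictions are
compared by one-way ANOVA, Tukey HSD at 95% family confidence, paired
observed-vs-predicted t-tests (significance at α = 0.01), and Spearman R.

## Worked example

```r
library(rosettecast)

records <- simulate_growth_curves(growth_sim_config(n_plants = 24, seed = 1))
cfg <- forecast_config(learner = "gbt", seed = 1)
cmp <- compare_windows(records, table1_windows(), cfg)
cmp$summary
#>   window global_mae global_rmse    n
#> 1     T1      0.463       0.546 2832
#> 2     T2      0.460       0.545 2832
#> 3     T3      0.471       0.558 2832
#> 4     T4      0.480       0.565 2760
#> 5     T5      0.516       0.599 3720
#> 6     T6      0.515       0.595 3624
```

Global MAE is in the generator's area units (plateau ≈ 10 units). The
shortened windows T1–T4 perform alike — training from 17 DAS (T3) loses
almost nothing against training from 15 DAS (T1) — while T5/T6, whose
training stops a day earlier, degrade. The statistical protocol quantifies
this at the 23-DAS checkpoint:

```r
report <- validation_report(cmp$checkpoints[cmp$checkpoints$time_step == 165, ])
report
#> Validation at step(s) 165
#> ANOVA across groups: F = 0.0824, p = 0.9978
#>
#> Observed vs predicted per window:
#>  window     t_p spearman_r  n significant
#>      T1 0.42150     0.8965 24       FALSE
#>      T2 0.44920     0.8843 24       FALSE
#>      T3 0.58020     0.8835 24       FALSE
#>      T4 0.91800     0.8304 24       FALSE
#>      T5 0.15420     0.8426 24       FALSE
#>      T6 0.09788     0.8609 24       FALSE
#> ...
```

No window's predictions differ significantly from the observations at this
sample size, and observed/predicted rank correlations are ~0.83–0.90.

An end-to-end run (simulation → tray rendering → marker detection →
rectification → segmentation → features → forecasts → fresh-weight chain →
validation report, with a checksum manifest) is one call:

```r
manifest <- run_pipeline(pipeline_config(seed = 1, out_dir = "run1"))
```

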