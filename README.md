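# mowsense

Detection of grassland mowing events from sparse satellite time series.

National paying agencies verify that subsidised grasslands are actually
mown during the vegetation season. Field visits do not scale, but two
satellite signals carry the mowing signature: the Sentinel-2 **NDVI**
drops sharply when grass is cut, and the Sentinel-1 6-day repeat-pass
**interferometric coherence** (VV and VH polarization) rises and stays
elevated for roughly 24–36 days while the cut field's scatterers are
stable. Both signals are sparse and noisy — around 75% of NDVI
acquisitions are cloud-invalid, and cloud-mask failures leave isolated
spurious NDVI drops.

`mowsense` turns per-field observation tables (`field_id, date, ndvi,
cohvv, cohvh`) into daily mowing probabilities and event decisions:

1. **Preprocessing** — cloud-mask outliers are removed with a triplet
   rule: for three consecutive valid NDVI measurements within 10 days,
   the middle one is dropped when
   `ndvi_3 − 2·ndvi_2 + ndvi_1 ≥ 0.6`.
   Coherence is smoothed with an exponential moving average
   (`out_n = α·in_n + (1−α)·out_{n−1}`, α = 1/3; a width-7 moving
   average is also available), then every channel is linearly
   interpolated onto a fixed 215-day April–October season grid.
2. **Features** — 14 per-day features: the three raw channels, the
   normalized day of year `t = doy/365`, the min–max-scaled observation
   gap `dt`, smoothed coherences, the mixed coherence
   `√(cohvh·cohvv)`, and difference/slope features between consecutive
   real measurements.
3. **Detector** — a three-layer 1-D convolutional network
   (conv → channel-softmax → batch-norm, twice, then conv → sigmoid)
   maps the `215 × 14` series to a length-215 vector of daily mowing
   probabilities. Training minimises binary cross-entropy with the
   Nadam optimizer (β₁ = 0.9, β₂ = 0.999, schedule_decay = 0.004) and
   early stopping.
4. **Evaluation** — daily probabilities are decoded into events
   (maximal runs above a threshold); a predicted start matches an
   actual start within a −3/+6-day window; event accuracy is
   `(TP+TN)/(TP+TN+FP+FN)`. End-of-season (EOS) accuracy scores the
   binary mown/not-mown status from a season-level score, and a
   rank-based ROC AUC summarises separation.
5. **Reject region** — an abstention interval `(t_low, t_upper)` over
   season scores is fitted on validation data so that requested
   true-positive and true-negative rates are met; scores inside the
   interval are referred to a human expert.

No satellite data ship with the package: a synthetic generator
(`simulate_dataset()`) reproduces the phenomenology of the real data —
half-oval seasonal NDVI curves, mowing signatures, 4/6-day observation
cadences, 75% cloud invalidation, rare outliers, rain-suppressed
coherence — so the entire pipeline is testable offline.

## Worked example

```r
library(mowsense)

res <- run_pipeline(
  sim = sim_config(n_fields = 1000, seed = 101),
  model_cfg = model_config(learning_rate = 1e-3, max_epochs = 120,
                           early_stopping_patience = 15, seed = 101))
#> simulating 1000 field-seasons
#> preprocessing onto the 215-day grid
#> training on 640 fields (validating on 160)
#> best epoch 110, validation BCE 0.06849
#> test: event accuracy 0.843, EOS accuracy 0.955, AUC 1.000
#> reject region (0.678, 1.000): 7.5% rejected, 1.000 retained accuracy
```

Reading the output: of the held-out 200 test fields, 84.3% of
event-level decisions (true positives within the −3/+6-day window, true
negatives, and the error counts) are correct; 95.5% of fields get the
right mown/not-mown season status; the season-score AUC of 1.0 means
mown and unmown fields separate completely on this synthetic draw. The
reject region fitted on validation scores abstains on 7.5% of test
fields, and every retained decision is correct.

Individual stages are exposed as plain functions
(`filter_ndvi_outliers()`, `ema_smooth()`, `interpolate_daily()`,
`build_feature_matrix()`, `train_model()`, `match_events()`,
`fit_reject_interval()`, …), and `inst/scripts/mowsense` provides a
command-line wrapper (`simulate`, `preprocess`, `featurize`, `train`,
`predict`, `evaluate`, `select-features`, `reject-fit`, `reject-apply`,
`sweep`).

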