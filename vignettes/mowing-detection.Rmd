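---
title: "Detecting grassland mowing events from coherence and NDVI time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting grassland mowing events from coherence and NDVI time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The detection problem

A mown grassland parcel leaves a joint fingerprint in two satellite
signals. The Sentinel-2 NDVI, a proxy for live green biomass, drops
sharply when the grass is cut and recovers over a few weeks of
regrowth. The Sentinel-1 6-day repeat-pass interferometric coherence
(VV and VH) measures how stable a field's radar scatterers are between
two acquisitions: cut stubble is stable, so coherence rises after
mowing and stays elevated for roughly 24–36 days. Neither signal alone
is reliable — NDVI is unavailable under cloud (about three quarters of
acquisitions in the Baltic study region are invalid) and coherence is
depressed by rain — which is why the detector consumes both.

`mowsense` frames detection as *daily sequence labelling*: every
field-season is mapped onto a fixed 215-day April–October grid, and the
model emits one mowing probability per day. Event decisions,
season-level (mown / not mown) decisions, and an abstention mechanism
are all derived from that daily vector.

## Preprocessing

**Cloud-mask outliers.** Residual cloud-mask failures appear as single
isolated NDVI drops, never as runs. For every three consecutive valid
NDVI measurements whose first and third values lie within 10 days, the
middle one is removed when

$$ndvi_3 - 2 \cdot ndvi_2 + ndvi_1 \ge 0.6 .$$

The 10-day span guard protects genuine mowing drops, whose signature
can recover within about 10 days. All triplets are evaluated on the
original values and removals applied in a single pass, so the result
does not depend on enumeration order; endpoints can never be triplet
centres and are never removed.

**Coherence smoothing.** Coherence is noisy and is smoothed *on the
valid measurements, before interpolation* — smoothing an interpolated
daily series would let long gaps dominate the filter state. Whether to
smooth before or after gridding is a genuinely open design point; we
chose before, and the tests pin that contract. The default is the
exponential moving average
$out_1 = in_1,\; out_n = \alpha\,in_n + (1-\alpha)\,out_{n-1}$ with
$\alpha = 1/3$; a centred moving average (odd width, default 7, window
truncated symmetrically at the edges) is available as an alternative.
NDVI is filtered but deliberately not smoothed: smoothing would blur
the very drop the detector looks for.

**Daily grid.** Each channel is linearly interpolated onto integer days
0–214; beyond the first/last measurement the nearest value is held
constant. A per-channel validity mask records which grid days carry a
real measurement. A channel with no valid measurement at all in a
season (possible under extreme cloud cover) is filled with a season
constant (NDVI 0.5, coherence 0.3) and reported; this case has no
natural answer and the constants simply keep the tensor finite.

## The 14 features

Per grid day: `ndvi`, `cohvv`, `cohvh`, normalized day of year
`t = doy/365` (Jan 1 = day 1; normalized once, globally, so that batch
normalization cannot distort a feature whose small differences are
meaningful), the min–max-scaled gap `dt` since the previous real
measurement (statistics from the training split only, clipped to [0,1]
on unseen extremes; it distinguishes real from interpolated days),
smoothed coherences `cohvv_sm`/`cohvh_sm`, the mixed coherence
`mixed_coh = sqrt(cohvh * cohvv)` (a geometric mean; the simplest
non-linear combination of the two polarizations), and
difference/slope features (`ndvi_diff`, `cohvv_sm_diff`,
`cohvh_sm_diff`, `ndvi_der`, `cohvh_sm_der`, `cohvv_sm_der`) computed
between consecutive *valid* measurements and carried unchanged across
the interpolated days until the next measurement. Using valid-measurement
neighbours (rather than interpolated ones) keeps these features sharp at
real observation days, which is where the information lives.

Daily labels mark the 7 days starting at each event start (clipped at
the season end). The width is configurable; 7 mirrors the −3/+6-day
evaluation tolerance, so a probability bump anywhere in the labelled
run decodes to a start inside the tolerance window.

## The detector

Three 1-D convolutions with same-length padding (kernel 9, channels
14→32→32→1). The first two are each followed by a softmax across the
channel axis at each timestep and then batch normalization; the third
by a sigmoid, yielding a probability per day. The channel-softmax is an
unusual hidden activation; it is applied per timestep because that is
the only axis where a softmax is well-defined for sequence input, and
the sweep harness (`sweep_models()`) exposes ReLU/tanh/sigmoid/linear
alternatives. With two hidden layers of kernel $k$ the output at day
$d$ sees days $d \pm 3(k-1)/2$; kernel 9 gives a ±12-day receptive
field, matching the 24–36-day persistence of the coherence signature.

Training minimises mean per-day binary cross-entropy over all 215 days
(interpolated days included — the `dt` feature lets the model discount
them) with the Nadam optimizer (β₁ = 0.9, β₂ = 0.999,
schedule_decay = 0.004, ε = 1e-7), batches of 64 fields, up to 300
epochs with early stopping on validation loss (patience 20, best
weights restored). Two learning rates are sensible defaults in this
family — 1e-3 and 1e-4 — and both are exposed; `model_config()`
defaults to 1e-4. Batch normalization uses batch statistics during
training and running statistics (momentum 0.9) at inference, so
predictions are independent of batch composition; momentum 0.9 makes
the running statistics trustworthy already after a few hundred
optimizer steps, which matters because softmax activations have tiny
variances that a slower-moving average would misestimate for a long
time. The network and its backward pass are implemented in-package on
im2col + BLAS matrix products; gradients are verified against central
differences in the test suite's development history and training is
bit-reproducible under a fixed seed on a single thread.

## Evaluation

Daily probabilities are decoded into events as maximal runs of days
above a threshold (default 0.5; a minimum run length is available). A
predicted start matches an actual start $a$ if it falls in
$[a-3, a+6]$: mowing is easier to see after the fact, hence the
asymmetric window. Actual events are processed in order and each
consumes the earliest unconsumed prediction in its window; every other
prediction is a false positive, unmatched actual events are false
negatives, and a field-season with no events on either side counts one
true negative (the natural unit that makes the pooled accuracy
$(TP+TN)/(TP+TN+FP+FN)$ well-defined). This greedy rule equals the
exhaustive maximum-matching oracle for these same-width windows — a
property the acceptance tests verify by enumeration.

Season-level scores default to the noisy-or
$1 - \prod_d (1 - p_d)$ of the daily probabilities ("probability of at
least one event"); a `max` alternative exists because noisy-or
saturates when daily probabilities are miscalibrated upward. EOS
accuracy thresholds the season score at 0.5; AUC is the rank-based
(Mann–Whitney) statistic with ties counting one half.

## Reject region

On validation season scores, `fit_reject_interval()` sets `t_upper` to
the $\lceil tpr \cdot n_{pos} \rceil$-th positive score in descending
order and `t_low` to the $\lceil tnr \cdot n_{neg} \rceil$-th negative
score in ascending order, so at least the requested shares of positives
(score ≥ `t_upper`, decided mown) and negatives (score ≤ `t_low`,
decided not mown) are retained and correctly decided by construction.
Scores strictly inside the interval are abstained; ties with a
threshold are decided, not abstained. Demanding higher retained rates
pushes the thresholds toward the class boundary, so the abstention
interval — and with it the rejected fraction — shrinks monotonically as
the requested rates grow. When the thresholds cross
(`t_low ≥ t_upper`) the interval is declared empty, nothing is
rejected, and a warning is raised.

## The synthetic generator

No field data ship with the package, so `simulate_dataset()` builds
labelled seasons that reproduce what the pipeline must cope with:

* baseline NDVI as a half-oval (ellipse-arc) curve with per-field
  amplitude (min 0.1–0.3, max 0.6–0.9), centre (day 95–120) and
  half-width (105–130 days) — the simplest curve family matching the
  characteristic rise/plateau/decay of unmown grass;
* mowing events with an NDVI drop of 0.2–0.45 recovering linearly over
  25–40 days and a coherence rise of 0.10–0.30 decaying over a 24–36
  day persistence period; event starts follow a summer-weighted prior
  (Gaussian around late June) and consecutive events are at least the
  regrowth upper bound apart;
* 95% of fields mown, 1–3 events each;
* coherence baselines 0.15–0.40 sampled every 6 days with Gaussian
  noise (sd 0.03) and rain days (10% of acquisitions) multiplying
  coherence by 0.4–0.8; NDVI sampled every 4 days, 75% invalidated,
  Gaussian noise sd 0.02, and 0.1% of surviving samples replaced by an
  isolated cloud-mask outlier drawn from $[0,\,0.45\,v + 0.1]$ — by
  construction never two in a row;
* everything clipped to the legal ranges, deterministic per
  `(seed, field index)` with independent per-field substreams.

The sample-size, cadence, missingness, persistence and mown-fraction
settings are the study conditions; the noise SDs, rain rate, baseline
and curve-parameter ranges are generator conventions chosen once to
look like the published example series, and the tests run against these
defaults. What passing tests show is that the pipeline recovers events
whose signature follows this model at realistic sparsity and noise;
they do not certify performance on real imagery, where coherence
baselines drift with soil moisture, outliers can correlate with fronts
of cloud, fields are spatially correlated, and labels themselves are
imperfect.

## Numerical choices and degenerate inputs

* EMA initialisation `out_1 = in_1` (the recursion needs an anchor;
  this is the standard convention).
* Triplet filtering is single-pass on the original values — no
  cascading removals — and requires at least three valid measurements.
* Interpolation holds the nearest value constant outside the measured
  range; a single measurement fills the whole season.
* `dt` is 0 up to the first measurement; diff/slope features are 0 up
  to and including the first valid measurement.
* Batch-norm ε = 1e-3; BCE is clamped with 1e-12 to avoid log(0);
  training errors out (naming the epoch) if the loss goes non-finite.
* Weight init is Glorot-uniform, seeded; batch shuffling, splits and
  permutation tests all derive from explicit seeds.
* Reject-region thresholds sit exactly on observed score quantiles, so
  they agree with an exhaustive search over distinct score values.

## Problem sizes used in the shipped study

The end-to-end synthetic study (tests and `scripts/acceptance.R`) uses
1000 fields split 64/16/20, the generator defaults above, and trains
with learning rate 1e-3 for up to 120 epochs with patience 15 — a
budget at which the validation loss curve is flat for this data size;
the headline numbers it produces are event accuracy ≈ 0.84, EOS
accuracy ≈ 0.95 and season-score AUC ≈ 1.0 on the held-out fifth.
Smaller fixtures (dozens of fields, shorter grids) back the unit tests.

## Known limitations

* The detector is non-causal (it sees the whole season), so it suits
  retrospective compliance checking, not real-time alerting.
* Multi-orbit coherence (different relative orbit numbers with
  overlapping 6-day pairs) is not modelled; the simulator emits one
  orbit.
* The reject region operates on season-level decisions only; per-event
  abstention is out of scope.
* A Kalman-filter smoother is a known alternative to the EMA in this
  setting; it is not implemented here since the EMA variant is the
  selected default and the moving average covers the comparison use
  case.
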