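# airspiral

Early-Parkinson's screening from a wrist-worn inertial sensor during mid-air
Archimedean-spiral tracing — an end-to-end, fully synthetic-testable R
implementation of the pipeline: cohort simulation, Kalman-filter attitude
estimation, sliding-window preprocessing, a family of attention-augmented
LSTM classifiers, and attention-interpretability analytics.

## The problem

Early Parkinson's disease (PD) announces itself through subtle motor signs —
4–6 Hz tremor bursts and bradykinetic slowing — that are hard to see in
conventional paper drawing tests. Tracing an Archimedean spiral *in mid-air*
removes the stabilizing surface and amplifies these signs. A wristband
streams six motion channels at 330 Hz: triaxial acceleration
(`ax, ay, az`, in g) and angular rate (`gx, gy, gz`, in deg/s), one packet
per sample (a 60-s recording is 19,800 packets).

The pipeline turns packets into a diagnosis in four stages:

1. **Attitude.** Per axis, a two-state Kalman filter (state =
   [angle, gyro bias]; `A = [[1, −dt], [0, 1]]`, gyro rate as control input,
   accelerometer tilt `roll = atan2(ay, az)`,
   `pitch = atan2(−ax, √(ay² + az²))` as observation) fuses the drift-free
   but noisy accelerometer with the smooth but drifting gyroscope.
2. **Preprocessing.** Roll/pitch traces are min-max normalized
   (`x′ = (x − x_min)/(x_max − x_min)`, statistics fitted on training data
   only) and cut into 32-step windows; subjects are split 8:1:1 into
   train/val/test so no subject leaks across splits.
3. **Classification.** LAFNet — a stacked LSTM whose hidden sequence
   `h_1..h_T` is aggregated by *linear attention*
   `a_t = W_a h_t + b_a`, `context = Σ_t a_t h_t` — feeds a dense softmax
   head. Four variants (tanh-gated attention, dropout placements, plain
   LSTM) are included for ablation.
4. **Interpretability.** Per-window attention weights are normalized
   (`α̂_t = α_t / Σα_t`), upsampled and Savitzky–Golay smoothed
   (window 51, order 3), overlaid on the angle traces, and apportioned into
   per-channel importance percentages.

No clinical recordings ship with the package. A first-class simulator
generates labelled cohorts with ground-truth attitude and tremor-burst
annotations: PD subjects get 4–6 Hz tremor bursts (2–5°, active 40–80% of
the time) and 1.3–2× slowing; both groups share 8–12 Hz physiological
jitter, gyro bias drift and sensor noise.

## Worked example

```r
library(airspiral)

# simulate a small labelled cohort: 6 healthy + 6 PD, 15 s at 330 Hz
cohort <- generate_cohort(n_healthy = 6, n_pd = 6, duration_s = 15, seed = 1)

# Kalman roll/pitch for one subject, versus naive baselines
s <- cohort[[7]]                      # a PD subject
att <- estimate_attitude(s$recording)
attitude_rmse(att, s$truth)
#>      roll     pitch
#> 0.1487899 0.1566877
attitude_rmse(gyro_integrate(s$recording), s$truth)   # drifts
#>      roll     pitch
#> 0.5237665 2.3886396
attitude_rmse(accel_only(s$recording), s$truth)       # noisy
#>     roll    pitch
#> 1.152976 1.139281

# windows, labels, splits, normalization
ds <- make_dataset(cohort_features(cohort), fractions = c(0.7, 0.15, 0.15),
                   seed = 1)
ds
#> <windowed_dataset> 1848 windows of 32 x 2, splits: test=308 train=1232 val=308

# train LAFNet and evaluate on held-out subjects
fit <- train_model(variant_spec("LAFNet"), ds,
                   train_config(epochs = 120, batch_size = 32, seed = 1))
evaluate_model(fit, ds, "test")
#> accuracy 89.94%  precision 97.67%  recall 81.82%  F1 89.05% (n = 308)
#>          predicted
#> actual    healthy  pd
#>   healthy     151   3
#>   pd           28 126
evaluate_subjects(fit, ds, "test")   # per-subject vote, threshold from val
#> accuracy 100.00%  precision 100.00%  recall 100.00%  F1 100.00% (n = 2)

# where does the model look? channel importance from attention weights
te <- dataset_split(ds, "test")
rep <- attention_report(fit, te$x, channel_names = c("roll", "pitch"))
round(colMeans(rep$channel_importance), 1)
#>  roll pitch
#>  50.6  49.4
```

The Kalman RMSEs (~0.15°) beat both naive baselines; window-level test
accuracy reflects that only burst-covered PD windows are separable, while
the per-subject vote recovers every held-out diagnosis; the two roll/pitch
channels contribute near-equally, as expected for a rotational tremor
loading both axes.

Window-level accuracy on this generator is bounded by the burst duty — PD
windows without an active tremor burst are by design nearly indistinguishable
from healthy ones at the 97-ms window scale — while the per-subject majority
vote recovers the diagnosis; the methods vignette
(`vignettes/airspiral-methods.Rmd`) derives this ceiling and documents every
modelling choice.

An end-to-end run (simulate → clean → attitude → preprocess → train →
evaluate → interpret, with a run manifest) is one call:

```r
res <- run_pipeline(default_config(seed = 1), out_dir = "run1")
```

or from a shell: `exec/airspiral run-all --seed 1 --out-dir run1`
(also `simulate` and `attitude` subcommands).

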