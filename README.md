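# leafplp

Generative calibration for leaf-clip ultrasound hydration sensing.

A wearable leaf clip that passes ultrasound through a leaf blade reads out
a transmit–receive voltage amplitude, V<sub>TRx</sub>, that rises as the
leaf dries: water attenuates the transmitted sound, so voltage and
hydration move in opposite directions. Each leaf has its own
*characteristic curve* — the discrete mapping between V<sub>TRx</sub> (mV)
and relative water content,

RWC = 100 · (m<sub>fresh</sub> − m<sub>dry</sub>) / (m<sub>turgid</sub> − m<sub>dry</sub>) \[%\],

acquired destructively by a stepwise oven-drying loop (10 mass/voltage
readings per leaf). Destructive calibration does not scale, so `leafplp`
predicts the curve for an *unseen* leaf from five photograph-derived
morphometric features — area A (cm²), perimeter P (cm), ratio A/P (cm),
caliper thickness T (µm) and shape skewness S — using a conditional
variational autoencoder (CVAE). Per cultivar, a master model holds two
slave CVAEs that reconstruct the 10-point voltage vector and the 10-point
RWC vector separately, each with encoder Q<sub>θ</sub>(z | X, c) and
decoder P<sub>φ</sub>(X′ | z, c) conditioned on the feature vector
c = (A, P, A/P, T, S). A cubic transfer polynomial RWC = f(V<sub>TRx</sub>)
fitted to the generated curve then converts one-shot voltage readings and
voltage time series into hydration values.

The package is aimed at plant-phenomics and biosensor groups who want to
reproduce, stress-test or extend this calibration pipeline. Because no
publicly archived 200-leaf sweet potato library exists (100 Honey/Cilembu,
50 Japanese/Beniazuma, 50 Orange/OFSP leaves), a first-class synthetic
module emulates that acquisition design — including the Honey cultivar's
two voltage-amplitude groups topping out near 300 and 600 mV — so every
stage is testable end to end.

## What is in the box

| Module | Functions |
|---|---|
| Synthetic leaves | `builtin_cultivar`, `sample_features`, `ground_truth_curve`, `simulate_drying_loop`, `generate_library`, `render_leaf_image` |
| Morphometrics | `segment_leaf`, `measure_area`, `measure_perimeter`, `measure_skewness`, `extract_features` |
| Calibration | `compute_rwc`, `assemble_curve`, `build_library`, `percent_change`, `write_library` / `read_library` |
| CVAE | `cvae_config`, `train_cvae`, `cvae_encode` / `cvae_decode`, `reparameterize`, `elbo_loss`, `predict_curve`, `save_generator` / `load_generator` |
| Transfer pipeline | `fit_transfer`, `voltage_to_rwc`, `translate_trace`, `one_shot_rwc`, `rmse`, `evaluate_holdout` |

A thin command-line front end ships at
`system.file("cli", "leafplp.R", package = "leafplp")` with subcommands
`simulate`, `extract-features`, `train`, `predict`, `translate`,
`one-shot` and `evaluate`.

## Worked example

Train a Japanese-cultivar master model on a synthetic 50-leaf library,
evaluate five held-out leaves, and translate a voltage reading:

```r
library(leafplp)

lib <- generate_library(builtin_cultivar("japanese"), n = 50, seed = 7)
gen <- train_cvae(lib, cvae_config(epochs = 2000, seed = 7))
holdout <- generate_library(builtin_cultivar("japanese"), n = 5, seed = 7007)
evaluate_holdout(gen, holdout, train_ids = lib$leaf_ids)
#> <evaluation_report> japanese - 5 held-out leaves
#>   best: V_TRx RMSE 4.04 mV (japanese-7007-0003), RWC RMSE 0.95% (japanese-7007-0001)
#>   mean: V_TRx RMSE 5.20 mV, RWC RMSE 1.02%
```

The report gives, per held-out leaf, the RMSE between the predicted and
recorded 10-point curves, in mV for the voltage slave and RWC percentage
points for the water-content slave; `best` singles out the most accurate
leaf (a selection, not a typical case — the mean is reported alongside).

```r
f <- holdout$features[1, ]
leaf <- leaf_features(area = f[["area_cm2"]], perimeter = f[["perimeter_cm"]],
                      thickness = f[["thickness_um"]],
                      skewness = f[["skewness"]])
curve <- predict_curve(gen, leaf)      # deterministic: z = prior mean
tf <- fit_transfer(curve)              # cubic RWC = f(V_TRx)
voltage_to_rwc(tf, 250)
#> 56.1
```

A 250 mV reading on this leaf therefore corresponds to about 56% RWC —
the one-shot measurement mode (`one_shot_rwc` wraps these three steps).
`translate_trace` applies the same transfer function to a whole
(time, voltage) series for continuous monitoring; voltages outside the
curve's span clamp to the nearest endpoint rather than extrapolating the
polynomial.

Quick percent-change summaries used for detached-leaf experiments:

```r
percent_change(238, 932, integer = TRUE)  # V_TRx rise during dehydration
#> 291
points_change(100, 1.8)                   # RWC drop in percentage points
#> -98.2
```

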