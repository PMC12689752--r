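# pelvnav

Navigation geometry for percutaneous sacroiliac (SI) screw placement.

SI screws stabilise the posterior pelvic ring by passing through the ilium
into the S1 or S2 vertebral body. A radiation-free navigation workflow
registers ("matches") the planned pelvis model to the patient by probing
three palpable landmarks — both anterior superior iliac spines (ASIS) and
the pubic symphysis — and then displays the planned drill trajectory to
the surgeon. `pelvnav` implements that workflow's computational core in R:

* **Registration** — closed-form least-squares similarity fit
  (absolute orientation): the transform `T(x) = s R x + t` minimising
  `Σᵢ ‖T(xᵢ) − yᵢ‖²` over the three labelled fiducials, via SVD of the
  landmark cross-covariance with the determinant correction (never a
  reflection). Reports FRE and per-landmark residuals;
  `target_registration_error()` propagates the error to surgical targets.
* **Placement metrics** — the full evaluation geometry: maximal lateral
  deviation (MLD, the largest orthogonal distance of the drilled axis from
  the planned axis, provably attained at the screw base or tip), entry and
  central-aim point deviations, angular deviation, and cortical
  perforation detection with anatomical direction classification
  (anterior → small pelvis, superior/inferior → neuroforamina,
  posterior → spinal canal; combined labels via 8-sector compass logic).
  Correct placement = absence of perforation.
* **Guidance** — the intraoperative feedback loop as a deterministic,
  replayable state machine over tracked drill poses (entry captured →
  aligned → depth reached → advance to the next screw in the fixed order
  S1 right, S1 left, S2 right, S2 left).
* **Phantom + Monte-Carlo engine** — a parametric pelvis phantom (two S1
  and two S2 corridors, S1 wider than S2) with a landmark/operator noise
  model, an in-silico trial runner that matches once per pelvis and drills
  four screws, and a symphysis-tilt experiment that reproduces the
  error-propagation mechanism: an anteriorly mis-marked symphysis tilts
  the registration about the inter-ASIS axis and fails the narrow S2
  corridor first, with anterior-component breaches.

See `vignettes/navigation-geometry.Rmd` for the models, parameter
rationale and numerical choices.

## Worked example

```r
library(pelvnav)

phantom <- make_phantom()                      # default parametric pelvis
pose    <- similarity_transform(translation = c(50, 30, 900))
probed  <- probe_landmarks(phantom, pose, noise_model(seed = 7))
fit     <- fit_similarity(phantom$landmarks, probed)
fit
#> <registration_fit> similarity (scale fitted)
#> <similarity_transform> scale 0.97619, rotation 0.748 deg, translation [50.577 28.615 899.806] mm
#>   FRE (rms): 1.497 mm
```

With 2 mm landmark noise the fit absorbs part of the error into a 0.75°
rotation and a 2.4% scale change; the 1.5 mm FRE understates the error at
the corridors (the classic FRE-vs-TRE gap).

```r
trial <- run_trial(trial_config(n_pelves = 10, seed = 42))
glance(trial)
#> # A tibble: 1 × 6
#>   n_pelves n_screws s1_correct_rate s2_correct_rate median_mld_mm median_angular_dev_deg
#>      <int>    <int>           <dbl>           <dbl>         <dbl>                  <dbl>
#> 1       10       40             0.4            0.05          4.06                   1.47

summ <- summarize_trial(trial)
summ$per_pelvis
#> # A tibble: 10 × 3
#>    pelvis n_perforated shared_direction
#>     <int>        <int> <lgl>
#>  1      1            4 TRUE
#>  2      2            2 TRUE
#>  3      3            3 FALSE
#>  ...
```

Under identical noise the wide S1 corridor is placed correctly 8× more
often than the narrow S2 corridor (40% vs 5% here), and in most pelves
all perforated screws share a breach direction — the signature of a
per-pelvis matching error, since the registration is fitted once per
pelvis and shared by its four screws. `autoplot(trial)` draws the metric
distributions; `tidy(trial)` returns the per-screw table.

The tilt mechanism in isolation:

```r
tilt <- symphysis_tilt_experiment(c(1, 2, 4, 8),
                                  trial_config(n_pelves = 100,
                                               noise = zero_noise(),
                                               seed = 1))
tidy(tilt)[, c("bias_mm", "axis_angle_to_interasis_deg",
               "s1_correct_rate", "s2_correct_rate",
               "s2_anterior_fraction")]
```

A pure anterior symphysis bias rotates the fitted registration about the
inter-ASIS axis (axis angle ≈ 0°); S2 screws start perforating at ~2 mm
bias, S1 only at ~4 mm, and the induced S2 breaches all carry an anterior
component.

## Command line

A thin CLI over the same functions is installed at `inst/cli/pelvnav`:

```sh
pelvnav phantom  --out-dir out --seed 1          # mesh + plan + landmarks
pelvnav register --model out/landmarks.json --probed probed.json --out tf.json
pelvnav evaluate --phantom out/phantom.json --drilled drilled.json --out report.csv
pelvnav simulate --config trial.yaml --out-dir run1 --seed 42
pelvnav guide    --plan out/plan.json --poses poses.jsonl --out events.jsonl
```

Exit code 0 on success, 2 on validation errors. Supported formats: STL
(ASCII + binary) and OBJ meshes, JSON plans/landmarks/transforms, JSONL
pose and event streams, YAML trial configs, CSV reports with a seed
metadata header.

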