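# atriakit

Quantitative electrophysiology of the mouse atrium, as a tested R
pipeline. The package targets the workflow used to characterise
atrium-selective AMPK-knockout (AMPK-dKO) mice, which develop atrial
conduction slowing, action-potential prolongation, ectopy and eventually
spontaneous atrial fibrillation:

* **Optical mapping** — voltage-dye movie processing (beat segmentation,
  8-beat ensemble averaging, 5×5 spatial smoothing, per-pixel
  normalization/inversion) and map extraction: activation time
  (max-dV/dt with sub-frame refinement), upstroke velocity, and APD₇₅
  (time from upstroke to 75% repolarization, `APD = t(V = 0.25) − t_act`
  on the normalized trace), with region-of-interest summaries.
* **Surface ECG** — R-peak detection, signal-averaged tracings of 10
  consecutive beats, noise-band (k·SD) fiducial measurement of P-wave
  duration, PR interval, QRS duration and heart rate, and premature
  atrial complex labelling (RR < 0.8 × median of the previous 5 sinus
  intervals).
* **Rhythm** — atrial-fibrillation episode detection (R-R coefficient of
  variation + absent consistent pre-QRS P deflection), the per-day
  diagnosis rule (episodes > 30 s in ≥ 2 same-day 1-minute recordings),
  and R-R variability (SD of instantaneous heart rate, Poincaré pairs).
* **qPCR + statistics** — ΔΔCt fold changes (`fold = 2^(−ΔΔCt)`),
  Student's t tests, two-way ANOVA with Holm–Šidák contrasts.
* **Synthetic data** — generators for movies, ECGs and Ct tables with
  known ground truth. Control presets use physiological murine values;
  knockout presets encode the study's effect sizes *exactly by
  construction*: activation time ×1.4, upstroke velocity ×0.5, APD₇₅
  ×1.5, P duration ×2, PR ×1.1, heart-rate SD ×3, Pitx2c left/right
  gradient 160-fold with a 60% knockout reduction.

All analysis works on real data in standard formats (multi-page 16-bit
TIFF + JSON sidecar for movies, CSV + JSON for ECG); the generators exist
so every stage is testable end to end without any recordings.

## Worked example

Generate a control and a knockout heart, run the full optical pipeline,
and compare:

```r
library(atriakit)

con <- generate_optical_movie(optical_preset("CON"), seed = 1)
dko <- generate_optical_movie(optical_preset("dKO"), seed = 2)

s_con <- analyze_movie(con$movie)$summary
s_dko <- analyze_movie(dko$movie)$summary
s_con
#> <map_summary LA> APD75 30.50 ms | activation span 7.06 ms | max slope 0.518 /ms
#>   pixels: activation 6400, apd 6400, upstroke 6400
s_dko
#> <map_summary LA> APD75 45.36 ms | activation span 9.93 ms | max slope 0.259 /ms
#>   pixels: activation 6400, apd 6400, upstroke 6400

s_dko$activation_span / s_con$activation_span   # 1.41: 40% conduction delay
s_dko$mean_max_slope / s_con$mean_max_slope     # 0.50: halved upstroke velocity
s_dko$mean_apd75 / s_con$mean_apd75             # 1.49: ~50% APD75 prolongation
```

The activation span is the 5th–95th percentile spread of per-pixel
activation times across the mapped field (7.06 ms ≈ 0.9 × the 7.9 ms
planar crossing time); the knockout ratios recover the encoded phenotype
through the complete movie → maps pipeline, noise included.

ECG intervals work the same way:

```r
sim <- generate_ecg(ecg_preset("dKO_wk1"), duration = 60, seed = 1)
measure_ecg_intervals(sim$ecg)
#> <ecg_intervals> P 22.85 ms | PR 41.21 ms | QRS 10.20 ms | HR 500 bpm
```

A thin command-line wrapper over the same functions lives at
`inst/cli/atriakit.R` (`simulate`, `map-analyze`, `ecg-intervals`,
`rhythm`).

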