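# respiq

Quantitative respiratory **flow-waveform reconstruction** from a contactless,
near-field impedance sensor — and a physics-based simulator to generate the
paired data such a sensor produces.

Most contactless respiration monitors (radar, cameras, thermal imaging)
recover only the respiratory *rate*. A transmissive 433 MHz dipole pair
coupled through the thorax senses something richer: air filling the lungs
lowers the effective permittivity ε of the coupling path, which modulates the
mutual impedance

```
Z12 = l²/(4πr²) · ( 1/(jωεr) + R0 + jωμr ) · e^(−j2πr/λ)
```

and with it the amplitude and phase of the received carrier, demodulated to
I/Q channels at 33 Hz. `respiq` implements the full chain that turns that raw
record into a flow waveform in L/s with self-assessed reliability:

1. **`sensor_sim`** — scripted breathing patterns (fast / normal / slow /
   apnea with clinical rate bounds), the Z12 physics above, and a hardware
   model (quadrature skew and imbalance, DC offsets, drift, receiver noise,
   low-signal "misplacement" intervals) producing paired `flow.csv` +
   `iq.csv` datasets: `breathing_script()`, `generate_flow()`,
   `mutual_impedance()`, `simulate_iq()`, `simulate_cohort()`.
2. **`preprocess`** — resampling to 100 Hz, amplitude/unwrapped phase,
   zero-phase 3rd-order Butterworth band-pass (0.1–16 Hz), derivative
   features, the phase-rate feature, and Yeo-Johnson + robust scaling fitted
   on training subjects only: `build_features()`, `fit_transform_state()`.
3. **`reconstruct`** — the published MLP regressor (hidden layers
   [150, 550, 800, 200, 550], dropout 0.3, AdamW, Huber loss) under
   subject-grouped cross-validation, with 10-pass Monte-Carlo-dropout
   reliability scores and unreliable-interval masks:
   `cross_validated_reconstruction()`, `predict_mc()`.
4. **`breath_features`** — zero-crossing onsets with hysteresis, cycle
   durations and rate classes (≤ 3 s fast, ≥ 6 s slow), inspiratory-limb
   tidal volumes, apnea intervals, reliability-gated cycle counts:
   `detect_onsets()`, `segment_cycles()`.
5. **`evaluate`** — synchronization, onset pairing, signed timing errors,
   reliability-gated detection rate, Bland–Altman tidal-volume agreement,
   flow correlation: `evaluate_subject()`, `full_report()`.

Everything is tibble-in / tibble-out with `tidy()`, `glance()` and
`autoplot()` methods on the fitted objects, and `run_pipeline()` chains the
stages into one seeded, reproducible run.

## Worked example

Simulate a 6-subject cohort (3 minutes each, coupling gains spread ×[0.5, 2]
to emulate posture-dependent amplitude bias), reconstruct every subject with
a model that never saw it, and evaluate agreement:

```r
library(respiq)

res <- run_pipeline(respiq_config(seed = 1), quiet = TRUE)
glance(res$report)   # pooled agreement metrics
```

```
# A tibble: 1 x 13
  n_subjects n_ref_cycles detection_rate insp_median_ms insp_sd_ms exp_median_ms
       <int>        <int>          <dbl>          <dbl>      <dbl>         <dbl>
1          6          180              1          0.494       123.          1.96
# i 7 more variables: exp_sd_ms <dbl>, vt_abs_median_l <dbl>, vt_bias_l <dbl>,
#   vt_r_min <dbl>, flow_r <dbl>, flow_r_min <dbl>, medae_flow_l <dbl>
```

```r
tidy(res$report)[, c("subject_id", "detection_rate", "insp_median_ms",
                     "vt_bias_l", "vt_r", "flow_r")]
```

```
# A tibble: 6 x 6
  subject_id detection_rate insp_median_ms vt_bias_l  vt_r flow_r
  <chr>               <dbl>          <dbl>     <dbl> <dbl>  <dbl>
1 S01                     1         11.4    -0.217   0.955  0.959
2 S02                     1         -1.11   -0.156   0.938  0.972
3 S03                     1          1.46   -0.00532 0.936  0.976
4 S04                     1         -6.51    0.0420  0.942  0.977
5 S05                     1          0.993   0.0276  0.944  0.964
6 S06                     1          0.844   0.157   0.947  0.977
```

Reading the numbers: the reconstruction finds essentially every scripted
breath (`detection_rate`), times inspiration onsets to within a few
milliseconds of the reference on this clean synthetic cohort
(`insp_median_ms`; the 33 Hz sensor grid alone floors real-sensor timing at
`sensor_timing_floor_ms() ≈ 30.3` ms), and shows a per-subject tidal-volume
bias (`vt_bias_l`) that follows each subject's coupling gain — yet the
within-subject tidal-volume correlation (`vt_r`) stays high: absolute
volumes are biased, relative trends survive. That is the core claim the
package demonstrates.

Plots: `autoplot(res$cv$recon[[1]], reference = res$cohort$flow[[1]])` shows
a reconstructed trace with its Monte-Carlo ribbon and unreliable shading;
`autoplot(res$report)` draws the tidal-volume Bland–Altman diagram;
`plot_reliability()` the reliability-score timeline.

A thin command-line interface over the same functions lives at
`inst/cli/respiq.R` (subcommands `simulate`, `preprocess`, `train`,
`reconstruct`, `analyze`, `report`, `run-all`), e.g.

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "respiq.R", package = "respiq"))')" \
  run-all --config demo.yaml --out runs/demo --seed 7
```

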