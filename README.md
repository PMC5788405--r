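# alarmdet

Detection of periodic biomedical equipment alarms — the tone–silence
beeps of patient monitors, infusion pumps and ventilators — in noisy
single-channel audio such as neonatal intensive care unit recordings.
The package is aimed at clinical-audio researchers who need automatically
labelled alarm events (which alarm, when) from long recordings, for
studies relating the acoustic environment to patient state or for smart
alarm-notification systems.

## The approach

Each alarm class is a *known* signal: a periodic cycle of one or more
tones (sets of sinusoidal components at device-specific frequencies
`f_b`) of total duration `L_sig`, followed by silence of duration
`L_sil`. One independent detector per class exploits that knowledge at
both ends of the pipeline:

* **Spectral structure.** Frame features are computed only inside the
  bands `f_b ± 20 Hz`. Either *statistical sinusoid detection* — every
  spectral peak is scored by 32-component Gaussian mixtures over
  magnitude-shape and phase-continuity features,
  `y²(j) = wrap(φ_l(k_p+j) − φ_{l−1}(k_p+j) − 2π k_p L / N_dft)`,
  trained on synthetic sinusoids at −7 dB SNR — or *supervised NMF*:
  `S ≈ [W_A, W_NA] H` minimising `D_KL(S‖WH) + β|H|₁` with fixed trained
  bases, the normalised alarm activations `H_A` serving as features. A
  generic baseline (frequency-filtered log Mel filter-bank energies,
  36-D) is included for comparison. Frames are classified
  alarm/non-alarm by a single diagonal Gaussian per class or by an
  RBM-pretrained neural network (32 logistic hidden units).

* **Temporal structure.** Per-frame log-posterior contrasts are
  aggregated over one signal-plus-silence window,

  `P_period(t) = Σ_{i=t..t+L_sig−1} (P_A − P_NA) + Σ_{i=t+L_sig..t+L_sig+L_sil−1} (P_NA − P_A)`,

  which peaks at period starts; peaks above a class-specific threshold,
  EER-thresholded and majority-smoothed frame labels, and their
  combination give three decision methods.

* **Evaluation.** Frame-level missing/false-alarm rates and DET/EER
  curves, and the period-based error rate
  `PB-ERR = 1 − 2N_C/(2N_C + N_FA + N_M)` with timestamp tolerance
  `T_tol` (default 49% of the period), plus local-SNR measurement and
  stratification and session-wise cross-validation.

Clinical recordings of this kind are not redistributable, so the package
includes a first-class synthetic soundscape generator (periodic
sum-of-sinusoid alarms with device versions, overlapping events,
broadband + tonal-interference backgrounds, two microphone channels,
closed-loop local-SNR calibration, CSV annotations) that every test runs
on.

## Worked example

Synthesise an annotated scene, train a detector per class, and score it:

```r
library(alarmdet)

reg <- default_registry()                  # 7 alarm classes a1..a16
pm  <- train_peak_models(rng_seed = 1)     # sinusoid/noise peak GMMs

events <- data.frame(class_id = c("a1", "a7", "a10"), version = 1L,
                     start = c(2, 9, 16), n_periods = 10L, snr_db = 18)
train_scene <- render_scene(scene_spec(60, events, seed = 1), reg)
test_scene  <- render_scene(scene_spec(60, events, seed = 2), reg)

cfg  <- alarm_config("sd_llh_amp", "gmm", "smooth+temporal", seed = 1)
dets <- train_detectors(list(train_scene), reg[c("a1", "a7", "a10")],
                        cfg, models = list(peak = pm))
res  <- run_detection(dets, test_scene)
res$per_class[, c("class_id", "eer", "mr", "far", "pb_err")]
#>   class_id       eer         mr         far pb_err
#> 1       a1 0.1187626 0.07627119 0.009324009      0
#> 2       a7 0.2040387 0.15957447 0.005339436      0
#> 3      a10 0.1267215 0.08450704 0.010292953      0
```

Read: at 18 dB local SNR the frame-level equal error rate is 12–20% per
class — the residual errors sit almost entirely on frames that straddle
tone onsets/offsets — while every one of the 10 alarm periods per class
is recovered at the period level (`pb_err = 0`, i.e. F1 = 1 against the
reference period timestamps at a tolerance of 49% of the period).
`res$events` holds the detected period starts per class; `res$labels`
the frame decisions.

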