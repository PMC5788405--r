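---
title: "Knowledge-based detection of periodic equipment alarms: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Knowledge-based detection of periodic equipment alarms: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`alarmdet` detects the periodic alarm sounds of biomedical equipment —
cardiorespiratory monitors, infusion pumps, ventilators, incubators — in
noisy single-channel audio such as recordings from a neonatal intensive
care unit. The package's premise is that these alarms are *known* signals:
each class is a periodic tone–silence cycle with fixed, device-specific
frequencies and durations, and the detector should exploit that knowledge
rather than learn everything from data. This vignette explains the models
the package implements, the parameters that matter, what the synthetic
soundscape generator does and does not emulate, and the numerical and
design choices made along the way.

## The alarm model

An alarm class is described by an `alarm_class_spec`: one or more device
*versions*, each a list of consecutive *tones* (a tone is a set of
simultaneous sinusoidal components with a duration in seconds) followed by
a silence interval. The signal interval `L_sig` is the total tone
duration, and `L_sig + L_sil` is the period. Versions model the slight
frequency/duration offsets between device units of the same model (the
defaults use +15 Hz and +5% — inside the ±20 Hz tolerance the detector
assumes). All per-class processing is restricted to the bands
`f_b ± delta` around each alarm-specific frequency, with `delta = 20` Hz
by default.

The system runs one detector per class, in parallel and with no shared
state, each consisting of: frame features → frame classifier → temporal
post-processing → decisions, evaluated at the frame and at the
alarm-period level.

## Spectral front-end

Audio is analysed at 24 kHz with frames of N = 2048 samples and a hop of
L = 1024 (≈85 ms / 43 ms). The sinusoid-detection front-end uses a
rectangular window and pads each frame with 2048 zeros, giving a 4096-point
DFT and 5.86 Hz bin spacing; the NMF front-end uses Hann windows without
padding. The baseline features (`compute_ff_lfbe`) are frequency-filtered
log Mel filter-bank energies: 18 triangular Mel filters spanning
0 Hz–Nyquist, log energies floored at 1e-12, differenced across
neighbouring filters (one-sided at the two edges), plus ±1-frame temporal
derivatives — 36 dimensions. Because the frequency filter is a difference
of log energies, the static part is exactly invariant to the waveform
amplitude scale.

## Statistical sinusoid detection

Every strict local maximum of the magnitude spectrum is a candidate
sinusoid. A peak at bin $k_p$ in frame $l$ is described by the magnitude
shape $y^1(j) = |S_l(k_p+j)|/|S_l(k_p)|$ and the phase continuity
$y^2(j) = \mathrm{wrap}\!\left(\phi_l(k_p+j) - \phi_{l-1}(k_p+j) -
2\pi k_p L / N_\mathrm{dft}\right)$ for $j = -M..M$ with $M = 6$, i.e.
26 dimensions. The subtracted term is the phase advance a stationary
sinusoid at bin $k_p$ accrues over one hop; note it must use the padded
DFT length $N_\mathrm{dft}$, not the frame length, for the cancellation
to be exact. Two 32-component diagonal-covariance Gaussian mixtures are
fitted by EM — $\lambda_s$ on peaks of synthetic random-frequency
sinusoids mixed with white noise at −7 dB broadband SNR, $\lambda_n$ on
noise-only peaks — and a peak is called sinusoidal when
$\log p(y|\lambda_s) > \log p(y|\lambda_n)$. Track-level detection links
marks across frames (bin drift ≤ 1), discards tracks shorter than 3
frames and tracks more than 40 dB below the loudest track in the file.
Within a frame, a mark within $M$ bins of a stronger mark is suppressed
first: the sidelobes of a strong off-grid sinusoid are themselves
phase-coherent and would otherwise spawn duplicate tracks.

The per-class *SD features* pick, in each alarm band and frame, the peak
maximising $\log p(y|\lambda_s)$, and emit the log-likelihood ratio
(`sd_ratio`), the pair of log-likelihoods (`sd_llh`), or the pairs plus
per-band magnitudes normalised to sum to one across the class's bands
(`sd_llh_amp`; the normalisation discards the overall alarm level while
keeping the amplitude *structure*, which separates classes that share a
frequency). A band with no peak receives a floor log-likelihood.

**Floor choice.** The floor is a fixed −300 nats, and observed
log-likelihoods are clipped there too. A file-relative floor (minimum
observed in the recording minus an offset) was considered and rejected:
the minimum over a recording is an extreme-value statistic (we measured
−937 vs −99 nats between two scenes of different lengths), so features
built on it are not comparable across recordings and the classifier's
operating point drifts between training and test material.

## Supervised NMF features

Per class, the Hann magnitude spectrogram restricted to the class's bands
is factorised as $S \approx WH$ with $W, H \ge 0$, minimising
$D_{KL}(S\|WH) + \beta|H|_1$ by the classical multiplicative updates
($\beta = 1$, up to 20 iterations, early stop at a relative objective
change below 1e-6, seeded strictly positive uniform initialisation).
Four alarm bases are trained on the class's annotated signal-interval
frames and fifteen non-alarm bases on frames free of any alarm; at
feature time $W = [W_A, W_{NA}]$ is fixed and only $H$ is estimated. Each
activation column is normalised to sum to one over all 19 bases (all-zero
columns fall back to uniform) and the four alarm rows are the features —
scale-invariant by construction.

Basis columns are L1-normalised **once after the final training update**,
not after every update. Per-update normalisation with compensation of $H$
leaves $WH$ unchanged but rescales the $\beta|H|_1$ penalty and can
*increase* the penalised objective, destroying the monotone-descent
guarantee of the multiplicative updates that the tests assert; end-of-run
normalisation removes the same scale ambiguity without touching the
descent property. KL is computed with the $0\log 0 = 0$ convention and a
1e-12 floor inside logarithms.

## Frame classifiers

The generative detector is a single Gaussian with diagonal covariance per
class (alarm / non-alarm), fitted in closed form with a 1e-6 variance
floor; more mixture components did not help at this feature dimension.
The discriminative detector is a one-hidden-layer network (32 logistic
hidden units, 1 logistic output) pretrained as a Gaussian–Bernoulli RBM
with one-step contrastive divergence and then trained by backpropagation
on the cross-entropy loss; minibatches of 10, inputs reshuffled per
epoch, momentum 0.9, learning rate 0.001, 80 unsupervised and 50
supervised epochs, weight decay 2e-7 and 1.2e-4. Classes are balanced by
seeded down-sampling of the majority class before the mean–variance
normalisation statistics are computed. Cross-entropy was chosen over
squared error as the natural loss for a logistic output.

Frame *scores* (for thresholds and DET curves) are the raw Gaussian
log-likelihood ratio, or the network output. Frame *posteriors* (for the
temporal model) are likelihoods normalised with equal class priors, then
floored at 1e-6 and renormalised. The floor matters: a single-Gaussian
log-likelihood ratio is unbounded, so without it the period-curve height
scales with how loud an alarm is rather than with how well its time
structure matches, and a period threshold trained at one SNR does not
transfer to another. With the floor the per-frame contrast is bounded by
about ±13.8 nats and curve heights are governed by durations.

The frame decision threshold is chosen by the equal-error-rate criterion
(threshold minimising |MR − FAR| over midpoints of the sorted training
scores, ties to the lower threshold) on training material — selecting it
on test data would leak.

## Temporal structure and decisions

For each frame $t$ the period probability
$$P_\mathrm{period}(t) = \sum_{i=t}^{t+L_\mathrm{sig}-1} (P_A - P_{NA})
 + \sum_{i=t+L_\mathrm{sig}}^{t+L_\mathrm{sig}+L_\mathrm{sil}-1} (P_{NA} - P_A)$$
aggregates the posterior contrast over one signal-plus-silence window, so
it peaks where a period begins. It is evaluated with cumulative sums and
tested bit-tolerantly against the direct double sum. Durations are
converted to frames by rounding at hop resolution; for the one multi-tone
class the signal interval is the total duration of its consecutive tones.

Three decision methods are implemented. Method 1 thresholds the frame
score at the EER threshold and smooths the labels by majority voting over
a centred window equal to min(L_sig, L_sil) frames (forced odd so
"majority" is unambiguous; edge windows truncated, ties keep the input
label). Method 2 thresholds $P_\mathrm{period}$ with a class-specific
threshold and takes curve peaks as period starts, with a greedy
descending-value acceptance that discards candidates closer than 75% of
the period to an accepted one. Method 3 combines them: a run of method-1
labels whose onset has no method-2 period within ±⌈L_sig/2⌉ frames is
reassigned to non-alarm. In the combined scheme the reported period
timestamp is the method-2 peak where one coincides, since the period
curve localises starts more sharply than the onset of a smoothed label
run.

The class-specific method-2 threshold is swept on training sessions to
minimise the period-based error. The optimum is usually a plateau; the
sweep returns the plateau's **lower quartile** rather than its midpoint:
a threshold that errs high irrecoverably misses periods, while the extra
peaks admitted by one that errs low are pruned by the minimum-separation
rule and, in the combined scheme, filtered by method 1.

## Evaluation

Frame level: MR = missed alarm frames / alarm frames, FAR = false-alarm
frames / non-alarm frames, DET curves over all score thresholds with the
equal-error point flagged. Period level: PB-ERR $= 1 - F_1 =
1 - 2N_C/(2N_C + N_{FA} + N_M)$, where a reference period is correct if a
hypothesis lies within ±T_tol of it; matching is greedy-chronological and
one-to-one, and T_tol must stay below half a period (the default
reporting tolerance is 49% of the period). Reference frame labels come
from annotation intervals at hop resolution, half-open [onset, offset).
The local SNR of an annotated interval is the mean per-bin power in the
class's bands over the mean per-bin power in the 100 Hz bands flanking
them (overlapping signal bins excluded), in dB; a Hann spectrogram is
recommended for it because rectangular-window sidelobes leak alarm power
into the flanks and bias the measure low. Cross-validation is
leave-one-session-out with per-class counts accumulated over folds before
rates are computed, the overall score being the unweighted class mean;
optional stratification groups annotated intervals into 5 dB local-SNR
bins and also sweeps a discard threshold.

## The synthetic soundscape generator

Clinical recordings of this kind are not redistributable, so the package
ships a generator that emulates their structure: periodic
sum-of-sinusoid alarms with 10 ms raised-cosine ramps, multiple device
versions, up to several alarms overlapping, and broadband backgrounds
(white, pink, or a "mixture" that adds occasional broadband transients
and short random-frequency beeps emulating the many other tonal devices
of a busy unit — it is these tonal interferers that defeat generic
spectral features while leaving band-restricted ones untouched). Two
channels are derived: the outside microphone (used for detection) and an
inside-incubator channel (gain 0.5 plus a first-order 2 kHz low-pass, a
plausible stand-in for incubator attenuation; used for SNR measurement).
Alarm gains are set in closed form from the additive band powers of the
filtered alarm and background so that the *measured* local SNR matches
the requested target — including the alarm's own leakage into the
flanking noise bands, without which high-SNR targets come out
systematically low. Event onsets snap to the hop grid so that annotation
intervals align with analysis frames.

Registry frequencies and durations are documented synthetic placeholders
(300–4000 Hz, ≥100 Hz apart except one deliberately shared frequency
between three classes); they encode the structural facts of the alarm
family, not any particular device's values, so comparisons to real
per-class behaviour can only be qualitative. The generator does not model
speech, infant cries, ventilator flow noise, or room acoustics —
passing tests on it demonstrates that the pipeline recovers known
structure under controlled noise, not clinical performance.

Study-condition defaults used by the tests and the acceptance script:
training scenes of 180–240 s and test scenes of 120–300 s with three
classes (a1, a7, a10); high-SNR period recovery at 15–20 dB local SNR
(training is multi-condition, 15/20 dB); the SNR trend over test scenes
at 0/5/10/15/20 dB with training at 10–20 dB — 0 dB is excluded from
*training* because at 0 dB local SNR the alarm contributes essentially
nothing to its own band, so its "alarm" frames are background and
contaminate the class model; and the feature/post-processing comparison
on mixture-background scenes at 5–10 dB, the noisy interference-rich
regime where knowledge-based features earn their keep. Problem sizes
(scene lengths, burst counts) are chosen so each experiment carries
enough alarm periods (≈ 50–100 per class) for stable rates.

## Known limitations

* Frames that straddle a tone onset/offset carry only partial tone energy
  and dominate the residual frame-level error at high SNR; this is a
  property of the 85 ms frame against 300–600 ms tones, shared by every
  per-frame detector, and it is why period-level scores are the headline
  metric.
* $\lambda_s$ is trained on stationary sinusoids; frequency-modulated
  alarms would need a different training corpus.
* The single-Gaussian detector is well matched to the low-dimensional SD
  features but underfits rich multimodal feature distributions; the NN
  alternative is provided but needs more data to shine.
* The local-SNR measure is bounded below by ~0 dB by construction (the
  signal band contains the noise floor), so "0 dB local SNR" means an
  alarm at the detectability limit.
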