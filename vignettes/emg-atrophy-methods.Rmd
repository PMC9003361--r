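---
title: "Methods: distinguishing causes of muscular atrophy from surface EMG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: distinguishing causes of muscular atrophy from surface EMG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emgatrophy)
```

## The clinical problem

Muscular atrophy after a limb fracture has two common, clinically distinct
causes: peripheral nerve injury and disuse under limb immobilization. The
distinction matters because rehabilitation differs — immobilization atrophy
recovers with exercise once the cast is removed, whereas nerve injury needs
simultaneous nerve and muscle rehabilitation. The established bedside
electrodiagnostic tool, needle EMG, is invasive and painful; surface EMG
(sEMG) is painless but noisier, so its diagnostic use requires careful
feature engineering and classification.

This package implements a complete, testable sEMG analysis chain for this
binary problem. Because no public recordings accompany the clinical
protocols it emulates, the package includes first-class synthetic
generators that reproduce the statistical structure the analysis relies on,
with ground truth for every downstream stage. Throughout, the positive
class is immobilization (label 1) and the negative class nerve injury
(label 0).

## Signal model

### Motor-unit action potentials and voluntary sEMG

Voluntary sEMG is modeled as a superposition of motor-unit action potential
(MUAP) trains. Each unit contributes a first-order Hermite–Rodriguez
waveform

$$ w(t) = A \, (t/\tau)\, e^{-(t/\tau)^2}, \qquad t \ge 0, $$

a standard parsimonious MUAP surrogate with time scale $\tau$ (default 3 ms,
jittered ±20% across units) and per-unit amplitude $A$ (default 0.5 mV,
jittered ±30%). Units fire as renewal processes with a 20 ms refractory
floor and a mean rate of 20 Hz, typical of maximum voluntary contraction.
Gaussian baseline noise (0.02 mV) and a 50 Hz powerline sinusoid (0.05 mV)
are added. The resulting signal has an RMS near 0.2 mV and a spectrum
concentrated between 20 and 500 Hz, as expected for surface recordings.

### Conditions and effect sizes

A condition is parameterized by the number of active motor units, an
amplitude scale, a time scale, and (for evoked responses) a latency scale:

| condition       | motor units | amplitude scale | time scale | latency scale |
|-----------------|------------:|----------------:|-----------:|--------------:|
| healthy         | 20          | 1.0             | 1.0        | 1.0           |
| nerve injury    | 8           | 1.0             | 0.7        | 1.4           |
| immobilization  | 18          | 0.7             | 1.0        | 1.0           |

The choices encode the physiology: nerve injury denervates motor units
(fewer units, hence a much smaller compound response) and slows conduction
(longer latency, briefer synchronized response), while immobilization mainly
shrinks fibres (smaller per-unit amplitude) with only mild unit loss. These
defaults were fixed once, before any classifier was run, so that evoked
responses show a clear group separation while voluntary-contraction feature
distributions of the two atrophy groups overlap — the regime in which a
classifier is actually needed. Subject-level severity (log-normal, 10% on
amplitude, 5% on duration) and per-acquisition gain (log-normal, 15%,
emulating electrode repositioning) create realistic between-sample spread.

### Evoked responses

Electrical stimulation of the nerve (2 mA, 2 Hz, 100 µs pulses for 30 s,
held as protocol metadata) elicits one epoch per stimulus: a 1 ms biphasic
stimulus artifact — modeled as a decaying half-cosine whose peak falls
exactly on the stimulus sample, so that it is visible at any sampling rate —
followed, after the epoch's true latency, by a compound muscle response.
The response template is one full sine cycle over the response duration,
scaled so that its peak-to-peak amplitude equals
`mu_count * amplitude_scale * 0.5` mV; its rectified area is then exactly
`amplitude * duration / pi`. Latency, amplitude and duration receive
per-epoch log-normal jitter (5%, 10%, 5%). Ground truth for all four
parameters is recorded per epoch before noise, which is what makes the
parameter-recovery tests possible.

At the defaults this yields healthy responses of 10 mV / 10 ms / 5 ms
latency, nerve-injury responses of 4 mV / 7 ms / 7 ms latency and
immobilization responses of 6.3 mV / 10 ms / 5 ms latency: the clinical
sign pattern (amplitude, duration and area smaller, latency longer for
nerve injury).

## Preprocessing

Channels are first sorted into a canonical role order (affected before
unaffected limb, tibialis anterior before gastrocnemius). Each channel then
passes a 50 Hz notch and a fourth-order Butterworth 20–500 Hz band-pass, in
that order. Numerical choices:

* **Notch design.** A constrained second-order IIR notch (biquad) with
  quality factor Q = 30, i.e. a −3 dB width of about 1.7 Hz. The `signal`
  package supplies the Butterworth designs but no notch designer, so the
  biquad coefficients are computed directly from the standard closed form.
* **Band-pass order.** "Fourth order" is read as the overall order (two
  poles per edge), the common reading; the per-edge order is configurable.
* **Zero-phase filtering.** Both filters run forward–backward by default
  because the analysis is offline and evoked latency must not be biased by
  group delay; a causal mode exists for streaming-like use, and latency
  extraction assumes the zero-phase default.
* **Warm-up.** The first 0.5 s of every record is flagged as filter warm-up
  and excluded from feature windows by default.

The sampling rate is configurable with a default of 2 kHz — four times the
upper band edge.

## Evoked-response analysis

Stimulus artifacts are detected as local maxima of |signal| above 8 times
the median absolute deviation, with a minimum separation of half the
inter-stimulus interval; detecting nothing is an explicit error, never an
empty success. Epochs of 100 ms follow each artifact (the inter-stimulus
interval at 2 Hz is 500 ms, so epochs never overlap).

Within an epoch, the first 2 ms are blanked to remove the artifact. The
response onset is the first sample where |signal| exceeds
`max(3 × SD(baseline), 5% of the epoch peak)` and stays above threshold for
at least 1 ms; the offset is the end of the last such excursion. The four
reported parameters are:

* **latency** — stimulus to onset, with sub-sample linear interpolation of
  the threshold crossing;
* **amplitude** — peak-to-peak between onset and offset, with parabolic
  (three-point quadratic) refinement of both extrema, which removes the
  sampling bias that would otherwise reach several percent for brief
  responses at 2 kHz;
* **duration** — onset to offset, both crossings interpolated;
* **AUC** — trapezoidal integral of the rectified signal between onset and
  offset, in mV·ms.

Epochs with no supra-threshold response return an explicit no-response
marker rather than zeros. Group differences are assessed per parameter with
an unpaired two-tailed Welch t-test at α = 0.05, reported as means ± SD
with t, p and a significance flag.

Two deliberately resolved ambiguities: latency is measured to response
*onset* (the standard reading of "delay" in nerve-conduction practice), and
the duration endpoint is the last sustained supra-threshold sample
(return-to-baseline), not a zero-crossing count. Accuracy at the defaults,
verified by the test suite over 200 epochs spanning latencies 3–10 ms,
amplitudes 1–10 mV and durations 4–12 ms: mean absolute errors of about
0.09 ms (latency), 0.05% (amplitude), 0.14 ms (duration) and 3% (AUC)
noiselessly, roughly doubling with noise at 5% of the response peak. The
AUC error is dominated by trapezoidal integration of 4 ms responses that
contain only eight samples at 2 kHz; tolerances are therefore stated on the
sweep mean, not per epoch.

## Feature extraction and ratio normalization

Features are gathered on 0.5 s windows with an overlap of 1/8 of the window
(step 0.4375 s) over a stable segment of the recording — for the 60 s
maximum-voluntary-contraction move, the middle 30 s by default. A 30 s
segment yields 68 windows and a 40 s segment 91, counts pinned in the tests
by an independent start-enumeration oracle. The alternative reading of
"overlap of 1/8" (step = window/8) is available via
`windowing_config(overlap_mode = "step_fraction")`. Per window:

* RMS $= \sqrt{\overline{x^2}}$ (mV), ARV $= \overline{|x|}$ (mV),
  iEMG $= \sum |x_i| / f_s$ (mV·s, the time-integral convention);
* MDF and MPF from a Hann-tapered periodogram zero-padded to ≥1024 points,
  restricted to the 20–500 Hz analysis band; MPF is the power-weighted mean
  frequency and MDF the half-power frequency with linear interpolation
  between bins. Welch averaging is deliberately not used inside a 0.5 s
  window — it would destroy the frequency resolution the band moments need.

Raw features depend on electrode contact and on the subject's willingness
to contract, so classification uses dimensionless ratios: each affected
feature is divided by the per-channel-role mean of a reference table. For
patients the reference is the contralateral channel of the same muscle; for
rats it is the pre-surgery healthy baseline of the same animal (10 baseline
epochs, averaged — the baseline acquisition count is not prescribed by the
protocol, so a small round number was fixed). Note that iEMG, being a time
integral, scales with the analysed duration, so its rat-protocol ratio
carries a constant duration factor common to all samples; this is harmless
after standardization and is retained for definitional fidelity.

For rat acquisitions the five features are computed over the concatenated
post-stimulus response windows (3–50 ms after each artifact). The artifact
itself carries no condition information but dominates whole-record power
identically in every group; restricting to the response window is what
makes the amplitude features informative.

The classifier feature set is {RMS, iEMG, MDF, MPF}; ARV is computed and
stored but excluded from the default model.

## Classification and evaluation

Three classifier families are supported behind one interface: gradient
boosted decision trees (xgboost), an RBF-kernel SVM (e1071) and k-nearest
neighbours (class). Hyperparameters come from small grids — gbdt: depth
{2, 3, 4} × trees {100, 300} at learning rate 0.1; SVM: cost {1, 10, 100} ×
γ = {0.5, 1, 2}/p with p features; kNN: odd k in {3, 5, 7, 9} — selected by
inner 3-fold cross-validated accuracy inside each training fold. Features
are standardized with training-fold statistics only; the test labels are
used solely to count the confusion matrix.

Evaluation follows the protocol of the emulated studies: an 80/20 random
row-level split and stratified 5-fold cross-validation, with accuracy,
specificity and sensitivity computed from TP/TN/FP/FN with positive =
immobilization. Zero-denominator metrics are reported as undefined (`NA`),
never as zero. Because windowed rows from one subject are highly
correlated, row-level splitting leaks subject identity; a subject-wise
split (`split_dataset(..., subject_wise = TRUE)`) is provided as the
stricter alternative, and neither mode is silently preferred — the
protocol's stated row-level split is the default, the leak is documented
here.

## What the synthetic data does and does not show

The generators reproduce: the two-protocol structure (6 + 6 rats × 150
evoked acquisitions plus healthy baselines; 7 + 3 patients × 4 channels ×
60 s MVC), the clinical evoked sign pattern, overlapping-but-separable
voluntary feature distributions, powerline interference, and
subject/acquisition-level gain variability. They do not model volume
conduction, electrode geometry, skin impedance, motor-unit synchronization
during fatigue, or non-stationarity of contraction effort. Passing tests
therefore demonstrate that the *analysis chain* is correct and that the
protocol's accounting and directional effects are faithfully propagated —
not that the reported synthetic classification accuracies would transfer to
real recordings. On the default synthetic cohorts the rat protocol is
close to perfectly classifiable (acquisition-level features average 60
evoked responses, so their variance is small) and the patient protocol is
harder (single-window features), reproducing the qualitative ordering of
the two experiments.

## Problem sizes and determinism

The test suite and the acceptance script run the full default rat cohort
(1800 acquisitions of 30 s at 2 kHz, streamed one acquisition at a time so
records are regenerated on demand rather than stored) and the full default
patient cohort (10 patients, 4 × 60 s channels). Every stochastic stage —
generators, severity factors, splits, fold assignment, classifier
randomness — derives from a single master seed through a documented integer
sub-seeding scheme (`derive_seed()`), so identical configuration and seed
reproduce byte-identical feature tables and reports.

## Known limitations

* The MUAP and response templates are stereotyped; real compound responses
  are polyphasic and their parameters correlate within subjects.
* The stable-segment selector is manual (configuration); an automatic
  variance-based selector was considered out of scope for the default path.
* The rat-protocol iEMG ratio mixes amplitude and duration information (see
  above).
* Classifier grids are small by design; the goal is honest comparison of
  three families under identical protocol, not leaderboard tuning.
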