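---
title: "Wavelet coherence analysis of vHIT recordings: models, calibration and design"
author: "vhitwca"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wavelet coherence analysis of vHIT recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

The video head impulse test (vHIT) records paired head and eye angular
velocities while an examiner delivers brief, passive, high-acceleration head
rotations (about 5 degrees in about 100 ms) in the plane of one semicircular
canal (SCC). The device reports a 0.7 s record per impulse with the rotation
onset aligned at 0.1 s, so the vestibulo-ocular reflex (VOR) response
occupies 0.1-0.2 s and corrective saccades follow in 0.2-0.7 s. The
conventional summaries are the VOR gain (ratio of eye to head velocity
response) and the presence of covert/overt saccades.

This package analyzes the same recordings in the time-frequency domain. The
head and eye series `X`, `Y` are transformed with the analytic Morlet
continuous wavelet transform, and their magnitude-squared wavelet coherence
(MSWC) is

$$R^2_n(s) = \frac{\left|S\!\left(s^{-1} W^{XY}_n(s)\right)\right|^2}
{S\!\left(s^{-1}|W^X_n(s)|^2\right)\; S\!\left(s^{-1}|W^Y_n(s)|^2\right)},$$

where $W^{XY} = W^X \overline{W^Y}$ is the cross-wavelet spectrum and $S$
a smoothing operator applied first along time and then across scales.
Without $S$ the ratio is identically 1 for any pair of signals, so the
smoothing is what gives the statistic discriminative content; the package
keeps an explicit `smooth = FALSE` switch purely so that tests can assert
this degeneracy.

The derived scalar is the **coherent frequency**: scanning the grid
frequencies upward from the lowest resolvable one, a frequency qualifies
when MSWC stays at or above 0.9 at *every* time sample of the exam; the
statistic is the top of the contiguous qualifying band anchored at the
lowest frequency, with a 0 sentinel when even the lowest frequency fails.
Because the head rotation profile is essentially fixed by the exam
protocol, this frequency summarizes how faithfully — over what bandwidth —
the eye follows the head, and is degraded both by low VOR gain mechanisms
and by saccadic interruptions.

## Numerical choices

* **Morlet parameters.** $\omega_0 = 6$; scale-to-frequency conversion via
  the Fourier factor $\lambda = 4\pi/(\omega_0 + \sqrt{2+\omega_0^2})$.
* **Grid.** 12 voices per octave. The smallest scale is placed so the top
  grid frequency equals Nyquist (125 Hz at the default 250 Hz sampling,
  which also keeps the 0-125 Hz crop window fully representable); scales
  extend down to 1.4 Hz, the full-record period.
* **Smoothing.** Time: per-scale Gaussian $e^{-t^2/(2s^2)}$ with
  reflection at the record edges. Scale: boxcar spanning 0.6 octave,
  truncated at the grid ends. These are the published defaults for the
  Morlet at $\omega_0 = 6$.
* **Guarding and clipping.** The coherence denominator is clamped from
  below at $10^{-12}$ of its maximum, and the ratio clipped to $[0,1]$.
  The clamp (rather than an additive constant) keeps the self-coherence
  identity exact wherever power is non-negligible while still pinning
  cells whose power is numerically zero (e.g. a smooth impulse has no
  energy near Nyquist).
* **CWT padding.** Zero-padding to at least four times the record length
  (power of two) so the largest scales do not wrap.
* **Cone of influence.** Computed (e-folding time $\sqrt{2}s$) and stored,
  but *not* used to mask the coherent-frequency scan: the statistic is
  defined over the entire exam. Masking is available behind a flag. Note
  that rows below ~4 Hz are edge-affected everywhere in a 0.7 s record;
  this is a property of the statistic itself, not of the implementation.
* **Scan semantics.** "Over the entire exam" is read as *every time
  sample* (min over time), and "evaluated from the lowest frequency" as a
  contiguity requirement. Both alternatives (mean over time; global
  maximum qualifying frequency) remain selectable.

One consequence of the grid floor deserves note: below ~3 Hz a 0.7 s
record holds under two cycles and the smoothed estimator has roughly one
degree of freedom, so even independent signals can exceed the 0.9
threshold there by chance. Null inputs therefore sometimes return a small
nonzero coherent frequency (confined below the physiological 4-8 Hz
impulse band) instead of the 0 sentinel. Cohort statistics are unaffected
because real traces are genuinely coherent over that floor band.

## The synthetic cohort generator

No clinical recordings are distributed; the generator reproduces the
statistical structure the analysis assumes, calibrated to the published
cohort statistics of 64 patients with sudden sensorineural hearing loss
with vertigo (20 complete recovery, 18 partial, 26 none; PR and NR share
the published incomplete-recovery distributions).

* **Head profile.** Raised-cosine velocity bump (amplitude 5 degrees,
  duration 100 ms, onset 0.1 s; small per-repeat jitter). Closed-form peak
  $2A/D$ and integral $A$.
* **Eye model.** `eye = gain x lowpass(head, cutoff) + saccade pulses +
  noise`, with a zero-phase brick-wall low-pass (so coherence, not lag,
  carries the class signal), Gaussian-pulse saccades (covert onsets in
  0.12-0.19 s, overt in 0.21-0.45 s, peaks 100-250 deg/s), and white noise
  high-passed at the coupling edge (default 8 deg/s RMS) so that the
  noise spectrum dominates above the cutoff.
* **Sign convention.** Both channels are stored sign-rectified (VOR
  response positive), as vHIT devices display them; corrective saccades
  are positive pulses.
* **Edge calibration.** A Morlet filter bank is constant-Q, so a spectral
  edge at $f$ is read back systematically below $f$ (by roughly 1-3
  voices, depending on $f$). The generator therefore computes, once per
  (rate, record length, impulse shape, grid, noise level), the
  deterministic map from brick-wall edge position to recovered coherent
  frequency — including the analytic expectation of the smoothed
  high-passed-noise power in the eye auto-spectrum — and inverts it, so
  the configured `couplingCutoff` is exactly what the analysis recovers
  (to grid quantization). With the cutoff at Nyquist the model reduces to
  `eye = gain * head` identically.
* **Gain convention.** The band-limit redistributes a little impulse
  energy outside the 0.1-0.2 s window, which would bias the area-ratio
  gain low; the VOR component is rescaled so the impulse-window area
  ratio equals the configured gain exactly.
* **Cutoff/gain truncation.** Coupling cutoffs are drawn truncated to
  [2, 15] Hz — below 2 Hz the statistic is unresolvable within a 0.7 s
  record, above 15 Hz it exceeds the impulse bandwidth — and gains to
  [0.05, 1.5]. Truncation is by resampling, so no probability mass piles
  at the bounds.
* **Class calibration.** Incomplete-recovery means/sds per SCC follow the
  published values (posterior gain 0.83 +/- 0.30, posterior coherent
  frequency 4.94 +/- 2.28 Hz, saccade percentages 30.4/21.8 total/overt,
  and analogously for the horizontal and anterior SCCs). CR means are
  recovered from the 20/44 mixture identity against the published overall
  means (e.g. posterior gain 0.99), except the posterior CR coherent
  frequency which is fixed at 6.4 +/- 1.0 Hz. CR saccade probabilities
  (not published) are set to roughly a third of the incomplete-class
  rates. Saccade occurrence is drawn per repeat as a three-way categorical
  (overt / covert-only / none), so the configured percentages are exactly
  the expected per-repeat shares.
* **Severity factor.** A latent per-patient standard normal correlates
  gain (loading -0.5), coupling cutoff (-0.5) and saccade propensity
  (+0.6 on the logit) across SCCs, emulating common vestibular end-organ
  damage; this is what gives the cohort its within-class correlation
  structure rather than pure class-mixture separation.
* **Determinism.** All randomness descends from the config seed through
  per-patient substreams; identical configs regenerate identical cohorts
  byte for byte (including CSV serialization).

What the generator does **not** emulate: nystagmus, blinks, device
tracking artifacts, head bounce, bilateral ears, or device-side saccade
de-saturation. Passing tests therefore demonstrate correctness of the
analysis pipeline under the stated causal model, not robustness to every
artifact of clinical recordings.

## Feature extraction

VOR gain defaults to the ratio of summed velocities (area ratio) over the
fixed 0.1-0.2 s impulse window — the convention of clinical devices,
robust to single-sample peaks — with samples of detected saccades excised
first; a peak-ratio method is available. Saccade detection thresholds the
signed residual `eye - gain x head` at 60 deg/s for at least 10 ms, then
refines event boundaries outward to a third of the threshold (two-level
refinement; the raw crossing quantizes onsets of brief pulses a full
sample or two late). Events are covert when the onset falls at or before
0.2 s. Saccade percentages are per-repeat shares (fraction of repeats
containing at least one overt event / any event), one of the readings the
published table permits. The representative repeat per SCC is the one
with the median coherent frequency (lower median for even counts, ties to
the earliest repeat).

## Augmentation

Three schemes balance the minority class (20 CR) to the majority size
(44): **OS** copies representative samples at random with replacement;
**EDE** extracts real non-representative repeats whose coherent frequency
is closest to the representative's (ties to the earliest; patients cycled
round-robin, exhausted patients skipped), so it never fabricates data;
**ITS** forms per-sample convex combinations of two distinct subjects'
trace triplets with one Uniform(0,1) weight shared across SCCs and
channels. By default augmentation is applied inside training folds only,
avoiding leakage; a paper-mode placement (augment before splitting, the
replication order) is available, and the package asserts the qualitative
ordering (augmented at least as accurate as raw) only under paper-mode,
where part of the gain is expected to be leakage — that is a property of
the replicated design, documented rather than hidden.

## Imaging and classification

Coherence maps are rendered with a fixed 256-level perceptually uniform
colormap (a bijection on the quantized [0,1] scale, so tests can decode
pixels back to values), linear time axis, log2 frequency axis, no
annotations. Three crop presets (horizontal 0.1-0.35 s x 4-8 Hz; vertical
0.1-0.2 s x 0-12 Hz; subtotal 0.1-0.3 s x 0-125 Hz) are rendered per SCC
at 224 x 224 each (equal pixel weight per canal), tiled in the fixed
order horizontal-anterior-posterior (left-to-right, or top-to-bottom for
the vertical style; the subtotal style tiles left-to-right), and resized
bilinearly to the backbone input. For 0-lower-bound frequency windows the
log-axis floor is the grid's lowest resolvable frequency; window regions
the grid cannot represent are painted as zero coherence, preserving the
window geometry.

The default backbone is a *fixture*: a small convolutional stack
(7x7/stride 4 conv, ReLU, 2x2 max-pool, 3x3/stride 2 conv, ReLU, 6x6
average pooling; 576 features) with He-scaled weights drawn once from a
fixed seed and never trained. Random convolutional projections preserve
the geometry that matters here (the height of the high-coherence band and
its saccadic interruptions) and make the pipeline fully reproducible with
no downloaded artifacts; pretrained backbones can be plugged in through
the same interface. The classifier is a linear SVM (C = 1) on z-scored
features (scaler fit on training data only), under stratified 5-fold
cross-validation repeated 10 times. Accuracy is the headline metric;
confusion counts are stored. The label-permutation control is run on the
class-balanced (over-sampled) variant, where chance is 50%; on the raw
20/44 mixture a permuted-label classifier drifts toward the 69% majority
rate, which would make the control uninformative.

## Problem sizes in the test suite

The bundled tests exercise the default study conditions: the 64-patient
cohort with 10 repeats per SCC for cohort-level checks; 50 seeds x 10
repeats per coupling cutoff for recovery; 1000 random pairs for coherence
bounds; 30-40 random draws for property checks such as trace invariants
and monotone degradation. Scaled-down sizes for pure invariants keep the
suite fast while the cohort-level checks run at full study scale.

## Known limitations

* The coherent-frequency statistic saturates at the grid top for
  noise-free full-band traces and has a spurious-qualification floor
  below ~3 Hz (see above).
* Recovery of a coupling cutoff is quantized to the 12-voice grid; a
  +/- half-voice discretization error is irreducible.
* The generator's edge calibration is computed for the canonical impulse
  profile at the class noise level; per-repeat amplitude/duration jitter
  perturbs it only negligibly (coherence is scale-invariant).
* PR and NR are generated from identical distributions; the pipeline
  classifies CR vs PR+NR and makes no attempt to separate PR from NR.
* With 20 minority patients, per-fold test sets contain only 4 CR
  samples; fold accuracies are correspondingly coarse (steps of ~8%).
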