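# vhitwca

Wavelet coherence analysis of video head impulse test (vHIT) recordings,
with a calibrated synthetic cohort generator, time-series augmentation, and
image-based outcome classification.

## The problem

The vHIT records paired head and eye angular velocities during brief,
passive head rotations in the plane of each semicircular canal (SCC). The
vestibulo-ocular reflex (VOR) drives the eye opposite the head; clinicians
summarize each exam by the VOR gain (eye/head velocity response ratio) and
by corrective saccades. In sudden sensorineural hearing loss with vertigo
(SSNHLV), vestibular function measured this way carries prognostic
information about hearing recovery under steroid treatment — but gain and
saccade counts compress a rich, non-stationary response into two numbers.

This package targets researchers in vestibular otoneurology and biomedical
signal processing who want the time-frequency view of the same recordings:
how coherently, and over what bandwidth, the eye follows the head.

## The statistic

For head and eye velocity series $X$ and $Y$, the magnitude-squared
wavelet coherence (MSWC) at time index $n$ and scale $s$ is

$$R^2_n(s) = \frac{\left|S\left(s^{-1} W^{XY}_n(s)\right)\right|^2}
{S\left(s^{-1}\left|W^X_n(s)\right|^2\right)\,
 S\left(s^{-1}\left|W^Y_n(s)\right|^2\right)},
\qquad W^{XY}_n = W^X_n \overline{W^Y_n},$$

with $W^X$, $W^Y$ the analytic Morlet ($\omega_0 = 6$) continuous wavelet
transforms and $S$ a smoothing operator (per-scale Gaussian in time, 0.6
octave boxcar across scales). The **coherent frequency** of an exam is the
highest frequency, scanned upward from the lowest resolvable one, at which
$R^2 \ge 0.9$ holds at every time sample of the 0.7 s record (0 if even
the lowest frequency fails). The pipeline around it:

- `simulateCohort()` — synthetic vHIT cohorts (no clinical data are
  bundled) calibrated to published SSNHLV cohort statistics: 64 patients
  (20 complete / 18 partial / 26 no recovery), 10 repeats per SCC, with
  per-class gain, coupling-cutoff and saccade distributions;
- `mswc()`, `coherentFrequency()` — the coherence map and its scalar;
- `vorGain()`, `detectSaccades()`, `buildFeatureTable()` — time-series
  features and the per-patient, per-SCC feature table;
- `augmentOS()`, `augmentEDE()`, `augmentITS()` — minority-class
  balancing by over-sampling, extraction of extra real repeats, and convex
  interpolation between subjects;
- `renderCoherenceRaster()`, `cropAndTile()` — coherence plots cropped in
  three styles (horizontal 0.1–0.35 s × 4–8 Hz, vertical 0.1–0.2 s ×
  0–12 Hz, subtotal 0.1–0.3 s × 0–125 Hz) and tiled per patient in the
  order horizontal–anterior–posterior;
- `fixtureBackbone()`, `extractFeatures()`, `trainSvm()`,
  `repeatedStratifiedCV()` — convolutional feature extraction with a
  linear SVM under repeated stratified 5-fold cross-validation,
  classifying complete vs incomplete hearing recovery.

## Worked example

One synthetic posterior-canal exam set from the no-recovery class:

```r
library(vhitwca)
params <- defaultClassParams()$NR$posterior   # gain 0.83 ± 0.30, cutoff 4.94 ± 2.28 Hz
reps <- simulateExamSet("posterior", params, repeats = 10, seed = 42)

gains <- sapply(reps, vorGain)
freqs <- sapply(reps, function(tr)
  coherentFrequency(mswc(headVelocity(tr), eyeVelocity(tr), samplingRate(tr))))
round(gains, 3)
#>  [1] 1.109 0.942 1.081 1.271 1.719 0.849 0.065 0.884 0.887 1.151
round(freqs, 2)
#>  [1] 3.69 9.84 4.65 6.57 6.96 5.21 2.76 7.81 3.48 7.37

rep1 <- selectRepresentative(reps, freqs)
attr(rep1, "frequency")
#> [1] 5.214218
saccadePercentages(reps)
#> overt total
#>     0    50
```

The per-repeat gains scatter widely (this class draws true gains of
0.83 ± 0.30, and repeats with covert saccades are harder to estimate);
the coherent frequencies scatter around the class's ~4.9 Hz coupling
cutoff, dragged low on saccade-laden repeats. The representative repeat —
the one with the median coherent frequency, 5.21 Hz here — is what enters
imaging and classification; half of the repeats contained a saccade, none
of them overt. Rendering and classifying a whole cohort:

```r
cohort <- simulateCohort(cohortConfig(seed = 7))
an     <- analyzeCohort(cohort)                    # MSWC of all 1920 repeats
ft     <- buildFeatureTable(cohort, an)            # 192 rows: 64 patients x 3 SCCs

samples <- representativeSamples(cohort, an)
bb <- fixtureBackbone()
for (i in seq_along(samples)) {
  img <- cropAndTile(lapply(an[[i]]$scc, `[[`, "repMap"), "horizontal")
  samples[[i]]$features <- extractFeatures(img, bb)
}
res <- repeatedStratifiedCV(samples, sapply(samples, `[[`, "label"),
                            list(), cvConfig(seed = 11))
res
#> CVResult: 10 x 5-fold CV, accuracy 84.3% [9.7]
```

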