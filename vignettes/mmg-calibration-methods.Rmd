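---
title: "Methods: MMG-based calibration of transcutaneous spinal cord stimulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MMG-based calibration of transcutaneous spinal cord stimulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Transcutaneous spinal cord stimulation (tSCS) requires, per patient, a
back-electrode position and a stimulation current before therapy can
start. The classical calibration reads posterior root muscle (PRM)
responses from leg-muscle EMG during double-pulse stimulation of
increasing intensity: a large first response whose second response (50 ms
later) is strongly suppressed indicates afferent (reflex) recruitment,
which is what the therapy targets. `tscstune` implements this EMG
pipeline, and on top of it a mechanomyographic (MMG) alternative: the
skin-normal axis of an accelerometer on the muscle belly replaces the
EMG electrodes, and a supervised classifier predicts the EMG-derived
response class from acceleration features. From either class grid the
package derives the personalized therapy parameters and quantifies how
well the sensor-based prediction agrees with the EMG ground truth.

# Calibration protocol and data model

One *session* is one (subject, electrode position, day). At each current
of a ramp (default 5 mA to the subject's tolerance limit in 5 mA steps)
the stimulator delivers three double biphasic pulses (50 ms inter-pulse
interval, 1 ms per phase) and three single pulses, 5 s apart. Four
muscles are recorded bilaterally — quadriceps (Q) and triceps surae
(TS) — with EMG at 1 kHz and acceleration at 0.5 kHz on a shared clock.

An *event* is the averaged response of one muscle at one current (and
position): averaged double-pulse EMG, averaged single- and double-pulse
acceleration, and their difference DIFF. Mechanical twitches last far
longer than the 50 ms inter-pulse interval, so the two twitch responses
of a double pulse overlap; subtracting the single-pulse response
isolates the mechanical response to the second pulse — that is the
purpose of the added single-pulse stimulation.

# Preprocessing

1. **Artifact detection.** Stimulation artifacts are detected in the EMG
   as threshold crossings of the double-differenced signal. The
   threshold is adaptive, `max(k * MAD(ddx), 0.25 * max(|ddx|))` with
   `k = 8`: the MAD term scales with sensor noise, the peak-fraction
   floor keeps near-noise-free recordings from triggering on the evoked
   response itself. Crossings within a 10 ms refractory period merge
   into one detection at the *first* crossing (the artifact onset); the
   onset is used rather than the |ddx| maximum because the biphasic
   artifact's double derivative has a two-sample near-tie whose argmax
   jitters by one sample under noise, which would misalign repetitions.
2. **Cropping.** Sweeps are cropped to the half-open window
   [-10, 400) ms around the first artifact: 410 EMG samples, 205
   acceleration samples. This half-open convention is binding for all
   window arithmetic in the package.
3. **Anti-hum filter.** Mains hum is removed by harmonic regression: a
   least-squares fit of intercept plus 50 Hz sine and cosine (samples
   within [-2, 5] ms of either pulse excluded from the fit), with the
   fitted 50 Hz component subtracted. A conventional zero-phase IIR
   notch was evaluated first and rejected: on a 410-sample crop its
   transient spans a large part of the window (a pure 50 Hz tone was
   attenuated by only 9-15 dB over the crop) and it rings on the
   stimulation artifact, injecting tens of microvolts into the
   measurement windows. The regression filter is zero-phase by
   construction, exact on a stationary tone, and artifact-free. Its
   assumption — hum stationary over 0.41 s — is mild; harmonics can be
   added via the `freqs` argument.
4. **Running-median high-pass.** A 31-sample sliding median (reflection
   padding at the edges) is subtracted from the EMG. This removes
   baseline drift and offsets without the ringing a linear high-pass
   would add around the artifact; responses shorter than half the
   kernel pass nearly unchanged.
5. **Gravity filter.** Acceleration sweeps are cropped on the EMG
   artifact clock (the acceleration has no artifact) and the mean of
   the first 10 ms (5 samples) is subtracted.
6. **Similarity check.** The three repetitions are compared pairwise by
   the coefficient of determination (squared Pearson correlation); the
   largest mutually connected group (every pair with R² ≥ 0.8, a
   maximum clique — subsets are enumerated largest-first so ties
   resolve deterministically) is averaged, and events with fewer than
   two connected repetitions are marked faulty. For acceleration sweeps
   a *low-activity floor* (peak-to-peak < 0.3 m/s²) connects
   repetitions regardless of R²: correlation between no-activity
   recordings is pure noise, and without the floor every
   no-response event would be discarded.
7. **Noisy-EMG exclusion.** Averaged EMG whose baseline RMS in
   [-10, 0) ms exceeds 20 µV (e.g. spontaneous activity surviving the
   average) is excluded. Exclusions are counted, never raised as
   errors.

# EMG ground-truth classes

From the averaged double-pulse EMG, `A1` and `A2` are the peak-to-peak
amplitudes in windows [5, 45] ms after pulse 1 and [55, 95] ms (the same
window shifted by the inter-pulse interval). The windows are a package
choice — they must end before the following pulse; the defaults leave
room for the observed 7-17 ms response latencies. Suppression is

$$S = \left(1 - \frac{A_2}{A_1}\right) \times 100.$$

Classes: **0** no response (A1 < 50 µV), **1** reflex response
(A1 > 50 µV and S > 60 %), **2** direct muscular response (A1 > 50 µV
and S < 60 %). The thresholds use strict inequalities on both sides, so
boundary cases are assigned downward (A1 = 50 µV → class 0, S = 60 % →
class 2); `A1 = 0` gives class 0 with S reported as 0 and flagged
undefined. The 2-class scheme merges classes 1 and 2 into "response"
(read as a union of the two classes); the merge identity
`label_2 = (label_3 > 0)` holds event-wise and is tested on every
synthetic cohort.

# MMG features

Each valid event yields 36 named features in three categories: *meta*
(BMI, sex, age, height — 4), *stim* (position, current — 2) and *MMG
data* (30). Amplitude statistics use `winA1` = [10, 60) ms after pulse 1
for the quadriceps, shifted 5 ms right for the triceps surae (delayed
response onset), and `winDIFF` = the same window after pulse 2.
Decisions taken where the feature list was under-specified:

* Spectral features (mean power frequency, area under and maximum of
  the PSD) use a Hann-windowed periodogram of the **full cropped
  signal**, not the amplitude windows; the signal is not demeaned since
  the crops are already baseline-corrected. Mean power frequency is
  the power-weighted mean Σf·P / ΣP.
* The correlation features (r and r² between single- and double-pulse
  acceleration) both use the window from 50 ms to the end of the
  crop. The listed windows for these two features differ in wording;
  the longer reading was applied to both.
* The curve distance between double- and single-pulse signals in
  `winDIFF` is the discrete Fréchet distance between the two
  (t [ms], amplitude) polylines, computed by the standard dynamic
  program and validated against a recursive oracle.
* Zero-crossing rate is counted over the full crop, in crossings per
  second, with zero samples inheriting the preceding sign.
* Max slope is the maximum forward difference times the sampling rate.
* Features 35-36 are the peak-to-peak amplitudes of the *other*
  recorded muscle of the same leg (crosstalk probe); if that partner
  event is invalid they are 0.

`SET-OBSERVE` = MMG data + meta (34 columns); `SET-PREDICT` = meta +
stim (6 columns), a sensor-less baseline containing nothing computed
from acceleration samples.

# Classification

Three families — radial-basis SVM (`e1071`), random forest (`ranger`,
100 trees) and LDA (`MASS`) — are evaluated in leave-one-subject-out
(LOSO) cross-validation with balanced accuracy (mean per-class recall
over the classes present in the test subject's truth; unadjusted, no
chance correction). Class imbalance is met with inverse-frequency case
weights (uniform priors for LDA). Features are standardized with
training-fold mean/SD for SVM and LDA and passed raw to the forest;
the standardization never sees the test subject.

Hyperparameters come from a random search (default 50 settings) scored
by an inner LOSO loop over the training subjects only, tuned on the
3-class labels and reused for the 2-class problem. Sampling
distributions (the upstream convention names the parameters but not
their ranges): SVM `C`, `gamma` log-uniform on [1e-3, 1e3]; RF
`min_samples_split` ∈ 2..20, `min_samples_leaf` ∈ 1..10, `max_depth` ∈
{3..30, unlimited}, `max_samples` ∈ [0.3, 1]; LDA `tol` log-uniform on
[1e-6, 1e-2] and estimation method ∈ {moment, mle}. The R forest maps
`min_samples_split`/`min_samples_leaf` to `min.node.size`/`min.bucket`
and `max_samples` to `sample.fraction`; LDA's `n_components` is
recorded but does not affect class prediction, which R's `lda`
determines from all discriminants.

# Therapy-parameter search

From a class grid over (position, current, muscle) the nested search
keeps positions with at least two class-1 labels at one current
(rule 1) and ranks survivors lexicographically: largest class-1 count
per current (2), smallest gap between the onset of any leg response and
that maximum (3), lowest such current (4), largest total class-1 count
(5); residual ties go to the most caudal position (a configurable
package choice — the rules are described as "nested" upstream without a
formal tie order, and the lexicographic cascade is the natural
formalization). "Onset of leg response" is the smallest current with
any non-zero label at the position. The therapy current is exactly 90 %
of the smallest current with a class-1 label at the selected position
(sub-motor threshold; no rounding); if no position passes rule 1 the
current is 0 mA. Single-position measurements (the patient protocol)
run the same cascade on their one position and report only the
current. Agreement between EMG-derived and classifier-derived
parameters uses an inclusive ±5 mA margin; under the 2-class scheme
"class 1" simply means "response", and the same search applies.

# The synthetic cohort generator

No public recordings exist for this calibration protocol, so the
package ships a generative model that reproduces the statistical
structure the pipeline relies on; all tests and the acceptance script
run on it.

* **Recruitment.** Each muscle has a reflex and a direct pathway with
  logistic recruitment in current (slope 0.8 mA). Reflex thresholds
  are drawn from the midpoints of the 5 mA current grid
  (12.5-27.5 mA), direct thresholds 15-20 mA above — afferents recruit
  first. Midpoint placement reflects that real thresholds rarely
  coincide with the tested grid and keeps each tested current clearly
  on one side of the sigmoid. The ground-truth class of an event
  follows from these thresholds.
* **EMG.** Responses are biphasic Gaussian-derivative waveforms
  (peak-to-peak normalized), latency 7-9 ms for Q and 14-17 ms for TS,
  gain 300-600 µV (direct pathway 2x); the second response of a double
  pulse is suppressed by `S_true` ∈ [75, 95] % (reflex) or `S_direct`
  ∈ [5, 25] % (direct). Biphasic rectangular artifacts (±5000 µV, 1 ms
  per phase) mark the pulses; additive Gaussian noise, default 4 µV SD.
* **MMG.** Twitches are double-exponential transients (rise 18-25 ms,
  decay 55-75 ms, a few hundred ms long — hence the overlap),
  amplitude 1-3 m/s² at full recruitment, onset 5 ms after the EMG
  response; the second twitch is scaled by the suppression and by a
  non-linear summation gain ∈ [1.0, 1.4]; no artifact; noise 0.03 m/s²
  SD. The waveform shapes are package choices; any smooth shape with
  these latencies and durations would serve.
* **Cohort structure.** Healthy subjects are measured at several
  positions, patients on two days at one position. Each subject has a
  best position; other positions shift all thresholds up by 5 mA per
  4 cm. The discomfort-limited maximum current is drawn per subject
  from 35-50 mA, so subjects contribute unequal event counts. With
  these defaults a mixed cohort shows roughly half class-0, a bit
  under 40 % class-1, and a small class-2 remainder, matching the
  imbalance this kind of calibration data shows in practice.

What the generator does **not** emulate: motor-unit structure,
movement and crosstalk artifacts, impedance or electrode-geometry
effects, hum (the anti-hum stage is exercised by dedicated tone tests),
and inter-day drift. Classifier accuracies on this synthetic cohort
are therefore upper bounds tied to its clean class structure — the
pipeline's correctness, not human-data performance, is what passing
tests demonstrate.

# Problem sizes and reproducibility

The test suite and the acceptance script work at deliberately modest
scale: the shared fixture cohort has 3 subjects, the end-to-end
recovery experiment 12 subjects (8 healthy × 2 positions + 4 patients,
~700 events) with the random search reduced to 5 iterations — enough
for every fold to rank hyperparameters while keeping a full run in the
order of a minute. All randomness flows from explicit integer seeds
(cohort plan, session noise, model fits, searches), and equal seeds
reproduce sessions, studies and reports byte for byte; `ranger` runs
single-threaded with a fixed seed for the same reason.

# Known limitations

* The 50 µV / 60 % class thresholds are fixed conventions of the EMG
  calibration; the generator was *not* tuned so that events sit near
  these boundaries, and real transition-zone events will classify less
  cleanly than synthetic ones.
* The low-activity similarity floor (0.3 m/s²) is calibrated to the
  generator's noise scale; real sensors may need a different floor
  (it is an argument of `preprocess_session()`).
* The harmonic-regression hum filter assumes stationary hum within a
  sweep and only removes the listed frequencies.
* Only the three classifier families above are implemented; the LOSO
  and search machinery is family-agnostic, but no other models are
  wired in.
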