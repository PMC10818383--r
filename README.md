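# tscstune

Calibration of transcutaneous spinal cord stimulation (tSCS) from
evoked muscle responses, with a mechanomyographic (MMG) alternative to
the classical EMG readout.

## What it does

Before tSCS therapy, an examiner must find a back-electrode position
and a stimulation current that recruit afferent (posterior-root) fibres
at a tolerable intensity. The classical procedure reads leg-muscle EMG
during double-pulse stimulation of increasing current: the first
response's peak-to-peak amplitude `A1` and the paired-pulse suppression

    S = (1 - A2/A1) x 100

classify each (muscle, current) event as **0** no response
(`A1 < 50 uV`), **1** reflex response (`A1 > 50 uV`, `S > 60%`) or
**2** direct muscular response (`A1 > 50 uV`, `S < 60%`). Reflex
activity marks afferent recruitment; the therapy current is 90% of the
lowest current with a reflex response at the best electrode position
(sub-motor threshold).

`tscstune` implements this pipeline end to end, and on top of it the
sensor-simplified variant in which accelerometers on the muscle belly
(MMG) replace the EMG electrodes:

* **Synthetic cohort generator** — sessions with sigmoidal reflex /
  direct recruitment, paired-pulse suppression, long overlapping
  mechanical twitches with non-linear summation, stimulation artifacts
  and sensor noise, plus the ground-truth registry to score against.
* **Preprocessing** — artifact detection (double-derivative
  threshold), cropping to [-10, 400) ms, 50 Hz anti-hum filtering,
  running-median high-pass, gravity filtering, R2-based similarity
  averaging of repetitions, DIFF = double - single acceleration.
* **EMG labeling** — `A1`, `A2`, `S` and the 2-/3-class ground truth.
* **MMG features** — 36 features per event (meta, stimulation, and 30
  acceleration-derived features incl. discrete Frechet distance, mean
  power frequency, zero-crossing rates), grouped into the sensor-based
  `SET-OBSERVE` (34 columns) and the sensor-less `SET-PREDICT` (6).
* **Classification** — leave-one-subject-out (LOSO) cross-validation
  of random forest, RBF-SVM and LDA with balanced accuracy, balanced
  class weights and nested random hyperparameter search.
* **Therapy parameters** — the nested position/current rule cascade,
  the 90% sub-motor current, and agreement reports (exact / +-5 mA /
  position match) between EMG-derived and classifier-derived
  parameters.

Functions take and return tibbles, so stages chain with the pipe;
fitted LOSO experiments support `tidy()`, `glance()` and `autoplot()`.

## Worked example

```r
library(tscstune)
library(dplyr)

# 4-subject demo cohort: 3 healthy (2 electrode positions), 1 patient
spec <- cohort_spec(n_healthy = 3, n_patients = 1,
                    positions_healthy = c(0, 4), n_days_patient = 1L,
                    seed = 7)
tabs <- build_study_tables(spec, seed = 8)
cat("events:", nrow(tabs$labels), " excluded:", tabs$exclusions$fraction, "\n")
#> events: 236  excluded: 0
table(tabs$features$label_3)
#>   0   1   2
#> 106  92  38
```

236 averaged events were produced (none excluded by the similarity or
noise checks); the EMG ground truth is dominated by no-response events,
with direct muscular responses (class 2) rarest — the imbalance this
kind of calibration data shows in practice.

```r
loso <- run_experiment(tabs$features, dataset = "ALL",
                       feature_set = "SET-OBSERVE", n_classes = 3,
                       model_family = "RF", search_iterations = 2,
                       seed = 9)
glance(loso)
#>   n_subjects mean_balanced_accuracy sd_balanced_accuracy model_family
#> 1          4                      1                    0 RF

gt <- derive_therapy_params(tabs$features, "label_3")
gt
#>   subject_id group   measurement position first_reflex therapy_current n_positions
#> 1 P1         patient d1                 4           15            13.5           1
#> 2 S1         healthy d1                 0           20            18             2
#> 3 S2         healthy d1                 0           20            18             2
#> 4 S3         healthy d1                 4           15            13.5           2

ml <- derive_therapy_params(bind_rows(loso$folds$predictions), "pred")
agreement_summary(compare_therapy_params(gt, ml))
#>   n prop_exact_current prop_within_margin n_position prop_position prop_position_and_margin
#> 1 4                  1                  1          3             1                        1
```

On this clean synthetic cohort the LOSO random forest reproduces the
EMG classes perfectly (mean balanced accuracy 1.0), and the therapy
parameters derived from its predictions — e.g. 13.5 mA = 0.9 x 15 mA at
the +4 cm position for S3 — match the EMG-derived parameters for every
subject (all agreement proportions 1.0). Real recordings contain
artifact sources the generator deliberately omits, so these numbers
demonstrate pipeline correctness, not expected clinical accuracy.

A thin command-line wrapper is installed under
`inst/cli/tscs-tune.R` (`tscs-tune.R all --config run.yaml --seed 1
--out results/`).

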