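#' Reference study cohort specification
#'
#' Returns the subject-level specification of the bundled demonstration
#' cohort: 11 healthy adults, each measured on a single day at three (two
#' subjects: four) back-electrode positions relative to the L3/L4
#' intervertebral space, and 11 patients with progressive multiple
#' sclerosis, each measured on two days at a single position. Ages, sex,
#' height and BMI match a typical mixed calibration study population; the
#' synthetic generator attaches per-muscle response models to these
#' subjects.
#'
#' @return A tibble with one row per subject: `subject_id`, `group`
#'   (`"healthy"`/`"patient"`), `age` (years), `sex` (0 male, 1 female),
#'   `height` (cm), `bmi` (kg/m^2), `n_days`, and a `positions` list-column
#'   of electrode offsets in cm (positive = cranial to L3/L4).
#' @seealso [cohort_spec()] for constructing custom cohorts,
#'   [generate_cohort()] for realizing recordings.
#' @export
#' @examples
#' reference_cohort_spec()
reference_cohort_spec <- function() {
  healthy <- tibble(
    subject_id = paste0("S", 1:11),
    group = "healthy",
    age = c(35, 30, 38, 33, 38, 33, 27, 28, 25, 40, 49),
    sex = c(0, 0, 0, 0, 0, 1, 1, 1, 1, 0, 0),
    height = c(173, 200, 180, 175, 184, 177, 159, 160, 173, 190, 176),
    bmi = c(24.1, 21.5, 22.5, 25.5, 24.8, 20.7, 18.6, 20.3, 20, 21.6, 30.7),
    n_days = 1L
  )
  healthy$positions <- lapply(1:11, function(i) {
    if (i %in% c(4, 10)) c(-4, 0, 4, 8) else c(-4, 0, 4)
  })
  patients <- tibble(
    subject_id = paste0("P", 1:11),
    group = "patient",
    age = c(65, 48, 66, 50, 53, 35, 60, 58, 55, 65, 60),
    sex = c(0, 1, 1, 1, 1, 1, 0, 0, 0, 0, 1),
    height = c(176, 159, 174, 173, 160, 181, 165, 174, 186, 178, 164),
    bmi = c(28.09, 25.71, 25.76, 16.7, 19.53, 19.5, 23.88, 20.15, 26.01,
            23.67, 19.33),
    n_days = 2L
  )
  # patients: one position per day, 0-4.5 cm cranial; fixed per subject here
  patients$positions <- lapply(seq_len(11), function(i) c(0, 4)[1 + i %% 2])
  bind_rows(healthy, patients)
}

#' Construct a synthetic cohort specification
#'
#' Builds a subject table for [generate_cohort()] with plausible metadata
#' drawn at random. Healthy subjects are measured once at several electrode
#' positions; patients are measured on `n_days` days at a single position
#' (a protocol that keeps patient burden low).
#'
#' @param n_healthy,n_patients Number of subjects per group.
#' @param positions_healthy Electrode offsets (cm from L3/L4) tested for
#'   each healthy subject.
#' @param positions_patient Candidate single positions for patients.
#' @param n_days_patient Measurement days per patient.
#' @param seed Integer seed for the metadata draw.
#' @return A tibble in the format of [reference_cohort_spec()].
#' @export
#' @examples
#' cohort_spec(n_healthy = 2, n_patients = 1, seed = 1)
cohort_spec <- function(n_healthy = 11, n_patients = 11,
                        positions_healthy = c(-4, 0, 4),
                        positions_patient = c(0, 4),
                        n_days_patient = 2L,
                        seed = 1L) {
  stopifnot(n_healthy + n_patients >= 1)
  set.seed(seed)
  mk <- function(n, prefix, group, age_range, n_days, positions) {
    if (n == 0) return(NULL)
    height <- round(runif(n, 158, 195))
    tibble(
      subject_id = paste0(prefix, seq_len(n)),
      group = group,
      age = round(runif(n, age_range[1], age_range[2])),
      sex = sample(c(0, 1), n, replace = TRUE),
      height = height,
      bmi = round(runif(n, 18, 30), 1),
      n_days = as.integer(n_days),
      positions = positions
    )
  }
  bind_rows(
    mk(n_healthy, "S", "healthy", c(24, 50), 1L,
       replicate(n_healthy, positions_healthy, simplify = FALSE)),
    mk(n_patients, "P", "patient", c(35, 70), n_days_patient,
       lapply(seq_len(n_patients), function(i)
         positions_patient[sample.int(length(positions_patient), 1)]))
  )
}

#' Stimulation protocol used during a calibration session
#'
#' The calibration applies, at each intensity, `reps_per_pulse_type` double
#' pulses (two biphasic pulses 50 ms apart) followed by the same number of
#' single biphasic pulses (1 ms per phase), with `inter_stimulus_gap`
#' seconds between stimulation incidences. The pattern is repeated with
#' increasing current from `start_current` in steps of `increment` until
#' `max_current` (in practice, the subject's discomfort level).
#'
#' @param start_current,increment,max_current Current ramp in mA.
#' @param reps_per_pulse_type Repetitions of each pulse type per current.
#' @param inter_pulse_interval Gap between the two pulses of a double
#'   pulse, ms.
#' @param phase_width Width of each biphasic pulse phase, ms.
#' @param inter_stimulus_gap Time between stimulation incidences, s.
#' @return A list of class `tscs_protocol`.
#' @export
stimulation_protocol <- function(start_current = 5, increment = 5,
                                 max_current = 50, reps_per_pulse_type = 3L,
                                 inter_pulse_interval = 50, phase_width = 1,
                                 inter_stimulus_gap = 5) {
  stopifnot(increment > 0, max_current >= start_current,
            reps_per_pulse_type >= 1)
  structure(
    list(start_current = start_current, increment = increment,
         max_current = max_current,
         reps_per_pulse_type = as.integer(reps_per_pulse_type),
         inter_pulse_interval = inter_pulse_interval,
         phase_width = phase_width,
         inter_stimulus_gap = inter_stimulus_gap),
    class = "tscs_protocol")
}

#' @export
print.tscs_protocol <- function(x, ...) {
  cat(sprintf(
    "tSCS calibration protocol: %g-%g mA step %g, %d+%d pulses/current, %g s gap\n",
    x$start_current, x$max_current, x$increment,
    x$reps_per_pulse_type, x$reps_per_pulse_type, x$inter_stimulus_gap))
  invisible(x)
}

protocol_currents <- function(protocol) {
  seq(protocol$start_current, protocol$max_current, by = protocol$increment)
}
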