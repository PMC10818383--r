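## Synthetic evoked-response generator.
##
## Waveform shapes (any smooth parametric shape with realistic latencies and
## durations would do; these are the documented choices):
##   * EMG response: first derivative of a Gaussian (biphasic, ~6 ms wide),
##     peak-to-peak normalised to 1, placed `latency` ms after the pulse.
##   * Stimulation artifact: two rectangular phases of 1 ms each (+A then -A)
##     at the pulse time, EMG only.
##   * MMG twitch: double exponential exp(-t/decay) - exp(-t/rise), peak
##     normalised to 1, onset `latency + acc_delay` ms after the pulse; lasts
##     several hundred ms so the two twitches of a double pulse overlap.

gauss_deriv <- function(t_ms, center_ms, width_ms = 1.5) {
  z <- (t_ms - center_ms) / width_ms
  (-z * exp(-z^2 / 2)) / (2 * exp(-0.5))
}

twitch_envelope <- function(t_ms, onset_ms, rise, decay) {
  tt <- t_ms - onset_ms
  h <- ifelse(tt >= 0, exp(-tt / decay) - exp(-tt / rise), 0)
  t_pk <- rise * decay / (decay - rise) * log(decay / rise)
  h / (exp(-t_pk / decay) - exp(-t_pk / rise))
}

# Pathway recruitments and the resulting first/second response amplitudes.
response_amplitudes <- function(model, current) {
  r_r <- recruitment(current, model$reflex_threshold, model$slope)
  r_d <- recruitment(current, model$direct_threshold, model$slope)
  g_r <- model$emg_gain
  g_d <- model$emg_gain * model$direct_gain_ratio
  list(
    r_r = r_r, r_d = r_d,
    emg1 = g_r * r_r + g_d * r_d,
    emg2 = g_r * r_r * (1 - model$S_true / 100) +
      g_d * r_d * (1 - model$S_direct / 100),
    acc1 = model$twitch_amplitude * (r_r + r_d),
    acc2 = model$twitch_amplitude *
      (r_r * (1 - model$S_true / 100) + r_d * (1 - model$S_direct / 100)) *
      model$summation_gain)
}

pulse_times_ms <- function(pulse_type) {
  switch(pulse_type,
         single = 0,
         double = c(0, IPI_MS),
         stop("invalid pulse_type: ", pulse_type, call. = FALSE))
}

# Deterministic (noise-free) sweep pair on a [-50, 450) ms window around
# the first pulse.
clean_event_pair <- function(model, current, pulse_type) {
  pulses <- pulse_times_ms(pulse_type)
  amp <- response_amplitudes(model, current)
  t_emg <- seq(-50, 449, by = 1000 / EMG_RATE)
  t_acc <- seq(-50, 448, by = 1000 / ACC_RATE)
  emg <- numeric(length(t_emg))
  acc <- numeric(length(t_acc))
  for (k in seq_along(pulses)) {
    p <- pulses[k]
    i <- which(t_emg == p)
    emg[i] <- emg[i] + model$artifact_amplitude
    emg[i + 1] <- emg[i + 1] - model$artifact_amplitude
    a_emg <- if (k == 1) amp$emg1 else amp$emg2
    a_acc <- if (k == 1) amp$acc1 else amp$acc2
    emg <- emg + a_emg * gauss_deriv(t_emg, p + model$latency)
    acc <- acc + a_acc *
      twitch_envelope(t_acc, p + model$latency + model$acc_delay,
                      model$twitch_rise, model$twitch_decay)
  }
  list(emg = emg, acc = acc, t_emg = t_emg, t_acc = t_acc)
}

#' Simulate one stimulation event for one muscle
#'
#' Generates the EMG and skin-normal acceleration sweep evoked by a single
#' or double biphasic pulse at the given current, on a window from 50 ms
#' before to 450 ms after the first pulse. The EMG contains the biphasic
#' stimulation artifact(s) and short evoked response(s); the acceleration
#' contains the long overlapping twitch transients and no artifact. For a
#' double pulse the second EMG response is suppressed according to the
#' model's pathway-specific suppression, and the second twitch is
#' additionally scaled by the non-linear summation gain.
#'
#' @param model A [muscle_model()].
#' @param current Stimulation current in mA (> 0).
#' @param pulse_type `"single"` or `"double"`.
#' @param seed Optional integer seed for the additive Gaussian sensor
#'   noise; the same seed and arguments reproduce the sweep exactly.
#' @return A list with `emg` (microvolt, 1 kHz), `acc` (m/s^2, 0.5 kHz),
#'   and the corresponding time vectors `t_emg`, `t_acc` in ms relative to
#'   the first pulse.
#' @export
#' @examples
#' sw <- simulate_event_pair(muscle_model(), current = 25,
#'                           pulse_type = "double", seed = 1)
#' range(sw$emg)
simulate_event_pair <- function(model, current, pulse_type, seed = NULL) {
  stopifnot(inherits(model, "muscle_model"), current > 0)
  sw <- clean_event_pair(model, current, pulse_type)
  if (!is.null(seed)) set.seed(seed)
  if (model$emg_noise_sd > 0)
    sw$emg <- sw$emg + rnorm(length(sw$emg), 0, model$emg_noise_sd)
  if (model$acc_noise_sd > 0)
    sw$acc <- sw$acc + rnorm(length(sw$acc), 0, model$acc_noise_sd)
  sw
}

#' Generate one synthetic calibration session
#'
#' Realizes a full session recording for one subject at one electrode
#' position: for each current of the protocol ramp, `reps_per_pulse_type`
#' double-pulse then single-pulse stimulation events, logged with their
#' timestamps, on four EMG channels (1 kHz) and four skin-normal
#' acceleration channels (0.5 kHz) sharing a common time origin.
#'
#' @param meta One-row data frame or list with `subject_id`, `group`,
#'   `age`, `sex`, `height`, `bmi`.
#' @param protocol A [stimulation_protocol()].
#' @param models Named list of four [muscle_model()] objects (one per
#'   muscle in `MUSCLES` order).
#' @param position Electrode offset from L3/L4 in cm.
#' @param seed Integer seed; fixed seed gives an identical session.
#' @param measurement Measurement-day identifier, e.g. `"d1"`.
#' @return A `tscs_session`: list with `meta`, `position`, `measurement`,
#'   `emg` and `acc` signal tibbles (`time` in s plus one column per
#'   muscle), the `events` log (`timestamp`, `pulse_type`, `current`), the
#'   per-(muscle, current) `ground_truth` tibble, and the protocol.
#' @export
generate_session <- function(meta, protocol, models, position = 0,
                             seed = 1L, measurement = "d1") {
  stopifnot(inherits(protocol, "tscs_protocol"),
            length(models) == 4, all(MUSCLES %in% names(models)))
  set.seed(seed)
  currents <- protocol_currents(protocol)
  reps <- protocol$reps_per_pulse_type
  events <- tidyr::expand_grid(
    current = currents,
    pulse_type = c(rep("double", reps), rep("single", reps))) %>%
    mutate(timestamp = 0.5 + (row_number() - 1) * protocol$inter_stimulus_gap,
           repetition = rep(rep(seq_len(reps), 2), length(currents))) %>%
    select("timestamp", "pulse_type", "current", "repetition")

  duration <- max(events$timestamp) + 0.5
  n_emg <- ceiling(duration * EMG_RATE)
  n_acc <- ceiling(duration * ACC_RATE)

  emg <- matrix(0, n_emg, 4, dimnames = list(NULL, MUSCLES))
  acc <- matrix(0, n_acc, 4, dimnames = list(NULL, MUSCLES))
  for (m in MUSCLES) {
    md <- models[[m]]
    if (md$emg_noise_sd > 0) emg[, m] <- rnorm(n_emg, 0, md$emg_noise_sd)
    if (md$acc_noise_sd > 0) acc[, m] <- rnorm(n_acc, 0, md$acc_noise_sd)
  }
  for (e in seq_len(nrow(events))) {
    ts <- events$timestamp[e]
    i0_emg <- round(ts * EMG_RATE) + 1L   # sample at the first pulse
    i0_acc <- round(ts * ACC_RATE) + 1L
    for (m in MUSCLES) {
      sw <- clean_event_pair(models[[m]], events$current[e],
                             events$pulse_type[e])
      idx_e <- (i0_emg - 50):(i0_emg + 449)
      idx_a <- (i0_acc - 25):(i0_acc + 224)
      emg[idx_e, m] <- emg[idx_e, m] + sw$emg
      acc[idx_a, m] <- acc[idx_a, m] + sw$acc
    }
  }

  ground_truth <- tidyr::expand_grid(muscle = MUSCLES, current = currents) %>%
    mutate(class_true = purrr::map2_int(
      .data$muscle, .data$current, ~ true_class(models[[.x]], .y)))

  structure(list(
    meta = as.list(meta[c("subject_id", "group", "age", "sex",
                          "height", "bmi")]),
    position = position,
    measurement = measurement,
    emg = bind_cols(tibble(time = (seq_len(n_emg) - 1) / EMG_RATE),
                    as_tibble(emg)),
    acc = bind_cols(tibble(time = (seq_len(n_acc) - 1) / ACC_RATE),
                    as_tibble(acc)),
    events = events,
    ground_truth = ground_truth,
    protocol = protocol), class = "tscs_session")
}

#' @export
print.tscs_session <- function(x, ...) {
  cat(sprintf(
    "tscs_session %s (%s) pos %+g cm, %s: %d events, %.0f s\n",
    x$meta$subject_id, x$meta$group, x$position, x$measurement,
    nrow(x$events), max(x$emg$time)))
  invisible(x)
}

#' Generate a synthetic cohort of calibration sessions
#'
#' Realizes one session per (subject, position, day) from a cohort
#' specification, drawing per-muscle response models for each subject.
#' Each subject has a "best" electrode position at which recruitment
#' thresholds are lowest; other positions shift all thresholds up by 5 mA
#' per 4 cm. Discomfort-limited termination is emulated by drawing each
#' subject's maximum current from `max_current_range`, so subjects
#' contribute unequal event counts.
#'
#' @param spec Cohort specification tibble, see [cohort_spec()].
#' @param seed Integer root seed; the same seed reproduces the cohort
#'   byte-for-byte. Different seeds redraw models and noise but keep the
#'   protocol event structure.
#' @param protocol Base [stimulation_protocol()]; the per-subject maximum
#'   current overrides its `max_current`.
#' @param max_current_range Range (mA) from which each subject's
#'   discomfort limit is drawn, snapped to the current grid.
#' @param emg_noise_sd,acc_noise_sd Sensor noise levels passed to every
#'   muscle model (set to 0 for noise-free data).
#' @return A `tscs_cohort`: list with `sessions` (list of
#'   `tscs_session`), `truth` (registry tibble of the true model
#'   parameters and best positions), `spec`, and `protocol`.
#' @export
#' @examples
#' co <- generate_cohort(cohort_spec(n_healthy = 1, n_patients = 1,
#'                                   positions_healthy = c(0, 4)), seed = 7)
#' length(co$sessions)
generate_cohort <- function(spec, seed = 1L,
                            protocol = stimulation_protocol(),
                            max_current_range = c(35, 50),
                            emg_noise_sd = 4, acc_noise_sd = 0.03) {
  stopifnot(nrow(spec) >= 1)
  plan <- cohort_plan(spec, seed, protocol, max_current_range,
                      emg_noise_sd, acc_noise_sd)
  sessions <- lapply(plan$entries, realize_session)
  structure(list(sessions = sessions, truth = plan$truth,
                 spec = spec, protocol = protocol),
            class = "tscs_cohort")
}

# Deterministic per-session plan (models, seeds, protocols) for a cohort
# spec. generate_cohort() materializes every session; the pipeline streams
# over the same plan one session at a time to bound memory.
cohort_plan <- function(spec, seed, protocol, max_current_range,
                        emg_noise_sd, acc_noise_sd) {
  entries <- list()
  truth <- list()
  for (s in seq_len(nrow(spec))) {
    subj <- spec[s, ]
    positions <- subj$positions[[1]]
    set.seed((seed * 10007L + s * 97L) %% .Machine$integer.max)
    best_position <- positions[sample.int(length(positions), 1)]
    max_grid <- seq(max_current_range[1], max_current_range[2],
                    by = protocol$increment)
    max_c <- max_grid[sample.int(length(max_grid), 1)]
    subj_protocol <- stimulation_protocol(
      start_current = protocol$start_current, increment = protocol$increment,
      max_current = max_c,
      reps_per_pulse_type = protocol$reps_per_pulse_type,
      inter_pulse_interval = protocol$inter_pulse_interval,
      phase_width = protocol$phase_width,
      inter_stimulus_gap = protocol$inter_stimulus_gap)
    models_by_pos <- lapply(positions, function(p)
      sample_subject_models(best_position, p, emg_noise_sd, acc_noise_sd))
    names(models_by_pos) <- as.character(positions)
    for (day in seq_len(subj$n_days)) {
      for (p in positions) {
        models <- models_by_pos[[as.character(p)]]
        sess_seed <- (seed * 10007L + s * 97L + day * 13L +
                        round(p) * 5L + 1000L) %% .Machine$integer.max
        entries[[length(entries) + 1L]] <- list(
          meta = subj, protocol = subj_protocol, models = models,
          position = p, seed = sess_seed, measurement = paste0("d", day))
        truth[[length(truth) + 1L]] <- bind_rows(
          lapply(models, model_registry_row)) %>%
          mutate(subject_id = subj$subject_id, measurement = paste0("d", day),
                 position = p, best_position = best_position,
                 max_current = max_c, .before = 1)
      }
    }
  }
  list(entries = entries, truth = bind_rows(truth))
}

realize_session <- function(entry) {
  generate_session(entry$meta, entry$protocol, entry$models,
                   position = entry$position, seed = entry$seed,
                   measurement = entry$measurement)
}

#' @export
print.tscs_cohort <- function(x, ...) {
  cat(sprintf("tscs_cohort: %d sessions, %d subjects\n",
              length(x$sessions), nrow(x$spec)))
  invisible(x)
}
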