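#' Per-muscle evoked-response model
#'
#' Parametric generative model for one muscle's evoked electrical and
#' mechanical response. Reflex (afferent-mediated) and direct (efferent)
#' pathways recruit sigmoidally with current; reflex fibres have the lower
#' threshold. The second response of a 50 ms double pulse is suppressed by
#' `S_true` percent for the reflex pathway (post-activation suppression)
#' and only by `S_direct` percent for the direct pathway. The mechanical
#' twitch is a long double-exponential transient whose second occurrence is
#' additionally scaled by `summation_gain` (non-linear force summation).
#'
#' @param muscle One of `"Q_left"`, `"Q_right"`, `"TS_left"`, `"TS_right"`.
#' @param reflex_threshold,direct_threshold Recruitment midpoints in mA;
#'   `reflex_threshold < direct_threshold`.
#' @param slope Sigmoid slope parameter, mA.
#' @param latency EMG response onset latency after the pulse, ms (longer
#'   for triceps surae than quadriceps).
#' @param emg_gain Peak-to-peak EMG amplitude at full reflex recruitment,
#'   microvolt.
#' @param direct_gain_ratio Direct-response EMG gain relative to
#'   `emg_gain`.
#' @param S_true,S_direct Percent suppression of the second response for
#'   the reflex and the direct pathway.
#' @param twitch_amplitude Peak acceleration at full recruitment, m/s^2.
#' @param twitch_rise,twitch_decay Twitch envelope time constants, ms.
#' @param acc_delay Extra electromechanical delay of the twitch relative
#'   to the EMG response, ms.
#' @param summation_gain Multiplicative scaling of the second twitch.
#' @param emg_noise_sd,acc_noise_sd Additive Gaussian sensor noise SDs.
#' @param artifact_amplitude Biphasic stimulation artifact amplitude in
#'   the EMG, microvolt (the acceleration channel has no artifact).
#' @return A list of class `muscle_model`.
#' @export
muscle_model <- function(muscle = "Q_left",
                         reflex_threshold = 17.5, direct_threshold = 32.5,
                         slope = 0.8, latency = 8,
                         emg_gain = 400, direct_gain_ratio = 2,
                         S_true = 85, S_direct = 15,
                         twitch_amplitude = 2, twitch_rise = 20,
                         twitch_decay = 65, acc_delay = 5,
                         summation_gain = 1.2,
                         emg_noise_sd = 4, acc_noise_sd = 0.03,
                         artifact_amplitude = 5000) {
  stopifnot(muscle %in% MUSCLES,
            reflex_threshold < direct_threshold,
            S_true >= 0, S_true <= 100,
            emg_noise_sd >= 0, acc_noise_sd >= 0,
            twitch_rise > 0, twitch_decay > twitch_rise)
  structure(as.list(environment()), class = "muscle_model")
}

#' @export
print.muscle_model <- function(x, ...) {
  cat(sprintf(
    "muscle_model %s: reflex %.1f mA, direct %.1f mA, latency %.1f ms, S %.0f%%\n",
    x$muscle, x$reflex_threshold, x$direct_threshold, x$latency, x$S_true))
  invisible(x)
}

#' Logistic recruitment of a response pathway
#'
#' Fraction of the pathway recruited at a given stimulation current,
#' modelled as a logistic sigmoid centred at the pathway threshold.
#'
#' @param current Stimulation current, mA.
#' @param threshold Recruitment midpoint, mA.
#' @param slope Sigmoid slope, mA.
#' @return Recruitment fraction in (0, 1).
#' @export
recruitment <- function(current, threshold, slope = 0.8) {
  stats::plogis((current - threshold) / slope)
}

#' True response class implied by a muscle model
#'
#' Ground-truth class of an event under the generative model: 0 below the
#' reflex threshold (no response), 1 between reflex and direct thresholds
#' (reflex response), 2 at or above the direct threshold (direct muscular
#' response).
#'
#' @param model A [muscle_model()].
#' @param current Stimulation current, mA (vectorised).
#' @return Integer class vector.
#' @export
true_class <- function(model, current) {
  ifelse(current >= model$direct_threshold, 2L,
         ifelse(current >= model$reflex_threshold, 1L, 0L))
}

# Draw a realistic model set for one subject at one electrode position.
# Thresholds live on the midpoints of the 5 mA current grid so that each
# tested current lies clearly on one side of the sigmoid; positions away
# from the subject's best position raise all thresholds by 5 mA per 4 cm.
sample_subject_models <- function(best_position, position,
                                  emg_noise_sd = 4, acc_noise_sd = 0.03) {
  shift <- 5 * abs(position - best_position) / 4
  models <- lapply(MUSCLES, function(m) {
    is_ts <- grepl("^TS", m)
    reflex <- sample(c(12.5, 17.5, 22.5, 27.5), 1) + shift
    muscle_model(
      muscle = m,
      reflex_threshold = reflex,
      direct_threshold = reflex + sample(c(15, 20), 1),
      slope = 0.8,
      latency = if (is_ts) runif(1, 14, 17) else runif(1, 7, 9),
      emg_gain = runif(1, 300, 600),
      S_true = runif(1, 75, 95),
      S_direct = runif(1, 5, 25),
      twitch_amplitude = runif(1, 1, 3),
      twitch_rise = runif(1, 18, 25),
      twitch_decay = runif(1, 55, 75),
      summation_gain = runif(1, 1.0, 1.4),
      emg_noise_sd = emg_noise_sd,
      acc_noise_sd = acc_noise_sd)
  })
  names(models) <- MUSCLES
  models
}

model_registry_row <- function(model) {
  tibble(
    muscle = model$muscle,
    reflex_threshold = model$reflex_threshold,
    direct_threshold = model$direct_threshold,
    latency = model$latency,
    emg_gain = model$emg_gain,
    S_true = model$S_true,
    S_direct = model$S_direct,
    twitch_amplitude = model$twitch_amplitude,
    summation_gain = model$summation_gain)
}
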