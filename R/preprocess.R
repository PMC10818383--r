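## Preprocessing of raw sweeps into averaged, validated events.
##
## Per event (muscle x current): the three double-pulse EMG repetitions are
## artifact-detected, cropped to [-10, 400) ms around the first artifact,
## notch-filtered at 50 Hz and high-passed by subtracting a 31-sample
## running median, then averaged after a pairwise-R^2 similarity check.
## Acceleration sweeps (double and single pulse) are cropped on the EMG
## artifact clock, gravity-filtered by subtracting the mean of the first
## 10 ms, similarity-averaged, and differenced (double - single = DIFF,
## the mechanical response to the second pulse).

#' Detect biphasic stimulation artifacts in an EMG sweep
#'
#' Marks an artifact where the double (second) derivative of the EMG
#' exceeds a threshold. The threshold adapts to the sweep: `k` times the
#' median absolute deviation of the double-differenced signal, floored at
#' `peak_fraction` of its absolute maximum so that near-noise-free sweeps
#' do not trigger on the evoked response itself. Crossings closer together
#' than the refractory period are merged into one detection at the
#' largest double-derivative magnitude.
#'
#' @param x Numeric EMG sweep (microvolt).
#' @param rate Sampling rate, Hz.
#' @param k Multiplier on the MAD of the double-differenced signal.
#' @param refractory Minimum separation of detections, ms.
#' @param peak_fraction Threshold floor as a fraction of `max(abs(ddx))`.
#' @return Integer vector of sample indices (1-based) of the detected
#'   artifacts, sorted; empty when nothing crosses the threshold (e.g. an
#'   all-zero sweep).
#' @export
#' @examples
#' sw <- simulate_event_pair(muscle_model(), 25, "double", seed = 1)
#' detect_stimulation_artifacts(sw$emg) # pulses at samples 51 and 101
detect_stimulation_artifacts <- function(x, rate = EMG_RATE, k = 8,
                                         refractory = 10,
                                         peak_fraction = 0.25) {
  n <- length(x)
  if (n < 3) return(integer(0))
  ddx <- diff(x, differences = 2) # ddx[j] is centred on x[j + 1]
  a <- abs(ddx)
  thr <- max(k * stats::mad(ddx), peak_fraction * max(a))
  hits <- which(a > thr & a > 0) + 1L
  if (length(hits) == 0) return(integer(0))
  refr <- refractory * rate / 1000
  # chain-cluster: split where the gap between crossings exceeds the
  # refractory period; the detection is each cluster's first crossing
  # (the artifact onset), which aligns repetitions consistently -- the
  # |ddx| maximum sits on a near-tie of the biphasic shape and would
  # jitter by one sample under noise
  grp <- cumsum(c(1, diff(hits) > refr))
  out <- vapply(split(hits, grp), `[`, integer(1), 1L)
  sort(unname(out))
}

#' Running-median high-pass filter
#'
#' Subtracts a sliding median (default kernel 31 samples) from the signal.
#' Removes baseline drift and offsets without the ringing of a linear
#' high-pass; short evoked responses pass nearly unchanged. Edges are
#' handled by reflection padding.
#'
#' @param x Numeric signal.
#' @param kernel Odd kernel size in samples.
#' @return The residual `x - runmed(x)`, same length as `x`.
#' @export
running_median_highpass <- function(x, kernel = 31) {
  stopifnot(kernel %% 2 == 1, kernel >= 3)
  n <- length(x)
  h <- (kernel - 1) / 2
  stopifnot(n > h + 1)
  xp <- c(rev(x[2:(h + 1)]), x, rev(x[(n - h):(n - 1)]))
  med <- stats::runmed(xp, kernel, endrule = "keep")
  x - med[(h + 1):(h + n)]
}

# Anti-hum filter: least-squares fit of intercept + sine/cosine at the
# hum frequency (and optional harmonics), subtracting the fitted hum
# component. Zero-phase by construction, exact on a pure tone, and -- in
# contrast to an IIR notch, whose transient spans a large part of a
# 410-sample crop and rings on the stimulation artifact -- free of edge
# and impulse artifacts. Samples listed in `exclude_idx` (e.g. around
# the stimulation artifacts) are ignored when fitting.
notch_filter <- function(x, rate = EMG_RATE, freqs = 50,
                         exclude_idx = NULL) {
  n <- length(x)
  t <- (seq_len(n) - 1) / rate
  basis <- do.call(cbind, lapply(freqs, function(f)
    cbind(sin(2 * pi * f * t), cos(2 * pi * f * t))))
  design <- cbind(1, basis)
  keep <- setdiff(seq_len(n), exclude_idx)
  coef <- qr.coef(qr(design[keep, , drop = FALSE]), x[keep])
  coef[is.na(coef)] <- 0
  x - as.numeric(basis %*% coef[-1])
}

#' Crop and filter an EMG sweep around its first stimulation artifact
#'
#' Crops to the half-open window \[-10, 400) ms around the artifact (410
#' samples at 1 kHz), applies a zero-phase 50 Hz anti-hum filter
#' (harmonic regression; the samples around the two possible stimulation
#' artifacts are excluded from the hum fit), and removes the baseline
#' with [running_median_highpass()].
#'
#' @param x Raw EMG sweep, microvolt.
#' @param artifact_index Sample index of the first stimulation artifact.
#' @param rate Sampling rate, Hz.
#' @param median_kernel Kernel of the running-median high-pass, samples.
#' @return Numeric vector of 410 filtered samples; time origin is the
#'   artifact, first sample at -10 ms.
#' @export
crop_filter_emg <- function(x, artifact_index, rate = EMG_RATE,
                            median_kernel = 31) {
  n_pre <- -CROP_START_MS * rate / 1000
  n_post <- CROP_END_MS * rate / 1000
  idx <- (artifact_index - n_pre):(artifact_index + n_post - 1)
  if (idx[1] < 1 || idx[length(idx)] > length(x))
    stop("crop window exceeds sweep bounds", call. = FALSE)
  cropped <- x[idx]
  t_ms <- CROP_START_MS + (seq_along(cropped) - 1) * 1000 / rate
  art_zone <- which((t_ms >= -2 & t_ms <= 5) |
                      (t_ms >= IPI_MS - 2 & t_ms <= IPI_MS + 5))
  running_median_highpass(notch_filter(cropped, rate = rate,
                                       exclude_idx = art_zone),
                          kernel = median_kernel)
}

#' Crop and gravity-filter an acceleration sweep
#'
#' The acceleration channel carries no stimulation artifact, so the
#' artifact time found in the synchronized EMG is used as the time origin.
#' The sweep is cropped to \[-10, 400) ms (205 samples at 0.5 kHz) and the
#' mean of the first 10 ms (5 samples) is subtracted as a non-dynamic
#' gravity filter.
#'
#' @param x Raw acceleration sweep, m/s^2.
#' @param artifact_time Artifact time in seconds on the sweep's clock.
#' @param rate Sampling rate, Hz.
#' @param t0 Time (s) of the first sample of `x` on the same clock.
#' @return Numeric vector of 205 gravity-filtered samples.
#' @export
preprocess_acc <- function(x, artifact_time, rate = ACC_RATE, t0 = 0) {
  if (is.na(artifact_time)) stop("missing artifact timestamp", call. = FALSE)
  i0 <- round((artifact_time - t0) * rate) + 1L
  n_pre <- -CROP_START_MS * rate / 1000
  n_post <- CROP_END_MS * rate / 1000
  idx <- (i0 - n_pre):(i0 + n_post - 1)
  if (idx[1] < 1 || idx[length(idx)] > length(x))
    stop("crop window exceeds sweep bounds", call. = FALSE)
  out <- x[idx]
  out - mean(out[seq_len(n_pre)])
}

#' Similarity check and averaging of repeated sweeps
#'
#' Computes the pairwise coefficient-of-determination (squared Pearson
#' correlation) connectivity matrix among the repetitions and averages the
#' largest group of mutually similar sweeps (every pair in the group with
#' R^2 at or above the threshold). If no group of at least two sweeps is
#' similar, the event is marked faulty. Optionally, sweeps whose
#' peak-to-peak amplitude is below `low_activity_floor` are treated as
#' trivially similar to each other: R^2 is not informative between
#' no-activity recordings that contain only sensor noise.
#'
#' @param reps List of equal-length numeric sweeps (>= 2).
#' @param r2_threshold Minimum pairwise R^2 to connect two repetitions.
#' @param low_activity_floor Peak-to-peak floor below which two sweeps are
#'   connected regardless of R^2; `NULL` disables the rule.
#' @return List with `average` (numeric or `NULL` when faulty), `kept`
#'   (indices of the averaged repetitions), `r2` (pairwise matrix), and
#'   `valid` (logical).
#' @export
similarity_average <- function(reps, r2_threshold = 0.8,
                               low_activity_floor = NULL) {
  stopifnot(length(reps) >= 2)
  n <- length(reps)
  len <- lengths(reps)
  if (length(unique(len)) != 1) stop("length mismatch", call. = FALSE)
  r2 <- diag(1, n)
  conn <- diag(TRUE, n)
  p2p <- vapply(reps, function(x) diff(range(x)), numeric(1))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (identical(reps[[i]], reps[[j]])) {
        r <- 1
      } else {
        r <- suppressWarnings(cor(reps[[i]], reps[[j]]))
        if (is.na(r)) r <- 0
      }
      r2[i, j] <- r2[j, i] <- r^2
      ok <- r^2 >= r2_threshold
      if (!is.null(low_activity_floor) &&
          p2p[i] < low_activity_floor && p2p[j] < low_activity_floor)
        ok <- TRUE
      conn[i, j] <- conn[j, i] <- ok
    }
  }
  # largest mutually-connected group = maximum clique; n is tiny (3 reps),
  # enumerate subsets largest-first, first hit wins (deterministic)
  best <- integer(0)
  for (size in n:2) {
    combos <- utils::combn(n, size)
    for (c_i in seq_len(ncol(combos))) {
      idx <- combos[, c_i]
      if (all(conn[idx, idx])) { best <- idx; break }
    }
    if (length(best)) break
  }
  if (length(best) < 2)
    return(list(average = NULL, kept = integer(0), r2 = r2, valid = FALSE))
  avg <- if (all(vapply(reps[best], identical, logical(1), reps[[best[1]]])))
    reps[[best[1]]] # averaging identical sweeps is exact
  else Reduce(`+`, reps[best]) / length(best)
  list(average = avg, kept = best, r2 = r2, valid = TRUE)
}

#' Response to the second pulse of a double stimulus (DIFF)
#'
#' Mechanical twitches outlast the 50 ms inter-pulse interval, so the two
#' responses of a double pulse overlap in the acceleration. Subtracting
#' the averaged single-pulse response from the averaged double-pulse
#' response isolates the response to the second pulse.
#'
#' @param acc_double_avg,acc_single_avg Equal-length averaged sweeps.
#' @return Sample-wise difference `acc_double_avg - acc_single_avg`.
#' @export
compute_diff <- function(acc_double_avg, acc_single_avg) {
  if (length(acc_double_avg) != length(acc_single_avg))
    stop("length mismatch", call. = FALSE)
  acc_double_avg - acc_single_avg
}

#' Preprocess a session into averaged events
#'
#' Runs the full preprocessing chain on one session recording and returns
#' one averaged event per (muscle, current): the averaged filtered
#' double-pulse EMG, the averaged single- and double-pulse acceleration,
#' and their DIFF, together with validity flags. Failures are recorded,
#' never raised: an event is excluded when artifact detection fails on any
#' repetition or the similarity check leaves fewer than two repetitions
#' (`similarity_fail`), or when the averaged EMG baseline in \[-10, 0) ms
#' is noisier than `noisy_emg_rms` (`noisy_emg`).
#'
#' @param session A `tscs_session` (see [generate_session()]) or an
#'   equivalently structured recording.
#' @param r2_threshold Similarity threshold passed to
#'   [similarity_average()].
#' @param acc_similarity_floor Peak-to-peak floor (m/s^2) under which
#'   acceleration repetitions count as similar (no-activity events).
#' @param noisy_emg_rms Baseline RMS bound (microvolt) for the averaged
#'   EMG.
#' @param artifact_k MAD multiplier for
#'   [detect_stimulation_artifacts()].
#' @return List with `events` (tibble: keys, list-columns `emg_double`,
#'   `acc_single`, `acc_double`, `acc_diff`, `valid`, `invalid_reason`)
#'   and `exclusions` (counts and fraction excluded).
#' @export
preprocess_session <- function(session, r2_threshold = 0.8,
                               acc_similarity_floor = 0.3,
                               noisy_emg_rms = 20,
                               artifact_k = 8) {
  ev <- session$events
  emg_t0 <- session$emg$time[1]
  acc_t0 <- session$acc$time[1]
  currents <- sort(unique(ev$current))
  out <- vector("list", length(currents) * length(MUSCLES))
  row_i <- 0L
  for (cur in currents) {
    for (m in MUSCLES) {
      row_i <- row_i + 1L
      emg_ch <- session$emg[[m]]
      acc_ch <- session$acc[[m]]
      crops <- list(double_emg = list(), double_acc = list(),
                    single_acc = list())
      for (pt in c("double", "single")) {
        rows <- ev[ev$current == cur & ev$pulse_type == pt, ]
        for (r in seq_len(nrow(rows))) {
          ts <- rows$timestamp[r]
          seg_from <- round((ts - 0.05 - emg_t0) * EMG_RATE) + 1L
          seg_to <- round((ts + 0.45 - emg_t0) * EMG_RATE)
          seg <- emg_ch[seg_from:seg_to]
          det <- detect_stimulation_artifacts(seg, k = artifact_k)
          if (length(det) == 0) next # faulty sweep, dropped
          art_idx <- seg_from + det[1] - 1L       # index in full channel
          art_time <- emg_t0 + (art_idx - 1) / EMG_RATE
          if (pt == "double") {
            crops$double_emg <- c(crops$double_emg,
                                  list(crop_filter_emg(emg_ch, art_idx)))
            crops$double_acc <- c(crops$double_acc,
                                  list(preprocess_acc(acc_ch, art_time,
                                                      t0 = acc_t0)))
          } else {
            crops$single_acc <- c(crops$single_acc,
                                  list(preprocess_acc(acc_ch, art_time,
                                                      t0 = acc_t0)))
          }
        }
      }
      valid <- TRUE
      reason <- "none"
      emg_avg <- acc_d_avg <- acc_s_avg <- acc_diff <- NULL
      if (length(crops$double_emg) < 2 || length(crops$double_acc) < 2 ||
          length(crops$single_acc) < 2) {
        valid <- FALSE
        reason <- "similarity_fail"
      } else {
        sim_e <- similarity_average(crops$double_emg, r2_threshold)
        sim_d <- similarity_average(crops$double_acc, r2_threshold,
                                    acc_similarity_floor)
        sim_s <- similarity_average(crops$single_acc, r2_threshold,
                                    acc_similarity_floor)
        if (!sim_e$valid || !sim_d$valid || !sim_s$valid) {
          valid <- FALSE
          reason <- "similarity_fail"
        } else {
          emg_avg <- sim_e$average
          acc_d_avg <- sim_d$average
          acc_s_avg <- sim_s$average
          acc_diff <- compute_diff(acc_d_avg, acc_s_avg)
          n_pre <- -CROP_START_MS * EMG_RATE / 1000
          base_rms <- sqrt(mean(emg_avg[seq_len(n_pre)]^2))
          if (base_rms > noisy_emg_rms) {
            valid <- FALSE
            reason <- "noisy_emg"
            emg_avg <- acc_d_avg <- acc_s_avg <- acc_diff <- NULL
          }
        }
      }
      out[[row_i]] <- tibble(
        subject_id = session$meta$subject_id,
        group = session$meta$group,
        age = session$meta$age, sex = session$meta$sex,
        height = session$meta$height, bmi = session$meta$bmi,
        measurement = session$measurement,
        position = session$position,
        current = cur, muscle = m,
        emg_double = list(emg_avg),
        acc_single = list(acc_s_avg),
        acc_double = list(acc_d_avg),
        acc_diff = list(acc_diff),
        valid = valid, invalid_reason = reason)
    }
  }
  events <- bind_rows(out)
  list(events = events, exclusions = exclusion_report(events))
}

exclusion_report <- function(events) {
  n <- nrow(events)
  n_sim <- sum(events$invalid_reason == "similarity_fail")
  n_noisy <- sum(events$invalid_reason == "noisy_emg")
  list(n_events = n, n_excluded = n_sim + n_noisy,
       fraction = (n_sim + n_noisy) / n,
       similarity_fail = n_sim, noisy_emg = n_noisy)
}

#' Preprocess every session of a cohort
#'
#' @param cohort A `tscs_cohort` from [generate_cohort()].
#' @param ... Passed to [preprocess_session()].
#' @return List with the combined `events` tibble and a pooled
#'   `exclusions` report.
#' @export
preprocess_cohort <- function(cohort, ...) {
  res <- lapply(cohort$sessions, preprocess_session, ...)
  events <- bind_rows(lapply(res, `[[`, "events"))
  list(events = events, exclusions = exclusion_report(events))
}
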