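## MMG feature extraction: 36 features per event in three categories
## (meta 1-4, stim 5-6, MMG data 7-36), computed from the averaged
## single-pulse, double-pulse and DIFF acceleration signals.

#' Amplitude-feature window for a muscle
#'
#' Amplitude features are measured in a 50 ms window close to the pulse:
#' 10-60 ms after pulse 1 for the quadriceps (`winA1`), shifted 5 ms right
#' for the triceps surae whose response onset is later. `winDIFF` is the
#' same window after the second pulse, i.e. offset by the 50 ms
#' inter-pulse interval when expressed relative to pulse 1.
#'
#' @param muscle Muscle identifier (`"Q_*"` or `"TS_*"`).
#' @param which `"A1"` (after pulse 1) or `"DIFF"` (after pulse 2).
#' @return Numeric length-2 interval in ms relative to pulse 1.
#' @export
#' @examples
#' acc_window("Q_left", "A1")    # 10 60
#' acc_window("TS_left", "DIFF") # 65 115
acc_window <- function(muscle, which = c("A1", "DIFF")) {
  which <- match.arg(which)
  base <- if (grepl("^TS", muscle)) c(15, 65) else c(10, 60)
  if (which == "DIFF") base + IPI_MS else base
}

# Indices of a half-open [a, b) ms window on a cropped sweep.
window_idx <- function(n, win_ms, rate, t0 = CROP_START_MS) {
  t_ms <- t0 + (seq_len(n) - 1) * 1000 / rate
  which(t_ms >= win_ms[1] & t_ms < win_ms[2])
}

#' Discrete Fréchet distance between two curves
#'
#' The minimum over all monotone couplings of the maximum pointwise
#' distance -- the "dog-leash" distance between two polylines. Computed by
#' the standard dynamic program over the coupling matrix.
#'
#' @param p,q Numeric matrices (points x coordinates) with the same number
#'   of columns.
#' @return Non-negative scalar; 0 iff the ordered point sequences
#'   coincide.
#' @export
#' @examples
#' p <- cbind(1:5, sin(1:5)); frechet_distance(p, p) # 0
frechet_distance <- function(p, q) {
  p <- as.matrix(p); q <- as.matrix(q)
  stopifnot(ncol(p) == ncol(q), nrow(p) >= 1, nrow(q) >= 1)
  n <- nrow(p); m <- nrow(q)
  d <- matrix(0, n, m)
  for (j in seq_len(m)) {
    d[, j] <- sqrt(rowSums((p - matrix(q[j, ], n, ncol(p),
                                       byrow = TRUE))^2))
  }
  ca <- matrix(0, n, m)
  ca[1, 1] <- d[1, 1]
  for (i in 2:max(n, 2)) if (n >= 2) ca[i, 1] <- max(ca[i - 1, 1], d[i, 1])
  for (j in 2:max(m, 2)) if (m >= 2) ca[1, j] <- max(ca[1, j - 1], d[1, j])
  if (n >= 2 && m >= 2) {
    for (i in 2:n) {
      for (j in 2:m) {
        ca[i, j] <- max(min(ca[i - 1, j], ca[i - 1, j - 1], ca[i, j - 1]),
                        d[i, j])
      }
    }
  }
  ca[n, m]
}

# One-sided periodogram PSD with a Hann window; returns freq (Hz) and
# density. The signal is not demeaned: the cropped signals are already
# baseline-corrected and a residual offset is informative.
psd_periodogram <- function(x, rate) {
  n <- length(x)
  w <- 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
  xf <- fft(x * w)
  nf <- floor(n / 2) + 1
  p <- (Mod(xf[seq_len(nf)])^2) / (rate * sum(w^2))
  scale <- rep(2, nf)
  scale[1] <- 1
  if (n %% 2 == 0) scale[nf] <- 1
  list(freq = (seq_len(nf) - 1) * rate / n, density = p * scale)
}

#' Mean power frequency of a signal
#'
#' Power-weighted mean frequency of the Hann-windowed periodogram of the
#' full signal.
#'
#' @param x Numeric signal.
#' @param rate Sampling rate, Hz.
#' @return Mean power frequency in Hz (0 for an all-zero signal).
#' @export
mean_power_frequency <- function(x, rate) {
  psd <- psd_periodogram(x, rate)
  tot <- sum(psd$density)
  if (tot == 0) return(0)
  sum(psd$freq * psd$density) / tot
}

#' Zero-crossing rate
#'
#' Sign changes per second over the whole signal; samples equal to zero
#' inherit the preceding sign, so a constant signal (zero or not) has rate
#' 0.
#'
#' @param x Numeric signal.
#' @param rate Sampling rate, Hz.
#' @return Crossings per second.
#' @export
zero_crossing_rate <- function(x, rate) {
  s <- sign(x)
  for (i in seq_along(s)) if (s[i] == 0) s[i] <- if (i > 1) s[i - 1] else 0
  sum(diff(s) != 0 & s[-length(s)] != 0) / (length(x) / rate)
}

max_slope <- function(x, rate) {
  if (length(x) < 2) return(0)
  max(diff(x)) * rate
}

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
p2p <- function(x) diff(range(x))

#' Extract the 36-feature vector of one event
#'
#' Computes the meta (1-4), stim (5-6) and MMG-data (7-36) features of a
#' valid averaged event. Amplitude statistics are taken from the
#' single-pulse signal in `winA1` and from DIFF in `winDIFF`; the discrete
#' Fréchet distance compares double- and single-pulse signals in
#' `winDIFF`; correlation features use the window from 50 ms to the end of
#' the crop; spectral and zero-crossing features use the full cropped
#' signals; features 35-36 are peak-to-peak amplitudes of the other
#' recorded muscle of the same leg (a simple crosstalk probe).
#'
#' @param event One-row event tibble (valid) from [label_events()].
#' @param partner_event One-row event tibble of the other muscle of the
#'   same leg, or `NULL` (features 35-36 are then 0).
#' @return Named numeric vector of length 36 (`f01_bmi` ...
#'   `f36_p2p_mmg_diff_2nd`).
#' @export
extract_event_features <- function(event, partner_event = NULL) {
  stopifnot(nrow(event) == 1, isTRUE(event$valid))
  single <- event$acc_single[[1]]
  double <- event$acc_double[[1]]
  dif <- event$acc_diff[[1]]
  n <- length(single)
  iA1 <- window_idx(n, acc_window(event$muscle, "A1"), ACC_RATE)
  iDF <- window_idx(n, acc_window(event$muscle, "DIFF"), ACC_RATE)
  iCor <- window_idx(n, c(50, CROP_END_MS), ACC_RATE)
  s_w <- single[iA1]
  d_w <- dif[iDF]
  t_w <- CROP_START_MS + (iDF - 1) * 1000 / ACC_RATE

  r <- suppressWarnings(cor(single[iCor], double[iCor]))
  if (is.na(r)) r <- 0

  partner_p2p_single <- partner_p2p_diff <- 0
  if (!is.null(partner_event) && nrow(partner_event) == 1 &&
      isTRUE(partner_event$valid)) {
    ps <- partner_event$acc_single[[1]]
    pd <- partner_event$acc_diff[[1]]
    jA1 <- window_idx(length(ps), acc_window(partner_event$muscle, "A1"),
                      ACC_RATE)
    jDF <- window_idx(length(pd), acc_window(partner_event$muscle, "DIFF"),
                      ACC_RATE)
    partner_p2p_single <- p2p(ps[jA1])
    partner_p2p_diff <- p2p(pd[jDF])
  }

  c(f01_bmi = event$bmi,
    f02_sex = event$sex,
    f03_age = event$age,
    f04_height = event$height,
    f05_position = event$position,
    f06_current = event$current,
    f07_sensor = as.numeric(grepl("^TS", event$muscle)),
    f08_mmg_single_mean = mean(s_w),
    f09_mmg_single_median = median(s_w),
    f10_mmg_single_std = pop_sd(s_w),
    f11_mmg_single_rms = sqrt(mean(s_w^2)),
    f12_mmg_diff_mean = mean(d_w),
    f13_mmg_diff_median = median(d_w),
    f14_mmg_diff_std = pop_sd(d_w),
    f15_mmg_diff_rms = sqrt(mean(d_w^2)),
    f16_frechet_mmg = frechet_distance(cbind(t_w, double[iDF]),
                                       cbind(t_w, single[iDF])),
    f17_p2p_mmg_single = p2p(s_w),
    f18_p2p_mmg_diff = p2p(d_w),
    f19_r2_mmg_single_double = r^2,
    f20_r_mmg_single_double = r,
    f21_mpf_double = mean_power_frequency(double, ACC_RATE),
    f22_mpf_single = mean_power_frequency(single, ACC_RATE),
    f23_mpf_diff = mean_power_frequency(dif, ACC_RATE),
    f24_auc_psd_single = psd_auc(single, ACC_RATE),
    f25_auc_psd_double = psd_auc(double, ACC_RATE),
    f26_auc_psd_diff = psd_auc(dif, ACC_RATE),
    f27_max_psd_single = max(psd_periodogram(single, ACC_RATE)$density),
    f28_max_psd_double = max(psd_periodogram(double, ACC_RATE)$density),
    f29_max_psd_diff = max(psd_periodogram(dif, ACC_RATE)$density),
    f30_zcr_single = zero_crossing_rate(single, ACC_RATE),
    f31_zcr_double = zero_crossing_rate(double, ACC_RATE),
    f32_zcr_diff = zero_crossing_rate(dif, ACC_RATE),
    f33_max_slope_diff = max_slope(dif[iDF], ACC_RATE),
    f34_max_slope_single = max_slope(s_w, ACC_RATE),
    f35_p2p_mmg_single_2nd = partner_p2p_single,
    f36_p2p_mmg_diff_2nd = partner_p2p_diff)
}

psd_auc <- function(x, rate) {
  psd <- psd_periodogram(x, rate)
  sum(psd$density) * (psd$freq[2] - psd$freq[1])
}

partner_muscle <- function(muscle) {
  c(Q_left = "TS_left", TS_left = "Q_left",
    Q_right = "TS_right", TS_right = "Q_right")[[muscle]]
}

#' Assemble the event feature table
#'
#' Extracts the 36-feature vector for every valid labeled event and
#' returns one row per event together with its grouping keys and labels.
#'
#' @param events Labeled event tibble from [label_events()].
#' @return Tibble: keys (`subject_id`, `group`, `measurement`, `position`,
#'   `current`, `muscle`), labels (`label_2`, `label_3`), and feature
#'   columns `f01_bmi` ... `f36_p2p_mmg_diff_2nd`.
#' @export
assemble_feature_table <- function(events) {
  valid <- events[events$valid, ]
  if (nrow(valid) == 0) stop("no valid events", call. = FALSE)
  rows <- lapply(seq_len(nrow(valid)), function(i) {
    ev <- valid[i, ]
    partner <- valid[valid$subject_id == ev$subject_id &
                       valid$measurement == ev$measurement &
                       valid$position == ev$position &
                       valid$current == ev$current &
                       valid$muscle == partner_muscle(ev$muscle), ]
    if (nrow(partner) == 0) partner <- NULL
    feats <- extract_event_features(ev, partner)
    bind_cols(
      ev %>% select("subject_id", "group", "measurement", "position",
                    "current", "muscle", "label_2", "label_3"),
      as_tibble(as.list(feats)))
  })
  bind_rows(rows)
}

#' Feature registry
#'
#' Machine-readable mapping of feature column names to their category and
#' description.
#'
#' @return Tibble with `name`, `number`, `category`, `description`.
#' @export
feature_registry <- function() {
  tibble(
    number = 1:36,
    name = feature_names(),
    category = c(rep("meta", 4), rep("stim", 2), rep("mmg_data", 30)),
    description = c(
      "body mass index", "sex (0 male, 1 female)", "age (years)",
      "body height (cm)",
      "electrode position, cm from L3/L4", "stimulation current (mA)",
      "sensor muscle group (0 Q, 1 TS)",
      "mean of single-pulse signal in winA1",
      "median of single-pulse signal in winA1",
      "std of single-pulse signal in winA1",
      "RMS of single-pulse signal in winA1",
      "mean of DIFF in winDIFF", "median of DIFF in winDIFF",
      "std of DIFF in winDIFF", "RMS of DIFF in winDIFF",
      "discrete Frechet distance double vs single in winDIFF",
      "peak-to-peak of single-pulse signal in winA1",
      "peak-to-peak of DIFF in winDIFF",
      "squared correlation single vs double, 50 ms to end",
      "correlation single vs double, 50 ms to end",
      "mean power frequency of double-pulse signal",
      "mean power frequency of single-pulse signal",
      "mean power frequency of DIFF",
      "area under PSD of single-pulse signal",
      "area under PSD of double-pulse signal",
      "area under PSD of DIFF",
      "max of PSD of single-pulse signal",
      "max of PSD of double-pulse signal",
      "max of PSD of DIFF",
      "zero-crossing rate of single-pulse signal",
      "zero-crossing rate of double-pulse signal",
      "zero-crossing rate of DIFF",
      "max slope of DIFF in winDIFF",
      "max slope of single-pulse signal in winA1",
      "peak-to-peak of single-pulse signal in winA1, other leg muscle",
      "peak-to-peak of DIFF in winDIFF, other leg muscle"))
}

feature_names <- function() {
  c("f01_bmi", "f02_sex", "f03_age", "f04_height", "f05_position",
    "f06_current", "f07_sensor", "f08_mmg_single_mean",
    "f09_mmg_single_median", "f10_mmg_single_std", "f11_mmg_single_rms",
    "f12_mmg_diff_mean", "f13_mmg_diff_median", "f14_mmg_diff_std",
    "f15_mmg_diff_rms", "f16_frechet_mmg", "f17_p2p_mmg_single",
    "f18_p2p_mmg_diff", "f19_r2_mmg_single_double",
    "f20_r_mmg_single_double", "f21_mpf_double", "f22_mpf_single",
    "f23_mpf_diff", "f24_auc_psd_single", "f25_auc_psd_double",
    "f26_auc_psd_diff", "f27_max_psd_single", "f28_max_psd_double",
    "f29_max_psd_diff", "f30_zcr_single", "f31_zcr_double", "f32_zcr_diff",
    "f33_max_slope_diff", "f34_max_slope_single", "f35_p2p_mmg_single_2nd",
    "f36_p2p_mmg_diff_2nd")
}

#' Select a named feature set
#'
#' `SET-OBSERVE` combines the 30 MMG-data features with the 4 meta
#' features (34 columns) -- the observation approach. `SET-PREDICT` uses
#' only the 4 meta and 2 stim features (6 columns) -- a sensor-less
#' prediction approach with no column computed from the acceleration
#' samples.
#'
#' @param table Feature table from [assemble_feature_table()].
#' @param set_name `"SET-OBSERVE"` or `"SET-PREDICT"`.
#' @return List with `x` (tibble of feature columns) and the label /
#'   key columns `label_2`, `label_3`, `subject_id`, `group`.
#' @export
select_feature_set <- function(table, set_name = c("SET-OBSERVE",
                                                   "SET-PREDICT")) {
  set_name <- match.arg(set_name)
  reg <- feature_registry()
  cols <- switch(set_name,
                 "SET-OBSERVE" = reg$name[reg$category %in%
                                            c("mmg_data", "meta")],
                 "SET-PREDICT" = reg$name[reg$category %in%
                                            c("meta", "stim")])
  list(x = table[, cols],
       label_2 = table$label_2, label_3 = table$label_3,
       subject_id = table$subject_id, group = table$group)
}
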