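## EMG ground-truth labeling from double-pulse amplitude characteristics.
##
## A1 and A2 are the peak-to-peak responses to the first and second pulse
## of a 50 ms double stimulus; the paired-pulse suppression is
## S = (1 - A2/A1) * 100. High suppression marks a reflex
## (afferent-mediated) response, low suppression a direct muscular
## response; A1 below 50 microvolt means no response.

#' Amplitude and suppression metrics of an averaged double-pulse EMG
#'
#' @param emg_double_avg Averaged, filtered double-pulse EMG sweep cropped
#'   to \[-10, 400) ms (time origin at pulse 1).
#' @param win1,win2 Measurement windows in ms relative to pulse 1 for the
#'   first and second response; `win2` is `win1` offset by the 50 ms
#'   inter-pulse interval. The defaults end before the second pulse.
#' @param rate Sampling rate, Hz.
#' @param t0 Time of the first sample, ms.
#' @return A one-row tibble with `A1`, `A2` (microvolt peak-to-peak), `S`
#'   (percent suppression, reported as 0 with `s_defined = FALSE` when
#'   `A1 = 0`).
#' @export
#' @examples
#' x <- numeric(410); x[26] <- 60; x[28] <- -40; x[76] <- 20; x[78] <- -20
#' response_metrics(x) # A1 = 100, A2 = 40, S = 60
response_metrics <- function(emg_double_avg, win1 = c(5, 45),
                             win2 = win1 + IPI_MS,
                             rate = EMG_RATE, t0 = CROP_START_MS) {
  t_ms <- t0 + (seq_along(emg_double_avg) - 1) * 1000 / rate
  i1 <- which(t_ms >= win1[1] & t_ms <= win1[2])
  i2 <- which(t_ms >= win2[1] & t_ms <= win2[2])
  if (length(i1) == 0 || length(i2) == 0)
    stop("empty measurement window", call. = FALSE)
  a1 <- diff(range(emg_double_avg[i1]))
  a2 <- diff(range(emg_double_avg[i2]))
  s_defined <- a1 > 0
  s <- if (s_defined) (1 - a2 / a1) * 100 else 0
  tibble(A1 = a1, A2 = a2, S = s, s_defined = s_defined)
}

#' Classify an event from its EMG amplitude characteristics
#'
#' Three-class scheme: class 0 (no response) when A1 < 50 microvolt;
#' class 1 (reflex response) when A1 > 50 and S > 60 percent; class 2
#' (direct muscular response) when A1 > 50 and S < 60. The two-class
#' scheme merges classes 1 and 2 into a single "response" class 1.
#' Boundary cases (A1 exactly at the threshold, S exactly 60) go to the
#' lower class (0 and 2 respectively).
#'
#' @param A1 Peak-to-peak first response, microvolt.
#' @param S Percent suppression.
#' @param scheme 2 or 3 (number of classes).
#' @param a1_threshold,s_threshold Decision thresholds.
#' @return Integer class label (vectorised over `A1`/`S`).
#' @export
#' @examples
#' classify_event(100, 80) # 1: reflex
#' classify_event(100, 30) # 2: direct muscular
#' classify_event(40, 90)  # 0: no response
classify_event <- function(A1, S, scheme = 3, a1_threshold = 50,
                           s_threshold = 60) {
  stopifnot(scheme %in% c(2, 3))
  responding <- A1 > a1_threshold
  if (scheme == 2) return(ifelse(responding, 1L, 0L))
  ifelse(!responding, 0L, ifelse(S > s_threshold, 1L, 2L))
}

#' Label every preprocessed event of an event table
#'
#' Computes A1/A2/S from the averaged double-pulse EMG of each valid event
#' and assigns both the 2-class and the 3-class label. Invalid events are
#' carried through with `NA` metrics and labels.
#'
#' @param events Event tibble from [preprocess_session()] /
#'   [preprocess_cohort()].
#' @param win1 First-response measurement window, ms (see
#'   [response_metrics()]).
#' @param a1_threshold,s_threshold Classification thresholds.
#' @return The event tibble with columns `A1`, `A2`, `S`, `label_2`,
#'   `label_3` appended.
#' @export
label_events <- function(events, win1 = c(5, 45), a1_threshold = 50,
                         s_threshold = 60) {
  metrics <- purrr::map2(events$emg_double, events$valid, function(x, ok) {
    if (!ok || is.null(x)) return(tibble(A1 = NA_real_, A2 = NA_real_,
                                         S = NA_real_, s_defined = NA))
    response_metrics(x, win1 = win1)
  }) %>% bind_rows()
  events %>%
    mutate(A1 = metrics$A1, A2 = metrics$A2, S = metrics$S,
           label_2 = ifelse(.data$valid,
                            classify_event(metrics$A1, metrics$S, 2,
                                           a1_threshold, s_threshold),
                            NA_integer_),
           label_3 = ifelse(.data$valid,
                            classify_event(metrics$A1, metrics$S, 3,
                                           a1_threshold, s_threshold),
                            NA_integer_))
}
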