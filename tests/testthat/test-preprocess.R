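test_that("stimulation artifacts are found at the injected pulse times", {
  m <- muscle_model()
  sw_d <- simulate_event_pair(m, 25, "double", seed = 1)
  det <- detect_stimulation_artifacts(sw_d$emg)
  pulse_idx <- which(sw_d$t_emg == 0)
  expect_length(det, 2)
  expect_lte(abs(det[1] - pulse_idx), 1)
  expect_equal(det[2] - det[1], 50) # 50 ms apart at 1 kHz
  sw_s <- simulate_event_pair(m, 25, "single", seed = 2)
  expect_length(detect_stimulation_artifacts(sw_s$emg), 1)
  expect_length(detect_stimulation_artifacts(numeric(500)), 0)
  # pure noise: nothing to detect
  set.seed(3)
  expect_length(detect_stimulation_artifacts(rnorm(500, 0, 4)), 0)
})

test_that("running-median high-pass matches the naive sliding median", {
  set.seed(10)
  for (kernel in c(5, 31)) {
    x <- cumsum(rnorm(300)) + sin(seq(0, 8, length.out = 300))
    expect_identical(running_median_highpass(x, kernel),
                     oracle_running_median(x, kernel))
  }
})

test_that("crop-and-filter removes offset and hum but keeps spikes", {
  n <- 1500
  art <- 600
  # constant offset vanishes
  out <- crop_filter_emg(rep(3.7, n), art)
  expect_length(out, 410)
  expect_lt(max(abs(out)), 1e-9)
  # a 50 Hz tone is attenuated by at least 20 dB
  tt <- (seq_len(n) - 1) / 1000
  tone <- sin(2 * pi * 50 * tt)
  out <- crop_filter_emg(tone, art)
  rms_in <- sqrt(mean(tone[(art - 10):(art + 399)]^2))
  expect_lt(20 * log10(sqrt(mean(out^2)) / rms_in), -20)
  # slow drift is removed while a short spike survives
  drift <- 50 * tt
  spike <- numeric(n)
  spike[art + 100 + 0:4] <- 80
  out <- crop_filter_emg(drift + spike, art)
  expect_gt(max(out), 0.8 * 80)
  expect_lt(sqrt(mean(out[1:10]^2)), 2) # baseline flat after drift removal
  expect_error(crop_filter_emg(rnorm(100), 50), "bounds")
})

test_that("time-shifting a sweep and its artifact leaves the crop alone", {
  set.seed(4)
  x <- rnorm(2000)
  shift <- 123
  a <- crop_filter_emg(x, 700)
  b <- crop_filter_emg(c(rnorm(shift), x), 700 + shift)
  expect_equal(a, b, tolerance = 1e-10)
})

test_that("similarity averaging keeps the mutually similar group", {
  set.seed(5)
  base <- sin(seq(0, 10, length.out = 200)) * 50
  r <- similarity_average(list(base, base, base))
  expect_true(r$valid)
  expect_equal(r$kept, 1:3)
  expect_identical(r$average, base) # idempotence on identical sweeps
  # two identical + one independent: the pair is kept
  noise <- rnorm(200, 0, 50)
  r <- similarity_average(list(base, base, noise))
  expect_equal(r$kept, 1:2)
  expect_identical(r$average, base)
  expect_equal(r$r2[1, 2], 1)
  expect_equal(r$r2[1, 3], cor(base, noise)^2)
  # three mutually dissimilar: faulty
  r <- similarity_average(list(rnorm(200), rnorm(200), rnorm(200)))
  expect_false(r$valid)
  expect_null(r$average)
  expect_error(similarity_average(list(base, base[-1])), "length")
})

test_that("low-activity sweeps count as similar when the floor is set", {
  set.seed(6)
  tiny <- replicate(3, rnorm(205, 0, 0.02), simplify = FALSE)
  expect_false(similarity_average(tiny, 0.8)$valid)
  expect_true(similarity_average(tiny, 0.8, low_activity_floor = 0.3)$valid)
})

test_that("acceleration preprocessing crops and removes gravity", {
  x <- rep(9.81, 500)
  out <- preprocess_acc(x, artifact_time = 0.4, rate = 500)
  expect_length(out, 205)
  expect_lt(max(abs(out)), 1e-12)
  # zero pre-stimulus baseline: unchanged by the gravity filter
  y <- numeric(500); y[210:260] <- 1.5
  out <- preprocess_acc(y, artifact_time = 0.4, rate = 500)
  expect_equal(out, y[196:400])
  expect_error(preprocess_acc(y, NA), "artifact")
})

test_that("DIFF is the sample-wise double/single difference", {
  a <- rnorm(205); b <- rnorm(205); c0 <- rnorm(205)
  expect_equal(compute_diff(a, a), numeric(205))
  expect_equal(compute_diff(a, numeric(205)), a)
  # linearity: a common additive signal cancels
  expect_equal(compute_diff(a + c0, b + c0), compute_diff(a, b))
  expect_error(compute_diff(a, b[-1]), "length")
})

test_that("with linear summation DIFF recovers the second-twitch template", {
  m <- quiet_model(summation_gain = 1, S_true = 80)
  cur <- 25
  sw_d <- simulate_event_pair(m, cur, "double")
  sw_s <- simulate_event_pair(m, cur, "single")
  # crop both on the (noise-free) EMG artifact clock
  det <- detect_stimulation_artifacts(sw_d$emg)
  t_art <- sw_d$t_emg[det[1]] / 1000 # seconds, pulse-anchored clock
  acc_d <- preprocess_acc(sw_d$acc, t_art, t0 = sw_d$t_acc[1] / 1000)
  acc_s <- preprocess_acc(sw_s$acc, t_art, t0 = sw_s$t_acc[1] / 1000)
  dif <- compute_diff(acc_d, acc_s)
  # closed-form second twitch: amplitude from the recruitment model,
  # double-exponential envelope at 50 ms + latency + mechanical delay
  r_r <- recruitment(cur, m$reflex_threshold, m$slope)
  r_d <- recruitment(cur, m$direct_threshold, m$slope)
  amp2 <- m$twitch_amplitude *
    (r_r * (1 - m$S_true / 100) + r_d * (1 - m$S_direct / 100))
  i0 <- round((t_art - sw_d$t_acc[1] / 1000) * 500) + 1
  t_ms <- (seq_along(dif) - 6 + (i0 - 1)) * 2 + sw_d$t_acc[1] # ms, pulse at 0
  onset <- 50 + m$latency + m$acc_delay
  template <- amp2 * ifelse(t_ms >= onset,
                            exp(-(t_ms - onset) / m$twitch_decay) -
                              exp(-(t_ms - onset) / m$twitch_rise), 0)
  t_pk <- m$twitch_rise * m$twitch_decay /
    (m$twitch_decay - m$twitch_rise) * log(m$twitch_decay / m$twitch_rise)
  template <- template / (exp(-t_pk / m$twitch_decay) -
                            exp(-t_pk / m$twitch_rise))
  expect_lt(sqrt(mean((dif - template)^2)), 1e-9)
})

test_that("a clean session preprocesses with no exclusions", {
  spec <- cohort_spec(n_healthy = 1, n_patients = 0, positions_healthy = 0,
                      seed = 31)
  co <- generate_cohort(spec, seed = 32,
                        protocol = stimulation_protocol(max_current = 25),
                        max_current_range = c(25, 25),
                        emg_noise_sd = 0, acc_noise_sd = 0)
  pp <- preprocess_session(co$sessions[[1]])
  expect_equal(pp$exclusions$fraction, 0)
  expect_equal(nrow(pp$events), 4 * 5) # muscles x currents
  expect_true(all(pp$events$valid))
  # DIFF identity holds on every valid event
  ok <- purrr::pmap_lgl(pp$events[c("acc_double", "acc_single", "acc_diff")],
                        function(acc_double, acc_single, acc_diff)
                          isTRUE(all.equal(acc_diff,
                                           acc_double - acc_single)))
  expect_true(all(ok))
})

test_that("a corrupted repetition triplet is excluded and counted", {
  spec <- cohort_spec(n_healthy = 1, n_patients = 0, positions_healthy = 0,
                      seed = 31)
  co <- generate_cohort(spec, seed = 32,
                        protocol = stimulation_protocol(max_current = 25),
                        max_current_range = c(25, 25))
  s <- co$sessions[[1]]
  # wipe the three double-pulse EMG sweeps of one event: no artifacts
  # detectable, similarity cannot succeed
  rows <- s$events[s$events$current == 15 & s$events$pulse_type == "double", ]
  set.seed(33)
  for (ts in rows$timestamp) {
    idx <- (round((ts - 0.05) * 1000) + 1):(round((ts + 0.45) * 1000))
    s$emg$Q_left[idx] <- rnorm(length(idx), 0, 4)
  }
  pp <- preprocess_session(s)
  bad <- pp$events[!pp$events$valid, ]
  expect_equal(nrow(bad), 1)
  expect_equal(bad$muscle, "Q_left")
  expect_equal(bad$current, 15)
  expect_equal(bad$invalid_reason, "similarity_fail")
  expect_equal(pp$exclusions$fraction, 1 / nrow(pp$events))
})
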