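test_that("sub-threshold currents evoke no EMG response", {
  m <- quiet_model()
  sw <- simulate_event_pair(m, current = 5, pulse_type = "single")
  resp <- sw$emg[sw$t_emg >= 5 & sw$t_emg <= 45]
  expect_lt(diff(range(resp)), 50)
})

test_that("full suppression removes the second response entirely", {
  # direct pathway far out of reach so only the (fully suppressed)
  # reflex pathway contributes
  m <- quiet_model(S_true = 100, summation_gain = 1,
                   direct_threshold = 500)
  sw_d <- simulate_event_pair(m, current = 25, pulse_type = "double")
  sw_s <- simulate_event_pair(m, current = 25, pulse_type = "single")
  # second EMG response window is flat
  resp2 <- sw_d$emg[sw_d$t_emg >= 55 & sw_d$t_emg <= 95]
  expect_lt(diff(range(resp2)), 1e-9)
  # and the twitches cancel: double - single vanishes everywhere
  expect_lt(max(abs(sw_d$acc - sw_s$acc)), 1e-9)
})

test_that("the same seed reproduces a sweep exactly", {
  m <- muscle_model()
  a <- simulate_event_pair(m, 20, "double", seed = 7)
  b <- simulate_event_pair(m, 20, "double", seed = 7)
  expect_identical(a, b)
  expect_error(simulate_event_pair(m, 20, "triple"), "pulse_type")
})

test_that("expected first-response amplitude is monotone in current", {
  m <- quiet_model()
  a1 <- vapply(seq(5, 50, 5), function(cur) {
    sw <- simulate_event_pair(m, cur, "single")
    diff(range(sw$emg[sw$t_emg >= 5 & sw$t_emg <= 45]))
  }, numeric(1))
  expect_true(all(diff(a1) >= -1e-12))
})

test_that("a session realizes the protocol event arithmetic", {
  proto <- stimulation_protocol(start_current = 5, max_current = 20,
                                increment = 5, reps_per_pulse_type = 3)
  models <- replicate(4, quiet_model(), simplify = FALSE)
  names(models) <- c("Q_left", "Q_right", "TS_left", "TS_right")
  for (i in seq_along(models)) models[[i]]$muscle <- names(models)[i]
  meta <- list(subject_id = "T1", group = "healthy", age = 30, sex = 0,
               height = 180, bmi = 22)
  s <- generate_session(meta, proto, models, seed = 3)
  expect_equal(nrow(s$events), 4 * 6) # 4 currents x (3 double + 3 single)
  expect_equal(unique(diff(s$events$timestamp)), proto$inter_stimulus_gap)
  # EMG and ACC lengths consistent with the rates and common origin
  expect_equal(nrow(s$emg), 2 * nrow(s$acc))
  expect_equal(s$emg$time[1], s$acc$time[1])
})

test_that("models out of reach produce an all-zero ground truth", {
  proto <- stimulation_protocol(max_current = 15)
  models <- lapply(c("Q_left", "Q_right", "TS_left", "TS_right"),
                   function(m) quiet_model(muscle = m,
                                           reflex_threshold = 52.5,
                                           direct_threshold = 72.5))
  names(models) <- c("Q_left", "Q_right", "TS_left", "TS_right")
  meta <- list(subject_id = "T1", group = "healthy", age = 30, sex = 0,
               height = 180, bmi = 22)
  s <- generate_session(meta, proto, models, seed = 3)
  expect_true(all(s$ground_truth$class_true == 0))
})

test_that("a fixed seed reproduces a session byte for byte", {
  spec <- cohort_spec(n_healthy = 1, n_patients = 0,
                      positions_healthy = 0, seed = 9)
  proto <- stimulation_protocol(max_current = 10)
  a <- generate_cohort(spec, seed = 5, protocol = proto)
  b <- generate_cohort(spec, seed = 5, protocol = proto)
  expect_identical(a$sessions[[1]], b$sessions[[1]])
  d1 <- tempfile(); d2 <- tempfile()
  write_session(a$sessions[[1]], d1)
  write_session(b$sessions[[1]], d2)
  for (f in c("emg.csv", "acc.csv", "events.csv", "meta.json"))
    expect_identical(readBin(file.path(d1, f), "raw", 1e7),
                     readBin(file.path(d2, f), "raw", 1e7))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("cohort session counts follow the subject table", {
  spec <- cohort_spec(n_healthy = 11, n_patients = 11,
                      positions_healthy = c(-4, 0, 4),
                      n_days_patient = 2L, seed = 1)
  proto <- stimulation_protocol(max_current = 10)
  co <- generate_cohort(spec, seed = 2, protocol = proto,
                        max_current_range = c(10, 10))
  # 11 healthy x 3 positions + 11 patients x 2 days x 1 position
  expect_length(co$sessions, 33 + 22)
  one <- cohort_spec(n_healthy = 1, n_patients = 0, positions_healthy = 0,
                     seed = 1)
  co1 <- generate_cohort(one, seed = 2, protocol = proto,
                         max_current_range = c(10, 10))
  expect_equal(nrow(co1$truth), 4) # one model per muscle
})

test_that("different seeds change the noise but not the event log", {
  spec <- cohort_spec(n_healthy = 1, n_patients = 0, positions_healthy = 0,
                      seed = 3)
  proto <- stimulation_protocol(max_current = 10)
  a <- generate_cohort(spec, seed = 11, protocol = proto,
                       max_current_range = c(10, 10))
  b <- generate_cohort(spec, seed = 12, protocol = proto,
                       max_current_range = c(10, 10))
  expect_identical(a$sessions[[1]]$events, b$sessions[[1]]$events)
  expect_false(identical(a$sessions[[1]]$emg, b$sessions[[1]]$emg))
})

test_that("session containers round-trip through plain-text files", {
  spec <- cohort_spec(n_healthy = 1, n_patients = 0, positions_healthy = 0,
                      seed = 3)
  co <- generate_cohort(spec, seed = 4,
                        protocol = stimulation_protocol(max_current = 10),
                        max_current_range = c(10, 10))
  d <- tempfile()
  write_session(co$sessions[[1]], d)
  back <- read_session(d)
  expect_equal(back$meta$subject_id, co$sessions[[1]]$meta$subject_id)
  expect_equal(back$events$current, co$sessions[[1]]$events$current)
  expect_equal(back$emg$Q_left, co$sessions[[1]]$emg$Q_left,
               tolerance = 1e-12)
  expect_equal(back$ground_truth$class_true,
               co$sessions[[1]]$ground_truth$class_true)
  unlink(d, recursive = TRUE)
})
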