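test_that("synthetic groups are reproducible and exactly gridded", {
  sp <- synth_spec(n_islets = 3, periods = c(4, 5, 6), noise_sd = 0.1,
                   seed = 9, duration = 60)
  g1 <- synth_group(sp)
  g2 <- synth_group(sp)
  expect_identical(g1$values, g2$values)
  expect_equal(unique(round(diff(g1$times), 9)), 20)
  expect_equal(n_traces(g1), 3)

  g3 <- synth_group(synth_spec(n_islets = 3, periods = c(4, 5, 6),
                               noise_sd = 0.1, seed = 10, duration = 60))
  expect_false(identical(g1$values, g3$values))
})

test_that("noise-free sine periods are recovered exactly by the pipeline", {
  for (per in c(2, 3, 5, 10)) {
    sp <- synth_spec(n_islets = 1, periods = per, noise_sd = 0,
                     duration = max(40, 4 * per), waveform = "sine")
    g <- synth_group(sp)
    expect_equal(as.numeric(major_period(group_trace(g, 1))), per,
                 tolerance = 0.05 / per + 0.011)
  }
})

test_that("relaxation waveform oscillates at the requested period", {
  sp <- synth_spec(n_islets = 1, periods = 5, noise_sd = 0, duration = 60,
                   waveform = "relaxation")
  g <- synth_group(sp)
  expect_equal(as.numeric(major_period(group_trace(g, 1))), 5,
               tolerance = 0.03)
  nads <- detect_nadirs(group_trace(g, 1))
  expect_equal(mean(diff(nads)) / 60, 5, tolerance = 0.02)
})

test_that("antiphase equal-period islets have near-zero synchrony", {
  sp <- synth_spec(n_islets = 2, periods = 5, phases = c(0, 0.5),
                   noise_sd = 0, duration = 90, waveform = "sine")
  expect_lt(synchronization_index(synth_group(sp)), 0.05)
})

test_that("parameter recovery tolerates 10% noise in >= 95% of cases", {
  set.seed(17)
  periods <- c(2, 3, 4, 5, 7, 10)
  n_cases <- 200
  ok <- 0
  for (i in seq_len(n_cases)) {
    per <- sample(periods, 1)
    amp <- runif(1, 0.8, 1.2)
    sp <- synth_spec(n_islets = 1, periods = per, amplitudes = amp,
                     phases = runif(1), noise_sd = 0.1 * amp,
                     drift_slope = runif(1, -0.005, 0.005),
                     duration = 90, waveform = "sine", seed = i)
    got <- as.numeric(major_period(group_trace(synth_group(sp), 1)))
    if (abs(got - per) <= 0.1 * per) ok <- ok + 1
  }
  expect_gte(ok / n_cases, 0.95)
})

test_that("the piecewise validation waveform has the stated segments", {
  s2 <- s2_fixture()
  segs <- attr(s2, "segments")
  expect_equal(segs$period_min, c(5, 3, 4))
  expect_equal(segs$amplitude, c(30, 50, 20))
  expect_equal(diff(range(s2$times)), 90 * 60)

  # segment-wise dominant periods
  expect_equal(as.numeric(major_period(s2, t_window = c(0, 1800))), 5.0,
               tolerance = 0.06)
  expect_equal(as.numeric(major_period(s2, t_window = c(1800, 3600))), 3.0,
               tolerance = 0.06)
  expect_equal(as.numeric(major_period(s2, t_window = c(3600, 5400))), 4.0,
               tolerance = 0.06)

  # final segment amplitude (half peak-to-trough) is 20
  last <- s2$values[s2$times > 3700]
  expect_equal((max(last) - min(last)) / 2, 20, tolerance = 0.01)

  # background subtraction centres the wave on zero
  expect_lt(abs(mean(background_subtract(s2)$values)), 0.5)
})

test_that("resettable oscillators: reset strength controls synchrony", {
  train <- periodic_train(pulse_profile(rest_time_r = 5), n_pulses = 8,
                          t_start = 1200)
  free <- resettable_oscillator_group(3, c(4, 5, 6), NULL, 0, seed = 5,
                                      duration = 80)
  zero <- resettable_oscillator_group(3, c(4, 5, 6), train, 0, seed = 5,
                                      duration = 80)
  expect_identical(free$values, zero$values)

  full <- resettable_oscillator_group(3, c(4, 5, 6), train, 1, seed = 5,
                                      duration = 80)
  # immediately after a full reset all phases coincide
  onset <- train$onsets[4]
  i <- which.min(abs(full$times - (onset + 40)))
  vals <- full$values[i, ]
  expect_lt(diff(range(vals)), 0.2)

  partial <- resettable_oscillator_group(3, c(4, 5, 6), train, 0.8,
                                         seed = 5, duration = 110)
  s_before <- synchronization_index(partial, t_window = c(0, 1200))
  s_during <- synchronization_index(partial,
                                    t_window = c(1200, max(train$onsets)))
  expect_gt(s_during, s_before)
})

test_that("invalid synthesis specs are rejected", {
  expect_error(synth_spec(periods = 0.5), "\\[1, 20\\]")
  expect_error(synth_spec(duration = 5, periods = 5), "twice")
  expect_error(synth_spec(noise_sd = -1), ">= 0")
})
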