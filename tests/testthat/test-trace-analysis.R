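make_sine <- function(period_min = 5, duration_min = 90, dt = 20,
                      amp = 1, baseline = 0, slope = 0, phase = 0) {
  tt <- seq(0, duration_min * 60, by = dt)
  ca_trace(tt, baseline + slope * tt / 60 +
             amp * sin(2 * pi * (tt / (period_min * 60) + phase)))
}

test_that("background subtraction removes any straight line exactly", {
  tt <- seq(0, 3600, by = 20)
  const <- ca_trace(tt, rep(3.7, length(tt)))
  expect_equal(background_subtract(const)$values, rep(0, length(tt)),
               tolerance = 1e-12)

  s <- make_sine(5, 600)
  tt <- s$times
  lined <- ca_trace(tt, s$values + 0.01 * tt + 42)
  rec <- background_subtract(lined)
  # sine recovered within 1% RMS over a long record
  err <- sqrt(mean((rec$values - s$values)^2))
  expect_lt(err, 0.01 * sqrt(mean(s$values^2)))
  # residual has no remaining trend
  fit <- stats::lm(rec$values ~ tt)
  expect_lt(abs(stats::coef(fit)[2]), 1e-9)
  expect_lt(abs(mean(rec$values)), 1e-9)
})

test_that("linear upsampling inserts points on segments, keeping originals", {
  tr <- ca_trace(c(0, 20), c(0, 3))
  up <- interpolate_upsample(tr, 2)
  expect_equal(up$values, c(0, 1, 2, 3))
  expect_equal(up$times, c(0, 20 / 3, 40 / 3, 20))

  s <- make_sine(5, 30)
  expect_identical(interpolate_upsample(s, 0), s)
  up2 <- interpolate_upsample(s, 2)
  expect_equal(length(up2$values), (length(s$values) - 1) * 3 + 1)
  # original samples preserved exactly
  expect_identical(up2$values[seq(1, length(up2$values), by = 3)], s$values)
  # convexity: no new extremes
  expect_lte(max(abs(up2$values)), max(abs(s$values)))
})

test_that("spectrogram of a pure sine concentrates at its period", {
  s <- interpolate_upsample(background_subtract(make_sine(5, 90)), 2)
  spec <- stft_spectrogram(s)
  expect_equal(dim(spec$magnitudes),
               c(length(seq(1, length(s$values) - 255, by = 5)), 1000))
  expect_true(all(spec$magnitudes >= 0))

  per <- spec$period_axis
  # one frequency-resolution element of the 256-sample window itself
  df <- 1 / (256 * (s$times[2] - s$times[1]))
  f0 <- 1 / 300
  in_band <- abs(1 / (per * 60) - f0) <= df
  for (i in seq(1, nrow(spec$magnitudes), by = 37)) {
    row <- spec$magnitudes[i, ]
    j <- which.max(row)
    expect_lt(abs(per[j] - 5), 0.35)
    # > 80% of magnitude mass within one window-resolution bin of the
    # true period
    expect_gt(sum(row[in_band]^2) / sum(row^2), 0.8)
  }

  z <- ca_trace(s$times, rep(0, length(s$times)))
  expect_true(all(stft_spectrogram(z)$magnitudes == 0))
  expect_error(stft_spectrogram(make_sine(5, 10)), "insufficient data")
})

test_that("major_period recovers analytic periods to 0.1 min", {
  expect_equal(as.numeric(major_period(make_sine(5, 90))), 5.0,
               tolerance = 0.021)
  p41 <- major_period(make_sine(4.1, 20), period_range = c(2, 8))
  expect_lt(abs(as.numeric(p41) - 4.1), 0.2)
  expect_equal(attr(major_period(make_sine(5, 90)), "confidence"), "high")
  expect_error(major_period(make_sine(5, 3)), "insufficient data")
})

test_that("white noise is flagged low-confidence", {
  set.seed(4)
  tt <- seq(0, 5400, by = 20)
  wn <- ca_trace(tt, rnorm(length(tt)))
  expect_equal(attr(major_period(wn), "confidence"), "low")
})

test_that("major_period agrees with a brute-force periodogram argmax", {
  # independent oracle: direct discrete periodogram over a dense period
  # grid, no FFT
  brute_period <- function(trace, period_range = c(2, 15)) {
    y <- stats::residuals(stats::lm(trace$values ~ trace$times))
    pers <- seq(period_range[1], min(period_range[2],
                                     diff(range(trace$times)) / 120), by = 0.02)
    power <- vapply(pers * 60, function(Ts) {
      w <- 2 * pi / Ts
      Mod(sum(y * exp(-1i * w * trace$times)))^2
    }, numeric(1))
    pers[which.max(power)]
  }
  set.seed(11)
  for (i in 1:100) {
    per <- runif(1, 2.2, 10)
    tr <- make_sine(per, duration_min = 60, amp = runif(1, 0.5, 2),
                    phase = runif(1))
    tr <- ca_trace(tr$times, tr$values + rnorm(length(tr$times), sd = 0.1))
    expect_lt(abs(as.numeric(major_period(tr)) - brute_period(tr)), 0.15)
  }
})

test_that("entrainment ratios classify canonical period pairs", {
  expect_equal(classify_entrainment(10, 5), "1:2")
  expect_equal(classify_entrainment(2, 4), "2:1")
  expect_equal(classify_entrainment(5, 5), "1:1")
  expect_equal(classify_entrainment(10, 3.3), "1:3")
  expect_equal(classify_entrainment(7, 2), "unentrained")
  # symmetry under exact p:q scaling for all small ratios
  for (p in 1:3) for (q in 1:3) {
    if (p == q && p > 1) next
    for (T0 in c(2, 5, 10)) {
      got <- classify_entrainment(T0, T0 * p / q)
      pq <- c(p, q) / max(1, ifelse(p == q, p, 1))
      expect_equal(got, sprintf("%d:%d", pq[1], pq[2]),
                   label = sprintf("p=%d q=%d T=%g -> %s", p, q, T0, got))
    }
  }
})

test_that("synchronization index reflects phase dispersion", {
  tt <- seq(0, 5400, by = 20)
  w <- 2 * pi * tt / 300
  g_in <- trace_group(tt, cbind(sin(w), sin(w)))
  expect_equal(synchronization_index(g_in), 1, tolerance = 1e-6)

  g_anti <- trace_group(tt, cbind(sin(w), sin(w + pi)))
  expect_lt(synchronization_index(g_anti), 0.05)

  # many uniformly spread phases average out
  n <- 50
  g_unif <- trace_group(tt, sapply(seq_len(n) - 1,
                                   function(k) sin(w + 2 * pi * k / n)))
  expect_lt(synchronization_index(g_unif), 0.2)

  expect_error(synchronization_index(trace_group(tt, cbind(sin(w)))),
               "fewer than 2")
  flat <- trace_group(tt, cbind(sin(w), rep(1, length(tt))))
  expect_error(synchronization_index(flat), "flat")
})

test_that("nadir detection finds sine minima and rejects ramps", {
  s <- make_sine(5, 60, dt = 1)
  nads <- detect_nadirs(s)
  expect_gt(length(nads), 9)
  expect_equal(mean(diff(nads)), 300, tolerance = 1 / 300)
  # sine minima at 3/4 period + k
  expect_lt(max(abs((nads - 225) %% 300)), 2.5)

  ramp <- ca_trace(seq(0, 3600, 20), seq(0, 1, length.out = 181))
  expect_error(detect_nadirs(ramp), "no oscillation|flat")
  flat <- ca_trace(seq(0, 3600, 20), rep(2, 181))
  expect_error(detect_nadirs(flat), "flat")
})

test_that("analyze_group ties the pipeline together", {
  sp <- synth_spec(n_islets = 4, periods = c(3, 4, 5, 7), noise_sd = 0.05,
                   duration = 90, waveform = "sine", seed = 3)
  g <- synth_group(sp)
  rep0 <- analyze_group(g)
  expect_s3_class(rep0$spectrogram, "ca_spectrogram")
  expect_equal(nrow(rep0$periods), 4)
  expect_true(all(is.na(rep0$periods$period_during)))

  # driven by a strongly resetting common pulse train: index rises during
  # pulsing and decays after the last pulse
  train <- periodic_train(pulse_profile(rest_time_r = 5), n_pulses = 10,
                          t_start = 1200)
  g2 <- resettable_oscillator_group(4, periods = c(4, 5, 6, 4.5),
                                    pulse_train = train,
                                    reset_strength = 0.9, seed = 2,
                                    duration = 110)
  rep2 <- analyze_group(g2, pulse_train = train)
  expect_gt(rep2$sync["during"], rep2$sync["before"])
  expect_gt(rep2$sync["during"], rep2$sync["after"])

  # single-islet group: periods reported, sync undefined
  g1 <- trace_group(g$times, g$values[, 1, drop = FALSE])
  rep1 <- analyze_group(g1)
  expect_true(is.na(rep1$sync["before"]))
  expect_false(is.na(rep1$periods$period_before[1]))
})
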