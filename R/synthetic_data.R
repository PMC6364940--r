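#' Specification for synthetic islet trace groups
#'
#' Describes a group of synthetic islet Ca2+ recordings with the
#' statistical structure the analysis pipeline assumes: per-islet
#' oscillations with natural periods of a few minutes, heterogeneous
#' phases and amplitudes, a slowly drifting baseline, additive Gaussian
#' noise, and sampling every 20 s.
#'
#' @param n_islets Number of islets (default 4, the usual group size).
#' @param periods Oscillation period per islet, minutes (each in
#'   `[1, 20]`).  Recycled to `n_islets`.
#' @param amplitudes Half peak-to-trough amplitude per islet (signal
#'   units).  Recycled.
#' @param phases Initial phase per islet as a fraction of a cycle.
#'   Recycled; defaults to evenly spread phases.
#' @param baseline Constant baseline level.
#' @param drift_slope Linear baseline drift, signal units per minute.
#' @param noise_sd Additive Gaussian noise standard deviation.
#' @param sampling_interval Sampling interval, seconds (default 20).
#' @param duration Record length, minutes (>= 2 x the longest period).
#' @param waveform `"sine"` or `"relaxation"` (plateau/trough square-ish
#'   wave with duty cycle 0.5, mimicking burst-like Ca2+ oscillations).
#' @param seed Integer seed controlling noise (and any other draws).
#' @return An object of class `synth_spec`.
#' @export
synth_spec <- function(n_islets = 4,
                       periods = c(4, 5, 6, 3),
                       amplitudes = 1,
                       phases = NULL,
                       baseline = 0,
                       drift_slope = 0,
                       noise_sd = 0,
                       sampling_interval = 20,
                       duration = 90,
                       waveform = c("sine", "relaxation"),
                       seed = 1) {
  waveform <- match.arg(waveform)
  if (n_islets < 1 || n_islets != round(n_islets))
    stop("`n_islets` must be a positive integer", call. = FALSE)
  periods <- rep_len(as.numeric(periods), n_islets)
  if (any(periods < 1 | periods > 20))
    stop("periods must lie in [1, 20] minutes", call. = FALSE)
  amplitudes <- rep_len(as.numeric(amplitudes), n_islets)
  if (any(amplitudes < 0)) stop("amplitudes must be >= 0", call. = FALSE)
  if (is.null(phases)) phases <- (seq_len(n_islets) - 1) / n_islets
  phases <- rep_len(as.numeric(phases), n_islets)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (duration < 2 * max(periods))
    stop("`duration` must be at least twice the longest period", call. = FALSE)
  if (sampling_interval <= 0)
    stop("`sampling_interval` must be positive", call. = FALSE)
  structure(
    list(n_islets = as.integer(n_islets), periods = periods,
         amplitudes = amplitudes, phases = phases, baseline = baseline,
         drift_slope = drift_slope, noise_sd = noise_sd,
         sampling_interval = sampling_interval, duration = duration,
         waveform = waveform, seed = as.integer(seed)),
    class = "synth_spec"
  )
}

# Relaxation waveform in roughly [-1.2, 1]: a smoothed square wave with
# plateau fraction 0.5 (active phase in the first half of the cycle,
# silent phase in the second) plus a slight downward ramp, so that each
# cycle's minimum falls just before the next active-phase onset, as in
# burst-like Ca2+ records.
relaxation_wave <- function(u, sharpness = 20, ramp = 0.2) {
  tanh(sharpness * sin(2 * pi * u)) - ramp * (u %% 1)
}

wave_value <- function(u, waveform) {
  if (waveform == "sine") sin(2 * pi * u)
  else relaxation_wave(u)
}

#' Generate a synthetic trace group
#'
#' @param spec A [synth_spec()].
#' @return A `trace_group`; bit-reproducible for a fixed seed.
#' @export
synth_group <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  tt <- seq(0, spec$duration * 60, by = spec$sampling_interval)
  vals <- with_preserved_seed(spec$seed, {
    sapply(seq_len(spec$n_islets), function(j) {
      u <- tt / (spec$periods[j] * 60) + spec$phases[j]
      spec$baseline + spec$drift_slope * tt / 60 +
        spec$amplitudes[j] * wave_value(u, spec$waveform) +
        stats::rnorm(length(tt), sd = spec$noise_sd)
    })
  })
  trace_group(tt, vals)
}

#' Piecewise variable-frequency validation waveform
#'
#' A 90-min sinusoid sampled every 20 s whose period and amplitude change
#' every 30 min: period 5 min at amplitude 30 for the first segment,
#' 3 min at 50 for the second, and 4 min at 20 for the final segment,
#' on a constant background offset.  The phase is continuous across
#' segment boundaries.  This is the standard worked example for
#' validating the spectrogram pipeline: after background subtraction the
#' wave is centred on zero, and the spectrogram shows three distinct
#' 30-min period bands.
#'
#' @param background Constant offset added to the wave.
#' @param sampling_interval Sampling interval, seconds.
#' @return A `ca_trace` with attribute `segments` (data frame of segment
#'   start/end minutes, periods, and amplitudes).
#' @export
s2_fixture <- function(background = 60, sampling_interval = 20) {
  segs <- data.frame(start_min = c(0, 30, 60), end_min = c(30, 60, 90),
                     period_min = c(5, 3, 4), amplitude = c(30, 50, 20))
  tt <- seq(0, 90 * 60, by = sampling_interval)
  seg_idx <- pmin(findInterval(tt / 60, segs$start_min), 3L)
  # continuous phase: integrate the instantaneous frequency
  phase0 <- c(0,
              30 / segs$period_min[1],
              30 / segs$period_min[1] + 30 / segs$period_min[2])
  u <- phase0[seg_idx] + (tt / 60 - segs$start_min[seg_idx]) / segs$period_min[seg_idx]
  vals <- background + segs$amplitude[seg_idx] * sin(2 * pi * u)
  out <- ca_trace(tt, vals)
  attr(out, "segments") <- segs
  out
}

#' Phase-oscillator group with pulse-triggered resetting
#'
#' A cheap surrogate for pulse-synchronized islets, used to exercise the
#' synchronization metrics without ODE runs: each islet is a phase
#' oscillator with its own natural period, and at every pulse onset all
#' phases move toward the start of an active phase by the fraction
#' `reset_strength` (1 = complete reset, 0 = no effect).  Traces are
#' emitted as relaxation waveforms.
#'
#' @param n Number of islets.
#' @param periods Natural periods, minutes (recycled to `n`).
#' @param pulse_train A `pulse_train` (or `NULL` for free running).
#' @param reset_strength Fraction in `[0, 1]`.
#' @param seed Integer seed for the initial phases.
#' @param duration Record length, minutes.
#' @param sampling_interval Sampling interval, seconds.
#' @param amplitude Waveform amplitude.
#' @param noise_sd Additive Gaussian noise SD.
#' @return A `trace_group`.
#' @export
resettable_oscillator_group <- function(n = 4, periods = c(4, 5, 6, 4.5),
                                        pulse_train = NULL,
                                        reset_strength = 0.8,
                                        seed = 1, duration = 90,
                                        sampling_interval = 20,
                                        amplitude = 1, noise_sd = 0) {
  if (reset_strength < 0 || reset_strength > 1)
    stop("`reset_strength` must be in [0, 1]", call. = FALSE)
  periods <- rep_len(as.numeric(periods), n) * 60
  tt <- seq(0, duration * 60, by = sampling_interval)
  onsets <- if (is.null(pulse_train)) numeric(0) else pulse_train$onsets
  vals <- with_preserved_seed(seed, {
    init <- stats::runif(n)
    noise <- matrix(stats::rnorm(length(tt) * n, sd = noise_sd),
                    nrow = length(tt))
    ph <- sapply(seq_len(n), function(j) {
      phase <- init[j]
      out <- numeric(length(tt))
      pending <- onsets
      t_prev <- tt[1]
      for (i in seq_along(tt)) {
        # advance to tt[i], applying any pulse resets inside the step
        while (length(pending) && pending[1] <= tt[i]) {
          phase <- phase + (pending[1] - t_prev) / periods[j]
          # move toward phase 0 (active-phase onset) along the shortest arc
          dev <- ((phase + 0.5) %% 1) - 0.5
          phase <- phase - dev * reset_strength
          t_prev <- pending[1]
          pending <- pending[-1]
        }
        phase <- phase + (tt[i] - t_prev) / periods[j]
        t_prev <- tt[i]
        out[i] <- phase
      }
      out
    })
    amplitude * apply(ph, 2, relaxation_wave) + noise
  })
  trace_group(tt, vals)
}
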