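#' Detect cycle nadirs of an oscillating trace
#'
#' Finds one time per oscillation cycle: the local minimum of the signal
#' between successive active phases.  The trace is lightly smoothed, the
#' active/silent alternation is identified with a two-threshold
#' (hysteresis) rule on robust quantiles so that brief excursions do not
#' split a phase, and each silent-segment minimum is refined by parabolic
#' interpolation around the sampled minimum.
#'
#' @param trace A `ca_trace` spanning at least two oscillation cycles.
#' @param smooth_s Width of the centred moving-average smoother in
#'   seconds.  The default (25 s) removes fast electrical spikes from
#'   model output; for 20-s-sampled experimental-style data it leaves the
#'   trace essentially untouched.
#' @param min_rel_amplitude Minimum oscillation amplitude (2--98 percent
#'   quantile range) relative to the absolute signal scale below which
#'   the trace is declared flat.
#' @return Numeric vector of nadir times in seconds.
#' @export
detect_nadirs <- function(trace, smooth_s = 25, min_rel_amplitude = 1e-3) {
  stopifnot(inherits(trace, "ca_trace"))
  tt <- trace$times
  dt <- trace_dt(trace)
  k <- max(1, round(smooth_s / dt))
  if (k %% 2 == 0) k <- k + 1
  xs <- if (k > 1)
    as.numeric(stats::filter(trace$values, rep(1 / k, k), sides = 2))
  else trace$values
  ok <- !is.na(xs)
  xs <- xs[ok]; tt2 <- tt[ok]
  q <- stats::quantile(xs, c(0.02, 0.98), names = FALSE)
  scale <- max(abs(q), diff(q))
  if (diff(q) < min_rel_amplitude * max(scale, .Machine$double.eps))
    stop("flat trace: peak-to-trough amplitude below threshold; ",
         "no oscillation detected", call. = FALSE)
  lo <- q[1] + 0.35 * diff(q)
  hi <- q[1] + 0.65 * diff(q)
  state <- xs[1] > hi
  seg_start <- integer(0); seg_end <- integer(0)
  for (i in seq_along(xs)) {
    if (state && xs[i] < lo) { state <- FALSE; seg_start <- c(seg_start, i) }
    else if (!state && xs[i] > hi) { state <- TRUE; seg_end <- c(seg_end, i) }
  }
  nads <- numeric(0)
  for (s in seg_start) {
    e <- seg_end[seg_end > s][1]
    if (is.na(e)) next  # unfinished silent phase at the end of the record
    i <- s - 1L + which.min(xs[s:e])
    if (i > 1L && i < length(xs)) {
      den <- xs[i - 1] - 2 * xs[i] + xs[i + 1]
      off <- if (abs(den) > 0) 0.5 * (xs[i - 1] - xs[i + 1]) / den else 0
      off <- max(-1, min(1, off))
      nads <- c(nads, tt2[i] + off * dt)
    } else {
      nads <- c(nads, tt2[i])
    }
  }
  if (length(nads) < 2)
    stop("no oscillation detected: fewer than two complete cycles ",
         "(is the trace monotone or too short?)", call. = FALSE)
  nads
}

#' Oscillation phase of a time point
#'
#' Phase 0 marks the beginning of a burst active phase; phase runs to 1
#' at the end of the following silent phase (the next cycle start), and
#' wraps modulo 1.
#'
#' @param t Time(s), seconds.
#' @param cycle_start Reference cycle start (active-phase onset), seconds.
#' @param natural_period Oscillation period, seconds (> 0).
#' @return Phase fraction(s) in `[0, 1)`.
#' @export
phase_of_time <- function(t, cycle_start, natural_period) {
  if (natural_period <= 0)
    stop("`natural_period` must be positive", call. = FALSE)
  ((t - cycle_start) / natural_period) %% 1
}

#' Active-phase onsets of a trace
#'
#' The onset (phase 0) of each burst active phase is the upward crossing
#' of the midpoint between the cycle minimum and maximum, a robust
#' marker-event definition of "beginning of the active phase".
#'
#' @inheritParams detect_nadirs
#' @return Numeric vector of onset times, seconds.
#' @export
active_phase_onsets <- function(trace, smooth_s = 25) {
  stopifnot(inherits(trace, "ca_trace"))
  dt <- trace_dt(trace)
  k <- max(1, round(smooth_s / dt)); if (k %% 2 == 0) k <- k + 1
  xs <- if (k > 1)
    as.numeric(stats::filter(trace$values, rep(1 / k, k), sides = 2))
  else trace$values
  ok <- !is.na(xs); xs <- xs[ok]; tt <- trace$times[ok]
  q <- stats::quantile(xs, c(0.02, 0.98), names = FALSE)
  mid <- mean(q)
  up <- which(xs[-1] >= mid & xs[-length(xs)] < mid)
  if (!length(up))
    stop("no active-phase onsets found", call. = FALSE)
  # linear interpolation of the crossing time
  frac <- (mid - xs[up]) / (xs[up + 1] - xs[up])
  tt[up] + frac * dt
}

#' Phase shift between an unperturbed and a pulse-perturbed trajectory
#'
#' Measures the timing difference of matched cytosolic Ca2+ nadirs in two
#' trajectories of the same model islet, one of which received a single
#' IP3 pulse.  The first perturbed nadir following the pulse-induced
#' resetting is paired with the nearest unperturbed nadir (ties toward
#' the earlier one) and the difference is expressed as a fraction of the
#' natural period, wrapped into (-0.5, 0.5].  Negative values are phase
#' advances, positive values delays.
#'
#' @param unperturbed,perturbed Trajectories from [simulate_iom()] with
#'   identical parameters and initial state.
#' @param pulse_time Pulse onset time, seconds.
#' @param natural_period Natural period in seconds; computed from the
#'   unperturbed trajectory when `NULL`.
#' @param settle_s Nadirs earlier than `pulse_time + settle_s` are not
#'   counted as post-reset nadirs (the pulse transient itself can graze a
#'   local minimum); default is the 10 s pulse plus one IP3 time
#'   constant.
#' @param ... Passed to [detect_nadirs()].
#' @return Phase difference in (-0.5, 0.5] (fraction of a period).
#' @export
phase_shift <- function(unperturbed, perturbed, pulse_time,
                        natural_period = NULL, settle_s = 20, ...) {
  nad_u <- detect_nadirs(trajectory_ca_trace(unperturbed), ...)
  nad_p <- detect_nadirs(trajectory_ca_trace(perturbed), ...)
  if (is.null(natural_period)) natural_period <- mean(diff(nad_u))
  cand <- nad_p[nad_p > pulse_time + settle_s]
  if (!length(cand))
    stop("no perturbed nadir found after the pulse", call. = FALSE)
  tp <- cand[1]
  d <- tp - nad_u
  if (min(abs(d)) > 0.75 * natural_period)
    stop("nadir matching ambiguous: perturbed nadir is more than 0.75 ",
         "periods from every unperturbed nadir", call. = FALSE)
  # nearest unperturbed nadir; ties broken toward the earlier one
  i <- which(abs(d) == min(abs(d)))[1]
  dphi <- d[i] / natural_period
  ((dphi + 0.5) %% 1) - 0.5
}

trajectory_ca_trace <- function(x) {
  if (inherits(x, "ca_trace")) return(x)
  if (is.data.frame(x) && all(c("time_s", "ca_c") %in% names(x)))
    return(ca_trace(x$time_s, x$ca_c))
  stop("expected a trajectory data frame with `time_s` and `ca_c` columns",
       call. = FALSE)
}

#' Phase response curve of the model islet to single IP3 pulses
#'
#' Simulates the unperturbed model to locate a reference active-phase
#' onset (after discarding a transient), then applies one short IP3 pulse
#' per run at each phase of an evenly spaced grid over `[0, 1)` and
#' records the resulting nadir shift via [phase_shift()].  Advances
#' (negative shifts) occur when the pulse lands in the Ca2+ plateau,
#' delays (positive) when it lands late in the silent phase; both signs
#' together make the curve type 2, the property that lets periodic
#' pulses entrain the oscillator.
#'
#' @param params Model parameters from [iom_params()].
#' @param n_phases Number of grid phases (>= 4); default 50.
#' @param pulse_duration Pulse length in seconds (default 10).
#' @param pulse_amplitude IP3 drive amplitude, uM; defaults to the value
#'   in `params`.
#' @param transient_s Transient discarded before the reference onset, s.
#' @param dt_out Output sampling interval of the underlying simulations, s.
#' @param ... Passed to [detect_nadirs()].
#' @return An object of class `prc_curve`: data frame with columns
#'   `phase`, `delta_phi`, plus attributes `natural_period` (s) and
#'   `onset_time` (s).
#' @export
compute_prc <- function(params = iom_params(), n_phases = 50,
                        pulse_duration = 10, pulse_amplitude = NULL,
                        transient_s = 1200, dt_out = 1, ...) {
  if (n_phases < 4) stop("`n_phases` must be >= 4", call. = FALSE)
  if (is.null(pulse_amplitude)) pulse_amplitude <- params$ip3_amp

  # the transient is discarded inside find_limit_cycle_state, so the
  # reference run starts on the limit cycle already
  y0 <- find_limit_cycle_state(params, transient_s = transient_s)
  horizon <- 2700
  unpert <- simulate_iom(params, no_pulses(), t_end = horizon,
                         dt_out = dt_out, initial = y0)
  tr_u <- trajectory_ca_trace(unpert)
  nad_u <- detect_nadirs(tr_u, ...)
  if (length(nad_u) < 3)
    stop("model is not oscillatory at these parameters (regime error)",
         call. = FALSE)
  period <- mean(diff(nad_u))
  onsets <- active_phase_onsets(tr_u, ...)
  onset <- onsets[onsets > 240][1]
  if (is.na(onset))
    stop("no active-phase onset found after the transient", call. = FALSE)
  # phase 0 is the active-phase onset, phase 1 the nadir ending the
  # following silent phase; the pulse grid spans that interval
  nad_next <- nad_u[nad_u > onset][1]
  if (is.na(nad_next))
    stop("no nadir found after the reference onset", call. = FALSE)
  span <- nad_next - onset

  phases <- seq(0, 1, length.out = n_phases + 1)[seq_len(n_phases)]
  dphi <- vapply(phases, function(ph) {
    tp <- onset + ph * span
    train <- pulse_train(tp, duration_d = pulse_duration,
                         drive_amplitude = pulse_amplitude)
    pert <- simulate_iom(params, train, t_end = horizon,
                         dt_out = dt_out, initial = y0)
    phase_shift(unpert, pert, pulse_time = tp, natural_period = period, ...)
  }, numeric(1))

  structure(
    data.frame(phase = phases, delta_phi = dphi),
    natural_period = period,
    onset_time = onset,
    class = c("prc_curve", "data.frame")
  )
}

#' Write a PRC to CSV
#'
#' @param prc A `prc_curve` from [compute_prc()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_prc_csv <- function(prc, path) {
  utils::write.csv(data.frame(phase = prc$phase, delta_phi = prc$delta_phi),
                   path, row.names = FALSE)
  invisible(path)
}
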