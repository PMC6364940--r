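#' Uniformly sampled calcium trace
#'
#' @param times Sample times in seconds, uniformly spaced (relative
#'   tolerance 1e-6), length >= 2.
#' @param values Signal values (uM or arbitrary fluorescence units).
#' @return An object of class `ca_trace` with elements `times` and
#'   `values`.
#' @export
ca_trace <- function(times, values) {
  times <- as.numeric(times); values <- as.numeric(values)
  if (length(times) < 2L)
    stop("a trace needs at least 2 samples", call. = FALSE)
  if (length(times) != length(values))
    stop("`times` and `values` must have equal length", call. = FALSE)
  if (anyNA(times) || anyNA(values))
    stop("trace contains missing values", call. = FALSE)
  dt <- diff(times)
  if (any(dt <= 0))
    stop("trace times must be strictly increasing", call. = FALSE)
  if ((max(dt) - min(dt)) > 1e-6 * max(dt))
    stop("trace is not uniformly sampled (spacing varies by more than 1e-6)",
         call. = FALSE)
  structure(list(times = times, values = values), class = "ca_trace")
}

#' @export
print.ca_trace <- function(x, ...) {
  cat(sprintf("Ca2+ trace: %d samples every %g s (%.1f min)\n",
              length(x$times), trace_dt(x), diff(range(x$times)) / 60))
  invisible(x)
}

trace_dt <- function(trace) (trace$times[2] - trace$times[1])

#' Group of traces on a shared time grid
#'
#' @param times Shared sample times, seconds.
#' @param values Matrix with one column per islet (rows are time points),
#'   or a list of equal-length numeric vectors.
#' @param labels Optional column labels.
#' @return An object of class `trace_group`.
#' @export
trace_group <- function(times, values, labels = NULL) {
  if (is.list(values) && !is.data.frame(values))
    values <- do.call(cbind, values)
  values <- as.matrix(values)
  if (nrow(values) != length(times))
    stop("`values` must have one row per time point", call. = FALSE)
  ca_trace(times, values[, 1])  # validates the grid
  if (is.null(labels))
    labels <- colnames(values)
  if (is.null(labels))
    labels <- paste0("islet_", seq_len(ncol(values)))
  colnames(values) <- labels
  structure(list(times = as.numeric(times), values = values, labels = labels),
            class = "trace_group")
}

#' @export
print.trace_group <- function(x, ...) {
  cat(sprintf("Trace group: %d islet(s), %d samples every %g s\n",
              ncol(x$values), nrow(x$values), x$times[2] - x$times[1]))
  invisible(x)
}

#' Number of traces in a group
#' @param group A `trace_group`.
#' @return Integer count.
#' @export
n_traces <- function(group) ncol(group$values)

#' Extract one trace from a group
#' @param group A `trace_group`.
#' @param i Column index or label.
#' @return A `ca_trace`.
#' @export
group_trace <- function(group, i) ca_trace(group$times, group$values[, i])

#' Mean trace of a group
#' @param group A `trace_group`.
#' @return A `ca_trace` holding the across-islet average.
#' @export
mean_trace <- function(group) ca_trace(group$times, rowMeans(group$values))

#' Remove a linear background
#'
#' Subtracts the least-squares straight line fitted to the trace, so the
#' output is centred on zero with no linear trend.  This mirrors the
#' standard preprocessing applied to islet fluorescence records before
#' spectral analysis.
#'
#' @param trace A `ca_trace` (length >= 3).
#' @return A `ca_trace` of residuals.
#' @export
background_subtract <- function(trace) {
  stopifnot(inherits(trace, "ca_trace"))
  if (length(trace$times) < 3L)
    stop("need at least 3 samples to fit a background line", call. = FALSE)
  fit <- stats::lm.fit(cbind(1, trace$times), trace$values)
  ca_trace(trace$times, fit$residuals)
}

#' Linear-interpolation upsampling
#'
#' Inserts `n_insert` equally spaced points between each pair of adjacent
#' samples using linear interpolation; original samples are preserved
#' exactly.  With `n_insert = 2` (the default used throughout the
#' analysis pipeline) a trace of length L becomes length 3(L-1) + 1.
#'
#' @param trace A `ca_trace`.
#' @param n_insert Number of points to insert per gap (>= 0).
#' @return A `ca_trace` on the refined grid.
#' @export
interpolate_upsample <- function(trace, n_insert = 2) {
  stopifnot(inherits(trace, "ca_trace"))
  if (n_insert < 0 || n_insert != round(n_insert))
    stop("`n_insert` must be a non-negative integer", call. = FALSE)
  if (n_insert == 0) return(trace)
  L <- length(trace$times)
  new_times <- seq(trace$times[1], trace$times[L],
                   length.out = (L - 1L) * (n_insert + 1L) + 1L)
  vals <- stats::approx(trace$times, trace$values, xout = new_times)$y
  idx_orig <- seq(1L, length(new_times), by = n_insert + 1L)
  vals[idx_orig] <- trace$values  # exact preservation of original samples
  ca_trace(new_times, vals)
}

#' Spectrogram configuration
#'
#' Defaults follow the standard islet analysis settings: a 256-point
#' Hanning window shifted by 5 samples, with each tapered window
#' zero-padded to give 1000 positive-frequency bins.
#'
#' @param window_len Window length in samples (>= 8).
#' @param hop Window shift in samples (>= 1).
#' @param n_freq_bins Number of positive-frequency bins
#'   (>= `window_len / 2`); the tapered window is zero-padded to
#'   `2 * n_freq_bins` samples.
#' @param window_shape Taper name; `"hanning"` (only supported value).
#' @return An object of class `spectrogram_config`.
#' @export
spectrogram_config <- function(window_len = 256, hop = 5,
                               n_freq_bins = 1000,
                               window_shape = "hanning") {
  if (window_len < 8) stop("`window_len` must be >= 8", call. = FALSE)
  if (hop < 1) stop("`hop` must be >= 1", call. = FALSE)
  if (n_freq_bins < window_len / 2)
    stop("`n_freq_bins` must be >= window_len / 2", call. = FALSE)
  window_shape <- match.arg(window_shape, "hanning")
  structure(list(window_len = as.integer(window_len), hop = as.integer(hop),
                 n_freq_bins = as.integer(n_freq_bins),
                 window_shape = window_shape),
            class = "spectrogram_config")
}

#' Short-time Fourier transform spectrogram on a period axis
#'
#' Slides a tapered window along the trace, zero-pads each windowed
#' segment to `2 * n_freq_bins` samples, and records the magnitude
#' spectrum over the positive-frequency bins.  The frequency axis is
#' converted to an oscillation period in minutes, which is how slow
#' calcium rhythms are usually read.
#'
#' @param trace A `ca_trace` at least as long as the window.
#' @param config A [spectrogram_config()].
#' @return An object of class `ca_spectrogram`: a list with
#'   `window_center_times` (s), `period_axis` (min, decreasing),
#'   `magnitudes` (windows x period bins), and `config`.
#' @export
stft_spectrogram <- function(trace, config = spectrogram_config()) {
  stopifnot(inherits(trace, "ca_trace"))
  stopifnot(inherits(config, "spectrogram_config"))
  x <- trace$values
  L <- length(x)
  wl <- config$window_len
  if (L < wl)
    stop("insufficient data: trace has ", L, " samples but the window needs ",
         wl, call. = FALSE)
  dt <- trace_dt(trace)
  nfft <- 2L * config$n_freq_bins
  taper <- hanning_window(wl)
  starts <- seq(1L, L - wl + 1L, by = config$hop)
  mags <- matrix(0, nrow = length(starts), ncol = config$n_freq_bins)
  padded <- numeric(nfft)
  for (i in seq_along(starts)) {
    seg <- x[starts[i]:(starts[i] + wl - 1L)] * taper
    padded[seq_len(wl)] <- seg
    sp <- stats::fft(padded)
    mags[i, ] <- Mod(sp[2:(config$n_freq_bins + 1L)])
  }
  freqs <- seq_len(config$n_freq_bins) / (nfft * dt)  # Hz
  structure(
    list(window_center_times = trace$times[starts] + (wl - 1) * dt / 2,
         period_axis = 1 / freqs / 60,
         magnitudes = mags,
         config = config),
    class = "ca_spectrogram"
  )
}

#' @export
print.ca_spectrogram <- function(x, ...) {
  cat(sprintf("Spectrogram: %d windows x %d period bins, window centres %.1f-%.1f min\n",
              nrow(x$magnitudes), ncol(x$magnitudes),
              min(x$window_center_times) / 60, max(x$window_center_times) / 60))
  invisible(x)
}

hanning_window <- function(n) {
  # symmetric Hann taper; signal::hanning gives the same shape
  0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))
}

#' Dominant band of a spectrogram over a time window
#'
#' For each STFT window centred inside `t_window` the period bin with the
#' largest magnitude is found (within `period_range`), and the
#' magnitude-weighted consensus period is returned.  Periods above 10 min
#' are excluded by default because such bands are known artifacts of the
#' windowed transform on slow drifting records.
#'
#' @param spec A `ca_spectrogram`.
#' @param t_window Length-2 numeric, time window in seconds (default: all).
#' @param period_range Reportable period range in minutes.
#' @return Dominant period in minutes (median over windows of the
#'   per-window argmax).
#' @export
spectrogram_band <- function(spec, t_window = NULL,
                             period_range = c(1, 10)) {
  stopifnot(inherits(spec, "ca_spectrogram"))
  keep_t <- if (is.null(t_window)) rep(TRUE, nrow(spec$magnitudes))
            else spec$window_center_times >= t_window[1] &
                 spec$window_center_times <= t_window[2]
  if (!any(keep_t))
    stop("no spectrogram windows fall inside `t_window`", call. = FALSE)
  keep_p <- spec$period_axis >= period_range[1] &
            spec$period_axis <= period_range[2]
  per <- spec$period_axis[keep_p]
  m <- spec$magnitudes[keep_t, keep_p, drop = FALSE]
  stats::median(per[apply(m, 1, which.max)])
}

#' Dominant oscillation period by FFT
#'
#' Detrends the selected segment, applies a Hann taper, zero-pads the FFT
#' until the period resolution is at or below 0.1 min across the
#' reportable range, and returns the period of the largest-magnitude bin
#' inside `period_range`.  The result is rounded to 0.1 min, the
#' precision at which islet oscillation periods are conventionally
#' reported.  An attribute `confidence` is set to `"low"` when the
#' spectral peak is not prominent (peak below 3x the median in-range
#' magnitude), as happens for aperiodic traces.
#'
#' @param trace A `ca_trace`.
#' @param t_window Optional length-2 window in seconds.
#' @param period_range Reportable period range, minutes.
#' @return Period in minutes with attribute `confidence`
#'   (`"high"`/`"low"`).
#' @export
major_period <- function(trace, t_window = NULL, period_range = c(2, 15)) {
  stopifnot(inherits(trace, "ca_trace"))
  tt <- trace$times; x <- trace$values
  if (!is.null(t_window)) {
    keep <- tt >= t_window[1] & tt <= t_window[2]
    tt <- tt[keep]; x <- x[keep]
  }
  span <- if (length(tt) > 1) tt[length(tt)] - tt[1] else 0
  if (length(tt) < 8 || span < 2 * period_range[1] * 60)
    stop("insufficient data: window must contain at least two cycles of the ",
         "shortest reportable period (", period_range[1], " min)", call. = FALSE)
  seg <- background_subtract(ca_trace(tt, x))
  dt <- trace_dt(seg)
  y <- seg$values * hanning_window(length(seg$values))
  # pad so that the period resolution T^2 * df is <= 0.1 min at the top of
  # the reportable range
  tmax_s <- min(period_range[2] * 60, span / 2)
  nfft <- 2^ceiling(log2(max(length(y), tmax_s^2 / (0.1 * 60) / dt)))
  sp <- Mod(stats::fft(c(y, numeric(nfft - length(y)))))[2:(nfft %/% 2)]
  freqs <- seq_len(nfft %/% 2 - 1) / (nfft * dt)
  periods <- 1 / freqs / 60
  keep <- periods >= period_range[1] & periods <= min(period_range[2], span / 2 / 60)
  if (!any(keep))
    stop("insufficient data: no FFT bins inside the reportable period range",
         call. = FALSE)
  sp_in <- sp[keep]; per_in <- periods[keep]
  i <- which.max(sp_in)
  conf <- if (sp_in[i] >= 3 * stats::median(sp_in)) "high" else "low"
  structure(round(per_in[i], 1), confidence = conf)
}

#' Classify p:q entrainment from two periods
#'
#' Finds the smallest coprime ratio p:q (p pulses per q response peaks,
#' both <= 3) such that p times the stimulus period matches q times the
#' response period within a relative tolerance.  A stimulus of 10 min
#' with a 5 min response is 1:2 (one pulse for every two calcium peaks);
#' a 2 min stimulus with a 4 min response is 2:1.
#'
#' @param stimulus_period Stimulus period, minutes.
#' @param response_period Response period, minutes.
#' @param tol Relative tolerance (0 < tol <= 0.3).
#' @return A string `"p:q"`, or `"unentrained"` if no small ratio fits.
#' @export
classify_entrainment <- function(stimulus_period, response_period, tol = 0.15) {
  if (stimulus_period <= 0 || response_period <= 0)
    stop("periods must be positive", call. = FALSE)
  if (tol <= 0 || tol > 0.3)
    stop("`tol` must be in (0, 0.3]", call. = FALSE)
  pairs <- list(c(1, 1), c(1, 2), c(2, 1), c(1, 3), c(3, 1), c(2, 3), c(3, 2))
  for (pq in pairs) {
    p <- pq[1]; q <- pq[2]
    if (abs(p * stimulus_period - q * response_period) <=
        tol * q * response_period)
      return(sprintf("%d:%d", p, q))
  }
  "unentrained"
}

#' Phase-based synchronization index
#'
#' Assigns each trace an instantaneous phase that advances linearly from
#' 0 to 2*pi between successive nadirs, and computes the Kuramoto order
#' parameter (the modulus of the mean unit phase vector across traces),
#' averaged over the time window.  The index is 1 for identical in-phase
#' oscillators and near 0 for phases spread uniformly on the circle.
#'
#' @param group A `trace_group` with >= 2 traces.
#' @param t_window Optional length-2 time window, seconds.
#' @param ... Passed to [detect_nadirs()] (e.g. `smooth_s`).
#' @return Synchronization index in `[0, 1]`.
#' @export
synchronization_index <- function(group, t_window = NULL, ...) {
  stopifnot(inherits(group, "trace_group"))
  if (n_traces(group) < 2L)
    stop("synchronization index is undefined for fewer than 2 traces",
         call. = FALSE)
  tt <- group$times
  phases <- lapply(seq_len(n_traces(group)), function(j) {
    nads <- detect_nadirs(group_trace(group, j), ...)
    ph <- rep(NA_real_, length(tt))
    ok <- tt >= nads[1] & tt <= nads[length(nads)]
    ph[ok] <- stats::approx(nads, seq_along(nads) - 1, xout = tt[ok])$y
    ph * 2 * pi
  })
  P <- do.call(cbind, phases)
  keep <- stats::complete.cases(P)
  if (!is.null(t_window))
    keep <- keep & tt >= t_window[1] & tt <= t_window[2]
  if (sum(keep) < 2)
    stop("time window too short: no overlap of defined phases", call. = FALSE)
  z <- exp(1i * P[keep, , drop = FALSE])
  mean(Mod(rowMeans(z)))
}

#' Full group analysis pipeline
#'
#' Reproduces the standard analysis applied to a group of islets: the
#' across-islet mean trace is background subtracted, upsampled by linear
#' interpolation, and turned into an STFT spectrogram; each islet's
#' dominant period is measured before and during pulsing; entrainment is
#' classified per islet against the stimulus period; and the
#' synchronization index is computed before, during, and after the pulse
#' train.  Without a pulse train only whole-record quantities are
#' reported.
#'
#' @param group A `trace_group`.
#' @param pulse_train Optional `pulse_train` delimiting the before /
#'   during / after windows (first to last pulse onset).
#' @param config A [spectrogram_config()].
#' @param n_insert Interpolation upsampling factor for the spectrogram
#'   input.
#' @param entrain_tol Tolerance for [classify_entrainment()].
#' @param ... Passed to [detect_nadirs()] via [synchronization_index()].
#' @return A list of class `islet_report` with elements `spectrogram`,
#'   `periods` (data frame), `sync` (named numeric), and `windows`.
#' @export
analyze_group <- function(group, pulse_train = NULL,
                          config = spectrogram_config(), n_insert = 2,
                          entrain_tol = 0.15, ...) {
  stopifnot(inherits(group, "trace_group"))
  avg <- interpolate_upsample(background_subtract(mean_trace(group)), n_insert)
  spec <- stft_spectrogram(avg, config)

  t0 <- group$times[1]; t1 <- group$times[length(group$times)]
  has_pulses <- !is.null(pulse_train) && length(pulse_train$onsets) > 0
  windows <- if (has_pulses) {
    on1 <- pulse_train$onsets[1]
    onN <- pulse_train$onsets[length(pulse_train$onsets)]
    list(before = c(t0, on1), during = c(on1, min(onN + 600, t1)),
         after = c(min(onN + 600, t1), t1))
  } else {
    list(before = c(t0, t1), during = NULL, after = NULL)
  }

  stim_period <- if (has_pulses && length(pulse_train$onsets) > 1)
    stats::median(diff(pulse_train$onsets)) / 60 else NA_real_

  per_row <- function(j) {
    tr <- group_trace(group, j)
    before <- try_period(tr, windows$before)
    during <- if (has_pulses) try_period(tr, windows$during) else NA_real_
    mode <- if (has_pulses && !is.na(stim_period) && !is.na(during))
      classify_entrainment(stim_period, during, tol = entrain_tol)
    else NA_character_
    data.frame(islet = group$labels[j],
               period_before = as.numeric(before),
               period_during = as.numeric(during),
               mode = mode, stringsAsFactors = FALSE)
  }
  periods <- do.call(rbind, lapply(seq_len(n_traces(group)), per_row))

  sync <- c(before = NA_real_, during = NA_real_, after = NA_real_)
  if (n_traces(group) >= 2) {
    sync["before"] <- try_sync(group, windows$before, ...)
    if (has_pulses) {
      sync["during"] <- try_sync(group, windows$during, ...)
      sync["after"] <- try_sync(group, windows$after, ...)
    }
  }

  structure(
    list(spectrogram = spec, periods = periods, sync = sync,
         windows = windows, stimulus_period = stim_period),
    class = "islet_report"
  )
}

try_period <- function(trace, w) {
  out <- try(major_period(trace, t_window = w), silent = TRUE)
  if (inherits(out, "try-error")) NA_real_ else out
}

try_sync <- function(group, w, ...) {
  out <- try(synchronization_index(group, t_window = w, ...), silent = TRUE)
  if (inherits(out, "try-error")) NA_real_ else out
}

#' @export
print.islet_report <- function(x, ...) {
  cat("Islet group analysis\n")
  if (!is.na(x$stimulus_period))
    cat(sprintf("  stimulus period: %.1f min\n", x$stimulus_period))
  print(x$periods, row.names = FALSE)
  s <- x$sync[!is.na(x$sync)]
  if (length(s))
    cat("  synchronization index:",
        paste(sprintf("%s %.2f", names(s), s), collapse = ", "), "\n")
  invisible(x)
}
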