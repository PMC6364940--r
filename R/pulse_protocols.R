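#' Square-wave pulse profile
#'
#' A pulse train is characterized by three numbers: the rest time `R`
#' between pulse onsets, the agonist concentration `C`, and the duration
#' `D` of each pulse.  `R` is given in minutes (the unit in which rest
#' times are reported), `D` in seconds.
#'
#' @param rest_time_r Rest time R between pulses, in minutes.  Interpreted
#'   by default as the onset-to-onset period of the train (see
#'   [periodic_train()]).
#' @param concentration_c Agonist concentration of the pulse, in uM.  The
#'   concentration is a label only: the model maps any pulse to a single
#'   IP3 drive amplitude (see [iom_params()]).
#' @param duration_d Pulse duration D, in seconds.
#' @return An object of class `pulse_profile`.
#' @examples
#' pulse_profile(rest_time_r = 5)
#' @export
pulse_profile <- function(rest_time_r, concentration_c = 10, duration_d = 10) {
  if (!is.numeric(rest_time_r) || length(rest_time_r) != 1L || rest_time_r <= 0)
    stop("`rest_time_r` must be a single positive number (minutes)", call. = FALSE)
  if (!is.numeric(duration_d) || length(duration_d) != 1L || duration_d <= 0)
    stop("`duration_d` must be a single positive number (seconds)", call. = FALSE)
  if (duration_d >= rest_time_r * 60)
    stop("pulse duration D (", duration_d, " s) must be shorter than the rest time R (",
         rest_time_r, " min)", call. = FALSE)
  structure(
    list(rest_time_r = rest_time_r,
         concentration_c = concentration_c,
         duration_d = duration_d),
    class = "pulse_profile"
  )
}

#' @export
print.pulse_profile <- function(x, ...) {
  cat(sprintf("Pulse profile: R = %g min, C = %g uM, D = %g s\n",
              x$rest_time_r, x$concentration_c, x$duration_d))
  invisible(x)
}

#' Realized pulse train
#'
#' Low-level constructor for a train of square pulses given by explicit
#' onset times.  Most users will call [periodic_train()] or
#' [random_train()] instead.
#'
#' @param onsets Pulse onset times in seconds, strictly increasing.
#' @param duration_d Pulse duration in seconds (common to all pulses).
#' @param drive_amplitude IP3 drive amplitude reached while a pulse is on,
#'   in uM.
#' @return An object of class `pulse_train`.
#' @export
pulse_train <- function(onsets, duration_d = 10, drive_amplitude = 0.35) {
  onsets <- as.numeric(onsets)
  if (length(onsets) < 1L || anyNA(onsets))
    stop("`onsets` must contain at least one finite time", call. = FALSE)
  if (is.unsorted(onsets, strictly = TRUE))
    stop("pulse onsets must be strictly increasing", call. = FALSE)
  if (duration_d <= 0)
    stop("`duration_d` must be positive", call. = FALSE)
  if (length(onsets) > 1L && min(diff(onsets)) < duration_d)
    stop("pulses overlap: successive onsets must be separated by at least ",
         duration_d, " s", call. = FALSE)
  if (drive_amplitude < 0)
    stop("`drive_amplitude` must be non-negative", call. = FALSE)
  structure(
    list(onsets = onsets, duration_d = duration_d,
         drive_amplitude = drive_amplitude),
    class = "pulse_train"
  )
}

#' @export
print.pulse_train <- function(x, ...) {
  cat(sprintf("Pulse train: %d pulse(s), D = %g s, drive %g uM\n",
              length(x$onsets), x$duration_d, x$drive_amplitude))
  cat(sprintf("  onsets (min): %s\n",
              paste(round(x$onsets / 60, 2), collapse = ", ")))
  invisible(x)
}

#' Empty pulse train
#'
#' Convenience constructor for the unstimulated condition.
#'
#' @param drive_amplitude IP3 drive amplitude that pulses would have, uM.
#' @return A `pulse_train` with no pulses.
#' @export
no_pulses <- function(drive_amplitude = 0.35) {
  structure(
    list(onsets = numeric(0), duration_d = 10,
         drive_amplitude = drive_amplitude),
    class = "pulse_train"
  )
}

#' Periodic pulse train from an R/C/D profile
#'
#' Builds a train of `n_pulses` square pulses.  By default the rest time R
#' is interpreted as the onset-to-onset period, so a train of twenty
#' pulses with R = 2 min spans 38 min from first to last onset, and twelve
#' pulses with R = 5 min span 55 min.  Setting `r_semantics = "gap"`
#' instead treats R as the off-time between the end of one pulse and the
#' onset of the next.
#'
#' @param profile A [pulse_profile()].
#' @param n_pulses Number of pulses (>= 1).
#' @param t_start Onset time of the first pulse, in seconds.  Defaults to
#'   20 min, the usual pre-pulse observation window.
#' @param drive_amplitude IP3 drive amplitude, uM.
#' @param r_semantics Either `"onset"` (R is the onset-to-onset period,
#'   the default) or `"gap"` (R is the inter-pulse off time).
#' @return A `pulse_train`.
#' @examples
#' tr <- periodic_train(pulse_profile(rest_time_r = 2), n_pulses = 20, t_start = 0)
#' max(tr$onsets) / 60  # 38 min
#' @export
periodic_train <- function(profile, n_pulses, t_start = 1200,
                           drive_amplitude = 0.35,
                           r_semantics = c("onset", "gap")) {
  stopifnot(inherits(profile, "pulse_profile"))
  r_semantics <- match.arg(r_semantics)
  if (!is.numeric(n_pulses) || length(n_pulses) != 1L || n_pulses < 1 ||
      n_pulses != round(n_pulses))
    stop("`n_pulses` must be a positive integer", call. = FALSE)
  period <- profile$rest_time_r * 60
  if (r_semantics == "gap")
    period <- period + profile$duration_d
  if (profile$duration_d >= period)
    stop("invalid profile: pulse duration is not shorter than the pulse period",
         call. = FALSE)
  onsets <- t_start + (seq_len(n_pulses) - 1L) * period
  pulse_train(onsets, duration_d = profile$duration_d,
              drive_amplitude = drive_amplitude)
}

#' Randomly spaced pulse train
#'
#' Builds a train whose successive onset-to-onset gaps are integers drawn
#' uniformly (in minutes) from `gap_min:gap_max`, reproducibly for a fixed
#' seed.  This is the protocol used to test synchronization by
#' non-periodic stimulation, with gaps drawn from 2--18 min.
#'
#' @param n_pulses Number of pulses (>= 1).
#' @param gap_min,gap_max Smallest and largest allowed gap, integer
#'   minutes.
#' @param seed Integer seed for the gap draws.
#' @param t_start Onset of the first pulse, seconds.
#' @param duration_d Pulse duration, seconds.
#' @param drive_amplitude IP3 drive amplitude, uM.
#' @return A `pulse_train`.
#' @examples
#' tr <- random_train(8, seed = 1)
#' diff(tr$onsets) / 60  # integer gaps in [2, 18]
#' @export
random_train <- function(n_pulses, gap_min = 2, gap_max = 18, seed = 1,
                         t_start = 1200, duration_d = 10,
                         drive_amplitude = 0.35) {
  if (!is.numeric(n_pulses) || n_pulses < 1 || n_pulses != round(n_pulses))
    stop("`n_pulses` must be a positive integer", call. = FALSE)
  if (gap_min <= 0 || gap_max < gap_min ||
      gap_min != round(gap_min) || gap_max != round(gap_max))
    stop("gaps must satisfy 0 < gap_min <= gap_max, both integer minutes",
         call. = FALSE)
  if (gap_min * 60 <= duration_d)
    stop("smallest gap (", gap_min, " min) must exceed the pulse duration (",
         duration_d, " s)", call. = FALSE)
  gaps <- if (n_pulses > 1L) {
    choices <- seq.int(gap_min, gap_max)
    with_preserved_seed(seed, {
      choices[sample.int(length(choices), n_pulses - 1L, replace = TRUE)]
    }) * 60
  } else numeric(0)
  onsets <- t_start + c(0, cumsum(gaps))
  pulse_train(onsets, duration_d = duration_d,
              drive_amplitude = drive_amplitude)
}

#' Is the pulse drive on at given times?
#'
#' @param train A `pulse_train`.
#' @param t Times in seconds.
#' @return Logical vector, `TRUE` where some pulse is on.
#' @export
drive_on_at <- function(train, t) {
  stopifnot(inherits(train, "pulse_train"))
  if (length(train$onsets) == 0L) return(rep(FALSE, length(t)))
  vapply(t, function(ti) {
    any(ti >= train$onsets & ti < train$onsets + train$duration_d)
  }, logical(1))
}

#' @export
as.data.frame.pulse_train <- function(x, ...) {
  data.frame(onset_s = x$onsets,
             duration_s = rep(x$duration_d, length(x$onsets)),
             amplitude = rep(x$drive_amplitude, length(x$onsets)))
}

#' Write / read a pulse train as CSV
#'
#' Columns are `onset_s`, `duration_s`, `amplitude`.
#'
#' @param train A `pulse_train`.
#' @param path File path.
#' @return `write_pulse_csv()` returns `path` invisibly; `read_pulse_csv()`
#'   returns a `pulse_train`.
#' @export
write_pulse_csv <- function(train, path) {
  utils::write.csv(as.data.frame(train), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pulse_csv
#' @export
read_pulse_csv <- function(path) {
  d <- utils::read.csv(path)
  need <- c("onset_s", "duration_s", "amplitude")
  if (!all(need %in% names(d)))
    stop("pulse CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (nrow(d) == 0L) return(no_pulses())
  pulse_train(d$onset_s, duration_d = d$duration_s[1],
              drive_amplitude = d$amplitude[1])
}

# Run `expr` under a fixed RNG seed without disturbing the caller's
# random-number stream.
with_preserved_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
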