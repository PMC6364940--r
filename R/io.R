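#' Read a trace group from CSV
#'
#' Expects a header row with a time column (`time_s`, or the first
#' column) followed by one column per islet.  Times are assumed to be in
#' seconds; sampling must be uniform and strictly monotone.
#'
#' @param path CSV file path.
#' @return A `trace_group`.
#' @export
read_trace_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- utils::read.csv(path, check.names = FALSE)
  if (ncol(d) < 2L)
    stop("trace CSV needs a time column plus at least one islet column",
         call. = FALSE)
  tcol <- if ("time_s" %in% names(d)) "time_s" else names(d)[1]
  tt <- d[[tcol]]
  if (!is.numeric(tt))
    stop("format error: time column `", tcol, "` is not numeric", call. = FALSE)
  dtt <- diff(tt)
  if (any(dtt <= 0)) {
    bad <- which(dtt <= 0)[1] + 1L
    stop("format error: time is not strictly increasing at row ", bad,
         call. = FALSE)
  }
  if ((max(dtt) - min(dtt)) > 1e-6 * max(dtt)) {
    bad <- which.max(abs(dtt - stats::median(dtt))) + 1L
    stop("format error: non-uniform sampling at row ", bad, call. = FALSE)
  }
  vals <- as.matrix(d[setdiff(names(d), tcol)])
  if (!is.numeric(vals))
    stop("format error: non-numeric islet column(s)", call. = FALSE)
  trace_group(tt, vals, labels = setdiff(names(d), tcol))
}

#' Write a trace group to CSV
#'
#' @param group A `trace_group`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(group, path) {
  stopifnot(inherits(group, "trace_group"))
  d <- data.frame(time_s = group$times, group$values, check.names = FALSE)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Write a spectrogram matrix to CSV
#'
#' Rows are STFT windows; the first column is the window centre time
#' (s), remaining columns one per period bin, named by the period in
#' minutes.
#'
#' @param spec A `ca_spectrogram`.
#' @param path Output path.
#' @param period_range Optional period range (min) to restrict columns,
#'   keeping file sizes manageable.
#' @return `path`, invisibly.
#' @export
write_spectrogram_csv <- function(spec, path, period_range = c(1, 15)) {
  stopifnot(inherits(spec, "ca_spectrogram"))
  keep <- spec$period_axis >= period_range[1] &
    spec$period_axis <= period_range[2]
  m <- spec$magnitudes[, keep, drop = FALSE]
  colnames(m) <- sprintf("p%.3f", spec$period_axis[keep])
  d <- data.frame(window_center_s = spec$window_center_times, m,
                  check.names = FALSE)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Run a complete in-silico experiment from a configuration
#'
#' Ties the pipeline together: either simulates a heterogeneous group of
#' model islets under a pulse protocol (`mode = "simulate"`) or
#' generates a synthetic group (`mode = "synth"`), then runs the
#' analysis pipeline and writes all artifacts (trace CSV, pulse CSV,
#' spectrogram CSV, report JSON with a provenance block) into an output
#' directory.
#'
#' The configuration is a named list (or path to a YAML file) with
#' blocks:
#' \describe{
#'   \item{mode}{`"simulate"` or `"synth"`.}
#'   \item{seed}{Integer seed used for population sampling / synthesis.}
#'   \item{model}{For `simulate`: `n_islets`, `t_end_min`, optional
#'     `g_cav_range`, `g_katp_range`, and named overrides of
#'     [iom_params()] defaults under `params`.}
#'   \item{synth}{For `synth`: arguments of [synth_spec()].}
#'   \item{protocol}{`type` (`"periodic"`, `"random"`, `"none"`),
#'     and for periodic: `r_min`, `n_pulses`; for random: `n_pulses`,
#'     `gap_min`, `gap_max`; common: `t_start_min`, `duration_s`.}
#'   \item{analysis}{Optional `window_len`, `hop`, `n_freq_bins`,
#'     `n_insert`, `entrain_tol`, `sync_threshold`.}
#' }
#'
#' @param config Named list or YAML file path.
#' @param outdir Output directory (created if needed).
#' @return The report list (invisibly), with element `files` naming the
#'   artifacts written.
#' @export
run_experiment <- function(config, outdir = ".") {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config,
                                   call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  mode <- match.arg(config$mode %||% "simulate", c("simulate", "synth"))
  seed <- as.integer(config$seed %||% 1L)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  tf <- tempfile(); writeLines(cfg_json, tf)
  cfg_hash <- unname(tools::md5sum(tf)); unlink(tf)

  stage <- function(name, expr) {
    out <- try(expr, silent = TRUE)
    if (inherits(out, "try-error"))
      stop("stage `", name, "` failed: ",
           conditionMessage(attr(out, "condition")), call. = FALSE)
    out
  }

  # --- stimulus protocol -------------------------------------------------
  pr <- config$protocol %||% list(type = "none")
  t_start <- (pr$t_start_min %||% 20) * 60
  dur <- pr$duration_s %||% 10
  train <- stage("protocol", switch(
    pr$type %||% "none",
    none = no_pulses(),
    periodic = periodic_train(
      pulse_profile(rest_time_r = pr$r_min %||% 5, duration_d = dur),
      n_pulses = pr$n_pulses %||% 12, t_start = t_start),
    random = random_train(pr$n_pulses %||% 8, gap_min = pr$gap_min %||% 2,
                          gap_max = pr$gap_max %||% 18, seed = seed,
                          t_start = t_start, duration_d = dur),
    stop("unknown protocol type: ", pr$type)
  ))

  # --- traces ------------------------------------------------------------
  group <- if (mode == "simulate") {
    m <- config$model %||% list()
    base <- do.call(iom_params, m$params %||% list())
    n <- m$n_islets %||% 3
    t_end <- (m$t_end_min %||% 90) * 60
    pops <- stage("population", make_heterogeneous_population(
      n, seed = seed,
      g_cav_range = unlist(m$g_cav_range %||% formals(make_heterogeneous_population)$g_cav_range),
      g_katp_range = unlist(m$g_katp_range %||% formals(make_heterogeneous_population)$g_katp_range),
      base = base))
    stage("simulate", {
      traces <- lapply(pops, function(p) {
        tr <- simulate_iom(p, train, t_end = t_end, dt_out = 1)
        ca_trace_of(tr, every = 20)  # 20-s acquisition grid
      })
      trace_group(traces[[1]]$times,
                  lapply(traces, function(x) x$values))
    })
  } else {
    sp <- do.call(synth_spec, utils::modifyList(config$synth %||% list(),
                                                list(seed = seed)))
    stage("synth", synth_group(sp))
  }

  # --- analysis ----------------------------------------------------------
  an <- config$analysis %||% list()
  sconf <- spectrogram_config(window_len = an$window_len %||% 256,
                              hop = an$hop %||% 5,
                              n_freq_bins = an$n_freq_bins %||% 1000)
  report <- stage("analyze", analyze_group(
    group,
    pulse_train = if (length(train$onsets)) train else NULL,
    config = sconf, n_insert = an$n_insert %||% 2,
    entrain_tol = an$entrain_tol %||% 0.15))

  sync_threshold <- an$sync_threshold %||% 0.6
  synchronized <- !is.na(report$sync["during"]) &&
    report$sync["during"] >= sync_threshold

  files <- c(traces = file.path(outdir, "traces.csv"),
             pulses = file.path(outdir, "pulses.csv"),
             spectrogram = file.path(outdir, "spectrogram.csv"),
             report = file.path(outdir, "report.json"))
  write_trace_csv(group, files["traces"])
  write_pulse_csv(train, files["pulses"])
  write_spectrogram_csv(report$spectrogram, files["spectrogram"])

  out <- list(
    provenance = list(config_hash = cfg_hash, seed = seed,
                      package_version = as.character(utils::packageVersion("isletsync"))),
    stimulus_period_min = report$stimulus_period,
    periods = report$periods,
    sync = as.list(report$sync),
    synchronized = synchronized,
    windows = report$windows
  )
  jsonlite::write_json(out, files["report"], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  out$files <- files
  invisible(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
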