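#' Parameters of the extended beta-cell dual oscillator model
#'
#' The model couples two conditional oscillators: a glycolytic oscillator
#' (phosphofructokinase with product activation, tracked by F6P and FBP)
#' and an electrical oscillator (membrane potential, delayed-rectifier
#' activation, cytosolic and ER Ca2+).  Coupling is bidirectional: ATP
#' produced downstream of glycolysis inhibits K(ATP) channels, and
#' cytosolic Ca2+ feeds back on metabolism through activation of
#' pyruvate dehydrogenase (PDH).  Muscarinic pulses enter as square
#' pulses of IP3 production; IP3 gates a Ca2+ release flux from the ER
#' into the cytosol.
#'
#' Units: conductances pS, potentials mV, capacitance fF, concentrations
#' uM, time s.  Defaults are calibrated so that the unperturbed model
#' bursts with a cytosolic Ca2+ period of about 5 min.
#'
#' @param g_cav Voltage-gated Ca2+ channel conductance, pS.
#' @param g_k Delayed-rectifier K+ conductance, pS.
#' @param g_kca Ca2+-activated K+ conductance, pS.
#' @param g_katp Maximal K(ATP) conductance, pS.
#' @param c_m Membrane capacitance, fF.
#' @param tau_n Delayed-rectifier activation time constant, s.
#' @param kd_kca Ca2+ affinity of the K(Ca) channel, uM.
#' @param alpha_ca Current-to-flux conversion, uM fA^-1 s^-1.
#' @param k_pmca Plasma-membrane Ca2+ pump rate, s^-1.
#' @param f_ca Fraction of free (unbuffered) Ca2+.
#' @param p_leak ER leak permeability, s^-1.
#' @param k_serca SERCA pump rate, s^-1.
#' @param sigma_v Cytosol-to-ER effective volume ratio.
#' @param p_ip3r Maximal IP3-receptor permeability, s^-1.
#' @param k_ip3 IP3 affinity of the release flux, uM.
#' @param v_pfk Maximal phosphofructokinase rate, uM s^-1.
#' @param k_pfk Relative activity of PFK with F6P bound but without the
#'   activating ligands.
#' @param j_gk Glucokinase (glucose input) flux, uM s^-1; fixed,
#'   corresponding to a constant 11 mM glucose bath.
#' @param v_pdh Maximal PDH-limited FBP consumption rate,
#'   uM^(1/2) s^-1.
#' @param k_pdh Ca2+ affinity of PDH activation, uM.
#' @param nu_pdh Gain of ATP production driven by PDH flux.
#' @param k_prod PDH flux at half-maximal ATP production drive, uM s^-1.
#' @param ca_atp Direct Ca2+ sensitivity of net ATP production, per uM
#'   (0, the default, disables this pathway: the only feedback of Ca2+
#'   onto metabolism is then the PDH route).
#' @param tau_a Nucleotide relaxation time constant, s.
#' @param a_tot Conserved adenine nucleotide pool (ATP + ADP), uM.
#' @param k1_amp,k2_fbp,k3_f6p,k4_atp Dissociation scales of the AMP,
#'   FBP, F6P^2 and ATP^2 regulatory sites of PFK, uM (uM^2 for k3, k4).
#' @param ip3_amp IP3 drive amplitude while a pulse is on, uM.
#' @param tau_ip3 IP3 relaxation time constant, s.
#' @return A named list of class `iom_params`.
#' @export
iom_params <- function(g_cav = 1000,
                       g_k = 2700,
                       g_kca = 370,
                       g_katp = 50000,
                       c_m = 5300,
                       tau_n = 0.02,
                       kd_kca = 0.5,
                       alpha_ca = 4.5e-3,
                       k_pmca = 215,
                       f_ca = 0.01,
                       p_leak = 0.15,
                       k_serca = 600,
                       sigma_v = 3.4,
                       p_ip3r = 1.9,
                       k_ip3 = 0.3,
                       v_pfk = 10,
                       k_pfk = 0.06,
                       j_gk = 0.61,
                       v_pdh = 3.75,
                       k_pdh = 0.55,
                       nu_pdh = 2.2,
                       k_prod = 0.9,
                       ca_atp = 0,
                       tau_a = 1400,
                       a_tot = 3000,
                       k1_amp = 30,
                       k2_fbp = 1,
                       k3_f6p = 50000,
                       k4_atp = 1000,
                       ip3_amp = 0.35,
                       tau_ip3 = 10) {
  p <- list(g_cav = g_cav, g_k = g_k, g_kca = g_kca, g_katp = g_katp,
            c_m = c_m, tau_n = tau_n, kd_kca = kd_kca,
            alpha_ca = alpha_ca, k_pmca = k_pmca, f_ca = f_ca,
            p_leak = p_leak, k_serca = k_serca, sigma_v = sigma_v,
            p_ip3r = p_ip3r, k_ip3 = k_ip3,
            v_pfk = v_pfk, k_pfk = k_pfk, j_gk = j_gk,
            v_pdh = v_pdh, k_pdh = k_pdh, nu_pdh = nu_pdh,
            k_prod = k_prod, ca_atp = ca_atp, tau_a = tau_a, a_tot = a_tot,
            k1_amp = k1_amp, k2_fbp = k2_fbp, k3_f6p = k3_f6p,
            k4_atp = k4_atp, ip3_amp = ip3_amp, tau_ip3 = tau_ip3)
  validate_iom_params(p)
  structure(p, class = "iom_params")
}

validate_iom_params <- function(p) {
  nonneg <- c("g_cav", "g_k", "g_kca", "g_katp", "p_ip3r", "ip3_amp",
              "j_gk", "v_pfk", "v_pdh", "a_tot")
  for (nm in nonneg)
    if (p[[nm]] < 0)
      stop("invalid parameter: `", nm, "` must be >= 0", call. = FALSE)
  pos <- c("c_m", "tau_n", "tau_a", "tau_ip3", "f_ca", "kd_kca", "k_ip3",
           "k_pdh", "k_prod", "k1_amp", "k2_fbp", "k3_f6p", "k4_atp")
  if (p$ca_atp < 0)
    stop("invalid parameter: `ca_atp` must be >= 0", call. = FALSE)
  for (nm in pos)
    if (p[[nm]] <= 0)
      stop("invalid parameter: `", nm, "` must be > 0", call. = FALSE)
  invisible(p)
}

#' @export
print.iom_params <- function(x, ...) {
  cat("Dual oscillator model parameters (extended with IP3 dynamics)\n")
  cat(sprintf("  g_CaV %g pS, g_K(ATP) %g pS, J_GK %g uM/s\n",
              x$g_cav, x$g_katp, x$j_gk))
  cat(sprintf("  IP3 pulse: amplitude %g uM, tau %g s\n", x$ip3_amp, x$tau_ip3))
  invisible(x)
}

#' Model state constructor
#'
#' The eight dynamical variables: membrane potential `v` (mV),
#' delayed-rectifier activation `n`, cytosolic and ER free Ca2+ `ca_c`,
#' `ca_er` (uM), the glycolytic metabolites `f6p` and `fbp` (uM), `atp`
#' (uM), and `ip3` (uM).
#'
#' @param v,n,ca_c,ca_er,f6p,fbp,atp,ip3 State variables.
#' @return Named numeric vector of length 8.
#' @export
iom_state <- function(v = -60, n = 0, ca_c = 0.1, ca_er = 150,
                      f6p = 200, fbp = 40, atp = 2400, ip3 = 0) {
  s <- c(v = v, n = n, ca_c = ca_c, ca_er = ca_er,
         f6p = f6p, fbp = fbp, atp = atp, ip3 = ip3)
  if (anyNA(s) || any(!is.finite(s)))
    stop("non-finite state variable: ",
         paste(names(s)[!is.finite(s)], collapse = ", "), call. = FALSE)
  if (s["n"] < 0 || s["n"] > 1)
    stop("`n` must lie in [0, 1]", call. = FALSE)
  conc <- c("ca_c", "ca_er", "f6p", "fbp", "atp", "ip3")
  if (any(s[conc] < 0))
    stop("concentrations must be >= 0: ",
         paste(conc[s[conc] < 0], collapse = ", "), call. = FALSE)
  s
}

state_names <- c("v", "n", "ca_c", "ca_er", "f6p", "fbp", "atp", "ip3")

#' Rate of change of IP3 under the pulse drive
#'
#' IP3 relaxes toward the drive amplitude while a pulse is on and decays
#' exponentially toward zero otherwise:
#' `d[IP3]/dt = (A - [IP3]) / tau_ip3` with `A = ip3_amp` during a pulse
#' and 0 between pulses.
#'
#' @param ip3 Current IP3 concentration, uM (>= 0).
#' @param drive_on Logical: is a pulse on?
#' @param params Model parameters ([iom_params()]).
#' @return d(IP3)/dt in uM/s.
#' @examples
#' ip3_rate(0.35, TRUE)   # 0: steady state at the drive amplitude
#' ip3_rate(0,    FALSE)  # 0: zero is a fixed point with the drive off
#' @export
ip3_rate <- function(ip3, drive_on, params = iom_params()) {
  if (!is.numeric(ip3) || any(ip3 < 0))
    stop("invalid parameter: `ip3` must be >= 0", call. = FALSE)
  if (params$tau_ip3 <= 0)
    stop("invalid parameter: `tau_ip3` must be > 0", call. = FALSE)
  amp <- ifelse(drive_on, params$ip3_amp, 0)
  (amp - ip3) / params$tau_ip3
}

#' Closed-form IP3 time course under a piecewise-constant drive
#'
#' Exact solution of the linear IP3 balance equation, used as an
#' independent check on the numerical integrator.
#'
#' @param t Times, s.
#' @param train A `pulse_train`.
#' @param params Model parameters.
#' @param ip3_0 Initial IP3 at `t = 0`, uM.
#' @return IP3 concentrations at `t`, uM.
#' @export
ip3_closed_form <- function(t, train, params = iom_params(), ip3_0 = 0) {
  # breakpoints where the drive switches
  bks <- sort(unique(c(0, train$onsets, train$onsets + train$duration_d)))
  bks <- bks[bks >= 0]
  vapply(t, function(ti) {
    x <- ip3_0
    t_prev <- 0
    for (b in c(bks[bks > 0 & bks < ti], ti)) {
      on <- drive_on_at(train, (t_prev + b) / 2)
      a <- if (on) params$ip3_amp else 0
      x <- a + (x - a) * exp(-(b - t_prev) / params$tau_ip3)
      t_prev <- b
    }
    x
  }, numeric(1))
}

#' Time derivatives of the full model state
#'
#' Reference R implementation of the model right-hand side.  The
#' compiled version used by [simulate_iom()] is algebraically identical;
#' this function exists for inspection, for unit tests, and for
#' computing derivatives at single states.
#'
#' @param state Named state vector ([iom_state()]).
#' @param t Time, s (the system is autonomous except for the pulse
#'   drive).
#' @param pulse_train A `pulse_train` (or `NULL`).
#' @param params Model parameters.
#' @return Named vector of time derivatives (per second).
#' @export
iom_derivatives <- function(state, t = 0, pulse_train = NULL,
                            params = iom_params()) {
  if (anyNA(state) || any(!is.finite(state))) {
    bad <- names(state)[!is.finite(state)]
    if (!length(bad)) bad <- "unknown"
    stop("non-finite state variable: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  drive <- if (is.null(pulse_train)) FALSE else any(drive_on_at(pulse_train, t))
  iom_rhs_r(state, params, drive_on = drive)
}

# plain-R right-hand side; mirrors src/iom.c term by term
iom_rhs_r <- function(y, p, drive_on = FALSE) {
  v <- y[["v"]]; n <- y[["n"]]; ca <- y[["ca_c"]]; caer <- y[["ca_er"]]
  f6p <- y[["f6p"]]; fbp <- y[["fbp"]]; atp <- y[["atp"]]; ip3 <- y[["ip3"]]

  minf <- 1 / (1 + exp((-20 - v) / 12))
  ninf <- 1 / (1 + exp((-16 - v) / 5))
  i_ca <- p$g_cav * minf * (v - 25)
  i_k <- p$g_k * n * (v + 75)
  i_kca <- p$g_kca * ca^2 / (ca^2 + p$kd_kca^2) * (v + 75)

  adp <- max(p$a_tot - atp, 1e-9)
  mgadp <- 0.165 * adp; adp3 <- 0.135 * adp; atp4 <- 0.05 * atp
  o_katp <- (0.08 * (1 + 2 * mgadp / 17) + 0.89 * (mgadp / 17)^2) /
    ((1 + mgadp / 17)^2 * (1 + adp3 / 26 + atp4 / 1))
  i_katp <- p$g_katp * o_katp * (v + 75)

  j_mem <- -(p$alpha_ca * i_ca + p$k_pmca * ca)
  o_ip3 <- p$p_ip3r * ip3^2 / (ip3^2 + p$k_ip3^2)
  j_er <- (p$p_leak + o_ip3) * (caer - ca) - p$k_serca * ca

  amp <- adp^2 / atp
  a1 <- amp / p$k1_amp; a2 <- fbp / p$k2_fbp
  a3 <- f6p^2 / p$k3_f6p; a4 <- atp^2 / p$k4_atp
  f13 <- 0.02; f23 <- 0.2; f41 <- 20; f42 <- 20; f43 <- 20
  top <- 0; bot <- 0; w1110 <- 0
  for (i in 0:1) for (j in 0:1) for (k in 0:1) for (l in 0:1) {
    w <- a1^i * a2^j * a3^k * a4^l /
      (f13^(i * k) * f23^(j * k) * f41^(i * l) * f42^(j * l) * f43^(k * l))
    bot <- bot + w
    if (k == 1) {
      top <- top + w
      if (i == 1 && j == 1 && l == 0) w1110 <- w
    }
  }
  j_pfk <- p$v_pfk * (w1110 + p$k_pfk * (top - w1110)) / bot
  j_pdh <- p$v_pdh * (ca / (ca + p$k_pdh)) * sqrt(max(fbp, 0))

  c(v = -(i_ca + i_k + i_kca + i_katp) / p$c_m * 1000,
    n = (ninf - n) / p$tau_n,
    ca_c = p$f_ca * (j_mem + j_er),
    ca_er = -p$f_ca * p$sigma_v * j_er,
    f6p = 0.3 * (p$j_gk - j_pfk),
    fbp = j_pfk - 0.5 * j_pdh,
    atp = (adp * exp((1 + p$nu_pdh * j_pdh / (j_pdh + p$k_prod)) *
                       (1 - p$ca_atp * ca)) - atp) / p$tau_a,
    ip3 = (ifelse(drive_on, p$ip3_amp, 0) - ip3) / p$tau_ip3)
}

params_vector <- function(p) {
  c(p$g_cav, p$g_k, p$g_kca, p$g_katp, p$c_m, p$tau_n, p$kd_kca,
    p$alpha_ca, p$k_pmca, p$f_ca, p$p_leak, p$k_serca, p$sigma_v,
    p$p_ip3r, p$k_ip3, p$v_pfk, p$k_pfk, p$j_gk, p$v_pdh, p$k_pdh,
    p$nu_pdh, p$k_prod, p$ca_atp, p$tau_a, p$a_tot, p$k1_amp, p$k2_fbp,
    p$k3_f6p, p$k4_atp, p$ip3_amp, p$tau_ip3, 0)  # last slot: drive flag
}

#' Simulate the model islet
#'
#' Integrates the eight model equations with a stiff-capable adaptive
#' solver (`deSolve::lsoda` driving the compiled right-hand side).  The
#' integration is split at every pulse onset and offset so that the
#' square-wave IP3 drive switches exactly at pulse boundaries, with no
#' smoothing across them.
#'
#' @param params Model parameters ([iom_params()]).
#' @param pulse_train A `pulse_train` (use [no_pulses()] for the
#'   unstimulated condition).
#' @param t_end End of the simulation, s (> 0).
#' @param dt_out Output sampling interval, s (default 1).
#' @param initial Initial state vector, or `"default"` to start from a
#'   point on the unperturbed limit cycle (a 20-min transient is
#'   discarded; see [find_limit_cycle_state()]).
#' @param rtol,atol Solver tolerances.
#' @return A data frame of class `iom_trajectory` with columns `time_s`,
#'   `v`, `n`, `ca_c`, `ca_er`, `f6p`, `fbp`, `atp`, `ip3`.
#' @export
simulate_iom <- function(params = iom_params(), pulse_train = no_pulses(),
                         t_end, dt_out = 1, initial = "default",
                         rtol = 1e-8, atol = 1e-8) {
  stopifnot(inherits(params, "iom_params"))
  if (is.null(pulse_train)) pulse_train <- no_pulses()
  stopifnot(inherits(pulse_train, "pulse_train"))
  if (t_end <= 0) stop("`t_end` must be positive", call. = FALSE)
  if (dt_out <= 0) stop("`dt_out` must be positive", call. = FALSE)
  if (length(pulse_train$onsets) &&
      (min(pulse_train$onsets) < 0 || max(pulse_train$onsets) >= t_end))
    stop("pulse onsets must lie within [0, t_end)", call. = FALSE)

  y <- if (identical(initial, "default"))
    find_limit_cycle_state(params)
  else iom_state(initial[["v"]], initial[["n"]], initial[["ca_c"]],
                 initial[["ca_er"]], initial[["f6p"]], initial[["fbp"]],
                 initial[["atp"]], initial[["ip3"]])

  pv <- params_vector(params)
  amp_scale <- if (params$ip3_amp > 0) pulse_train$drive_amplitude / params$ip3_amp else 0

  # segment boundaries: pulse switching times
  sw <- sort(unique(c(pulse_train$onsets,
                      pulse_train$onsets + pulse_train$duration_d)))
  sw <- sw[sw > 0 & sw < t_end]
  bounds <- c(0, sw, t_end)
  grid <- seq(0, t_end, by = dt_out)

  out <- matrix(NA_real_, nrow = length(grid), ncol = 8,
                dimnames = list(NULL, state_names))
  out[1, ] <- y
  for (s in seq_len(length(bounds) - 1L)) {
    t0 <- bounds[s]; t1 <- bounds[s + 1L]
    on <- any(drive_on_at(pulse_train, (t0 + t1) / 2))
    pv[32] <- if (on) amp_scale else 0
    gsel <- grid > t0 & grid <= t1
    tt <- unique(c(t0, grid[gsel], t1))
    sol <- deSolve::lsoda(y, tt, func = "iom_derivs", parms = pv,
                          dllname = "isletsync", initfunc = "iom_initmod",
                          rtol = rtol, atol = atol, maxsteps = 500000)
    if (attr(sol, "istate")[1] < 0)
      stop("integration error near t = ",
           round(sol[nrow(sol), 1], 1), " s", call. = FALSE)
    if (anyNA(sol[nrow(sol), -1]))
      stop("integration error: non-finite state near t = ", t1, call. = FALSE)
    y <- sol[nrow(sol), -1]
    if (any(gsel)) {
      rows <- match(round(grid[gsel], 9), round(sol[, 1], 9))
      out[which(gsel), ] <- sol[rows, -1, drop = FALSE]
    }
  }
  traj <- data.frame(time_s = grid, out)
  attr(traj, "params") <- params
  attr(traj, "pulse_train") <- pulse_train
  class(traj) <- c("iom_trajectory", "data.frame")
  traj
}

#' State on the unperturbed limit cycle
#'
#' Integrates the unstimulated model from a fixed interior state and
#' discards a transient, returning the final state.  Results are cached
#' per parameter set within a session.
#'
#' @param params Model parameters.
#' @param transient_s Transient length to discard, s (default 20 min).
#' @return Named state vector on (or very near) the limit cycle.
#' @export
find_limit_cycle_state <- function(params = iom_params(), transient_s = 1200) {
  key <- paste(c(unlist(params), transient_s), collapse = "|")
  hit <- limit_cycle_cache[[key]]
  if (!is.null(hit)) return(hit)
  pv <- params_vector(params)
  y0 <- iom_state()
  sol <- deSolve::lsoda(y0, c(0, transient_s), func = "iom_derivs",
                        parms = pv, dllname = "isletsync",
                        initfunc = "iom_initmod",
                        rtol = 1e-8, atol = 1e-8, maxsteps = 2000000)
  y <- sol[nrow(sol), -1]
  names(y) <- state_names
  limit_cycle_cache[[key]] <- y
  y
}

limit_cycle_cache <- new.env(parent = emptyenv())

#' Extract the cytosolic Ca2+ trace of a trajectory
#'
#' @param traj An `iom_trajectory`.
#' @param every Keep every `every`-th sample (e.g. 20 to mimic the 20-s
#'   acquisition interval when `dt_out = 1`).
#' @return A `ca_trace`.
#' @export
ca_trace_of <- function(traj, every = 1) {
  idx <- seq(1, nrow(traj), by = every)
  ca_trace(traj$time_s[idx], traj$ca_c[idx])
}

#' Heterogeneous model islet population
#'
#' Draws `n` parameter sets whose Ca2+ and K(ATP) conductances are
#' sampled uniformly from the given ranges, reproducibly for a fixed
#' seed.  Conductance heterogeneity translates into different natural
#' oscillation periods across the population.  Each sampled set is
#' optionally verified to oscillate (at least three Ca2+ nadirs within a
#' 60-min test run).
#'
#' @param n Number of islets (>= 0).
#' @param seed Integer seed.
#' @param g_cav_range,g_katp_range Sampling ranges, pS.
#' @param method `"stratified"` (default) draws islet i from the i-th
#'   sub-interval of the Ca2+ conductance range (and the opposite
#'   stratum of the K(ATP) range), guaranteeing visibly distinct natural
#'   periods, as when model islets are constructed with deliberately
#'   different conductance pairs; `"uniform"` draws both conductances
#'   independently over the full ranges.
#' @param base Base parameter set to modify.
#' @param verify Check that every sampled set oscillates (slower).
#' @return List of `iom_params` of length `n`.
#' @export
make_heterogeneous_population <- function(n, seed = 1,
                                          g_cav_range = c(960, 1040),
                                          g_katp_range = c(49300, 50600),
                                          method = c("stratified", "uniform"),
                                          base = iom_params(),
                                          verify = FALSE) {
  if (n < 0 || n != round(n)) stop("`n` must be a non-negative integer",
                                   call. = FALSE)
  method <- match.arg(method)
  if (n == 0) return(list())
  draws <- with_preserved_seed(seed, {
    if (method == "uniform" || n == 1) {
      cbind(stats::runif(n, g_cav_range[1], g_cav_range[2]),
            stats::runif(n, g_katp_range[1], g_katp_range[2]))
    } else {
      # islet i samples stratum i of g_cav and stratum n+1-i of g_katp,
      # so the period-lengthening effects of low g_cav and high g_katp
      # compound and the population spans the period range
      edges_c <- seq(g_cav_range[1], g_cav_range[2], length.out = n + 1)
      edges_k <- seq(g_katp_range[1], g_katp_range[2], length.out = n + 1)
      i <- seq_len(n)
      cbind(stats::runif(n, edges_c[i], edges_c[i + 1]),
            stats::runif(n, rev(edges_k)[i + 1], rev(edges_k)[i]))
    }
  })
  pops <- lapply(seq_len(n), function(i) {
    p <- base
    p$g_cav <- draws[i, 1]
    p$g_katp <- draws[i, 2]
    p
  })
  if (verify) {
    for (i in seq_len(n)) {
      tr <- simulate_iom(pops[[i]], no_pulses(), t_end = 3600, dt_out = 2)
      nads <- try(detect_nadirs(ca_trace_of(tr)), silent = TRUE)
      if (inherits(nads, "try-error") || length(nads) < 3)
        stop("regime error: sampled parameter set ", i,
             " (g_CaV = ", round(draws[i, 1]), ", g_KATP = ",
             round(draws[i, 2]), ") does not oscillate", call. = FALSE)
    }
  }
  pops
}

#' Natural period of a parameter set
#'
#' Convenience helper: simulates the unperturbed model and returns the
#' mean nadir-to-nadir Ca2+ period.
#'
#' @param params Model parameters.
#' @param t_end Simulation length, s.
#' @param ... Passed to [detect_nadirs()].
#' @return Period in seconds.
#' @export
natural_period <- function(params = iom_params(), t_end = 3600, ...) {
  tr <- simulate_iom(params, no_pulses(), t_end = t_end, dt_out = 2)
  mean(diff(detect_nadirs(ca_trace_of(tr), ...)))
}

#' Write a trajectory to CSV
#'
#' Columns: `time_s`, `v`, `n`, `ca_c`, `ca_er`, `f6p`, `fbp`, `atp`,
#' `ip3`.
#'
#' @param traj An `iom_trajectory`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}

#' Write model parameters as YAML
#'
#' One YAML document per model islet.
#'
#' @param params_list A list of `iom_params` (or a single set).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_params_yaml <- function(params_list, path) {
  if (inherits(params_list, "iom_params")) params_list <- list(params_list)
  docs <- vapply(params_list, function(p) yaml::as.yaml(unclass(p)),
                 character(1))
  writeLines(paste0("---\n", paste(docs, collapse = "---\n")), path)
  invisible(path)
}

#' Initial states at staggered oscillation phases
#'
#' Prepares one initial state per model islet, each placed on its own
#' limit cycle at a chosen phase (fraction of the cycle past a Ca2+
#' nadir).  With the default evenly spread fractions this emulates a
#' group of islets observed at arbitrary, unsynchronized phases, the
#' condition under which pulse protocols are applied.
#'
#' @param pops List of `iom_params` (e.g. from
#'   [make_heterogeneous_population()]).
#' @param fractions Cycle fractions in `[0, 1)`, one per islet; default
#'   `(i - 1) / n` for islet i.
#' @param settle_s Free-running span simulated to locate each islet's
#'   nadirs, s.
#' @return List of named state vectors.
#' @export
phase_spread_states <- function(pops, fractions = NULL, settle_s = 1800) {
  n <- length(pops)
  if (is.null(fractions)) fractions <- (seq_len(n) - 1) / n
  fractions <- rep_len(fractions, n)
  lapply(seq_len(n), function(i) {
    y0 <- find_limit_cycle_state(pops[[i]])
    tr <- simulate_iom(pops[[i]], no_pulses(), t_end = settle_s,
                       dt_out = 1, initial = y0)
    nad <- detect_nadirs(ca_trace_of(tr))
    P <- mean(diff(nad))
    t_i <- nad[1] + fractions[i] * P
    y <- unlist(tr[which.min(abs(tr$time_s - t_i)), -1])
    names(y) <- state_names
    y
  })
}
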