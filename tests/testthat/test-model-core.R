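test_that("IP3 balance: rates at fixed points and parameter validation", {
  p <- iom_params()
  expect_equal(ip3_rate(0.35, TRUE, p), 0)   # steady state at the drive
  expect_equal(ip3_rate(0, FALSE, p), 0)     # zero fixed point, drive off
  expect_equal(ip3_rate(0, TRUE, p), 0.35 / 10)
  expect_equal(ip3_rate(0.1, FALSE, p), -0.1 / 10)
  expect_error(ip3_rate(-0.1, TRUE, p), "invalid parameter")
  expect_error(iom_params(tau_ip3 = 0), "> 0")
})

test_that("simulated IP3 matches the closed-form exponential to 1e-6", {
  p <- iom_params()
  train <- pulse_train(c(100, 400), duration_d = 10)
  traj <- simulate_iom(p, train, t_end = 600, dt_out = 1)

  expected <- ip3_closed_form(traj$time_s, train, p)
  expect_lt(max(abs(traj$ip3 - expected)), 1e-6)

  # 10 s of drive from zero reaches A (1 - e^-1)
  i110 <- which(traj$time_s == 110)
  expect_equal(traj$ip3[i110], 0.35 * (1 - exp(-1)), tolerance = 1e-5)

  # ip3 stays inside [0, ip3_amp]
  expect_true(all(traj$ip3 >= -1e-12 & traj$ip3 <= 0.35 + 1e-12))
})

test_that("sustained drive saturates IP3 at the pulse amplitude", {
  p <- iom_params()
  train <- pulse_train(0, duration_d = 150, drive_amplitude = p$ip3_amp)
  traj <- simulate_iom(p, train, t_end = 160, dt_out = 1)
  # after 10+ time constants the asymptote is reached
  expect_equal(traj$ip3[traj$time_s == 140], 0.35, tolerance = 1e-4)
})

test_that("R and compiled right-hand sides agree at random states", {
  p <- iom_params()
  pv <- isletsync:::params_vector(p)
  set.seed(1)
  for (i in 1:25) {
    y <- iom_state(v = runif(1, -70, -20), n = runif(1),
                   ca_c = runif(1, 0.02, 0.4), ca_er = runif(1, 50, 400),
                   f6p = runif(1, 30, 250), fbp = runif(1, 0.1, 60),
                   atp = runif(1, 1500, 2900), ip3 = runif(1, 0, 0.35))
    drv <- i %% 2 == 0
    want <- isletsync:::iom_rhs_r(y, p, drive_on = drv)
    pv[32] <- as.numeric(drv)
    got <- deSolve::lsoda(y, c(0, 1e-9), func = "iom_derivs", parms = pv,
                          dllname = "isletsync", initfunc = "iom_initmod")
    # compare the one-step increment implied by the C derivatives
    num <- (got[2, -1] - y) / 1e-9
    expect_equal(unname(num), unname(want), tolerance = 1e-4)
  }
})

test_that("derivatives reduce to the unmodified model when ip3 = 0", {
  p <- iom_params()
  y <- iom_state(ip3 = 0)
  d_off <- iom_derivatives(y, 0, NULL, p)
  # with ip3 = 0 the release flux is closed: only the ip3 equation can
  # differ between drive on and off
  train <- pulse_train(0, duration_d = 10)
  d_on <- iom_derivatives(y, 5, train, p)
  expect_equal(d_off[1:7], d_on[1:7])
  expect_equal(unname(d_off[["ip3"]]), 0)
  expect_equal(unname(d_on[["ip3"]]), 0.35 / 10)

  # zero-ip3 reduction: release term absent means the ca derivatives
  # match a model with the IP3R permeability set to 0
  p0 <- iom_params(p_ip3r = 0)
  expect_equal(iom_derivatives(y, 0, NULL, p0), d_off)
})

test_that("raising ip3 moves Ca2+ from the ER to the cytosol", {
  p <- iom_params()
  y_lo <- iom_state(ca_c = 0.1, ca_er = 200, ip3 = 0)
  y_hi <- iom_state(ca_c = 0.1, ca_er = 200, ip3 = 0.35)
  d_lo <- iom_derivatives(y_lo, 0, NULL, p)
  d_hi <- iom_derivatives(y_hi, 0, NULL, p)
  expect_gt(d_hi[["ca_c"]], d_lo[["ca_c"]])
  expect_lt(d_hi[["ca_er"]], d_lo[["ca_er"]])
})

test_that("non-finite states are reported with the offending field", {
  expect_error(iom_derivatives(c(v = NaN, n = 0.1, ca_c = 0.1, ca_er = 100,
                                 f6p = 100, fbp = 10, atp = 2000, ip3 = 0)),
               "non-finite state variable: v")
})

test_that("ER calcium falls over a pulse when the gradient is outward", {
  p <- iom_params()
  y0 <- find_limit_cycle_state(p)
  tp <- 120
  train <- pulse_train(tp, duration_d = 10)
  traj <- simulate_iom(p, train, t_end = 200, dt_out = 1, initial = y0)
  i_on <- which(traj$time_s == tp)
  i_off <- which(traj$time_s == tp + 10)
  if (traj$ca_er[i_on] > traj$ca_c[i_on]) {
    expect_lt(traj$ca_er[i_off], traj$ca_er[i_on])
  }
})

test_that("a zero-amplitude train reproduces the unperturbed trajectory", {
  p <- iom_params()
  y0 <- find_limit_cycle_state(p)
  base <- simulate_iom(p, no_pulses(), t_end = 900, dt_out = 1, initial = y0)
  null_train <- pulse_train(c(100, 300), duration_d = 10,
                            drive_amplitude = 0)
  same <- simulate_iom(p, null_train, t_end = 900, dt_out = 1, initial = y0)
  # segment restarts at the (null) pulse boundaries perturb the solver's
  # step sequence; agreement is at solver-tolerance level, not bitwise
  expect_equal(same$ca_c, base$ca_c, tolerance = 1e-4)
  expect_equal(same$atp, base$atp, tolerance = 1e-4)
})

test_that("population sampling is reproducible and heterogeneous", {
  pops1 <- make_heterogeneous_population(3, seed = 4)
  pops2 <- make_heterogeneous_population(3, seed = 4)
  expect_identical(pops1, pops2)
  expect_equal(length(make_heterogeneous_population(0)), 0)
  g <- vapply(pops1, `[[`, numeric(1), "g_cav")
  expect_equal(length(unique(g)), 3)
  r <- vapply(pops1, `[[`, numeric(1), "g_katp")
  expect_true(all(r >= 49300 & r <= 50600))
})

test_that("invalid simulation arguments error early", {
  expect_error(simulate_iom(iom_params(), no_pulses(), t_end = -5), "positive")
  expect_error(simulate_iom(iom_params(), pulse_train(500), t_end = 400),
               "within")
})
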