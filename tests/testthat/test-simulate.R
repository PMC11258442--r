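test_that("steady flow at each step converges to the pressure-flow law", {
  # linear eye: Q = C P, terminal flow at the commanded-9-mmHg step is C*9
  # minus the small series-resistance drop handled via the sampled IOP
  p_lin <- true_eye_params(Cr = 5, beta = 0, phir = 80, gamma = 5)
  tr <- simulate_perfusion_trace(p_lin, quick_protocol(), noise_model(0, 0))
  last_of_step <- function(tr, k) {
    idx <- which(tr$step_index == k)
    idx[length(idx)]
  }
  i9 <- last_of_step(tr, 4)  # commanded 9 mmHg
  expect_equal(tr$flow_nl_min[i9], 5 * tr$pressure_mmHg[i9], tolerance = 1e-6)
  expect_equal(tr$flow_nl_min[i9], 45, tolerance = 0.01)

  # nonlinear eye at the reference pressure: power term is 1, Q = Cr * P
  p_nl <- true_eye_params(Cr = 4, beta = 0.5, phir = 80, gamma = 5)
  proto8 <- perfusion_protocol(step_pressures = c(6, 8, 10),
                               step_duration = 150)
  tr2 <- simulate_perfusion_trace(p_nl, proto8, noise_model(0, 0))
  i8 <- last_of_step(tr2, 2)
  P8 <- tr2$pressure_mmHg[i8]
  expect_equal(tr2$flow_nl_min[i8], 4 * (P8 / 8)^0.5 * P8, tolerance = 1e-6)
  expect_equal(tr2$flow_nl_min[i8], 32, tolerance = 0.05)

  # every step's terminal flow matches the power law at the terminal IOP
  p <- true_eye_params(Cr = 6, beta = 0.8, phir = 60, gamma = 8)
  tr3 <- simulate_perfusion_trace(p, quick_protocol(), noise_model(0, 0))
  for (k in seq_len(9)) {
    i <- last_of_step(tr3, k)
    P <- tr3$pressure_mmHg[i]
    expect_equal(tr3$flow_nl_min[i], 6 * (P / 8)^0.8 * P, tolerance = 1e-3)
  }
})

test_that("simulated traces conserve volume", {
  for (beta in c(0, 0.5)) {
    p <- true_eye_params(Cr = 5, beta = beta, phir = 80, gamma = 5)
    tr <- simulate_perfusion_trace(p, quick_protocol(), noise_model(0, 0))
    expect_lt(mass_balance_error(tr), 1e-3)
  }
})

test_that("traces are bit-reproducible under a fixed seed", {
  p <- true_eye_params()
  proto <- perfusion_protocol(step_pressures = c(6, 9, 12), step_duration = 120)
  tr1 <- simulate_perfusion_trace(p, proto, noise_model(0.05, 0.05, seed = 42))
  tr2 <- simulate_perfusion_trace(p, proto, noise_model(0.05, 0.05, seed = 42))
  expect_identical(tr1$flow_nl_min, tr2$flow_nl_min)
  expect_identical(tr1$pressure_mmHg, tr2$pressure_mmHg)
})

test_that("step transients decay with the linearized time constant", {
  # tau = phi(P) / (1/R + dQ_out/dP), with flow in nL/min and time in min
  p <- true_eye_params(Cr = 5, beta = 0, phir = 80, gamma = 1e6)
  r_sys <- 0.001
  proto <- perfusion_protocol(step_pressures = c(9, 12), step_duration = 150)
  tr <- simulate_perfusion_trace(p, proto, noise_model(0, 0), r_sys = r_sys)
  idx <- which(tr$step_index == 2)
  P <- tr$pressure_mmHg[idx]
  p_inf <- P[length(P)]
  # fit log|P - P_inf| over the first portion of the decay
  sel <- 2:30
  dev <- abs(P[sel] - p_inf)
  keep <- dev > 1e-6
  fit <- stats::lm(log(dev[keep]) ~ tr$time_s[idx][sel][keep])
  tau_obs <- -1 / coef(fit)[2]
  phi_mid <- 80 * (13 + 1e6) / ((p_inf + 9) / 2 + 1e6)
  tau_pred <- 60 * phi_mid / (1 / r_sys + 5)
  expect_equal(unname(tau_obs), tau_pred, tolerance = 0.1)
})

test_that("simulator rejects invalid inputs", {
  expect_error(perfusion_protocol(step_pressures = c(-1, 9)), "positive")
  p <- true_eye_params(gamma = -3)
  expect_error(
    simulate_perfusion_trace(p, perfusion_protocol(step_pressures = c(2, 9),
                                                   step_duration = 60),
                             noise_model(0, 0)),
    "gamma")
})
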