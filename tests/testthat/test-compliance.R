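test_that("step-response estimates recover a constant compliance", {
  # gamma very large: phi(P) ~ phir, the eye is a linear capacitor
  p <- true_eye_params(Cr = 5, beta = 0, phir = 70, gamma = 1e5)
  tr <- simulate_perfusion_trace(p, perfusion_protocol(), noise_model(0, 0))
  pts <- extract_stable_points(tr)
  fac <- fit_facility(pts)
  phi <- estimate_compliance_points(tr, pts, fac)
  truth <- 70 * (13 + 1e5) / (phi$pressure_mmHg + 1e5)
  expect_equal(phi$phi_nl_mmHg, truth, tolerance = 0.05)
  expect_true(all(phi$flag == "ok"))
})

test_that("a near-zero-compliance eye stores almost no volume", {
  # phir 0.5 nL/mmHg; r_sys chosen so the (very fast) transient is still
  # resolved by the sampling grid
  p <- true_eye_params(Cr = 5, beta = 0, phir = 0.5, gamma = 1e5)
  proto <- perfusion_protocol(sampling_interval = 0.5)
  tr <- simulate_perfusion_trace(p, proto, noise_model(0, 0), r_sys = 0.05)
  pts <- extract_stable_points(tr)
  fac <- fit_facility(pts)
  phi <- estimate_compliance_points(tr, pts, fac)
  expect_lt(max(abs(phi$excess_volume_nl)), 2)
  expect_equal(phi$phi_nl_mmHg, rep(0.5, nrow(phi)), tolerance = 0.15)
})

test_that("the phi estimate is linear in the true compliance", {
  est_phi <- function(phir) {
    p <- true_eye_params(Cr = 5, beta = 0.3, phir = phir, gamma = 1e5)
    tr <- simulate_perfusion_trace(p, perfusion_protocol(), noise_model(0, 0))
    pts <- extract_stable_points(tr)
    phi <- estimate_compliance_points(tr, pts, fit_facility(pts))
    mean(phi$phi_nl_mmHg)
  }
  expect_equal(est_phi(120) / est_phi(60), 2, tolerance = 0.05)
})

test_that("pressure-dependent compliance points are refit exactly", {
  P <- c(6, 9, 12, 15, 18)
  pts <- data.frame(pressure_mmHg = P, phi_nl_mmHg = 60 * (13 + 5) / (P + 5))
  fit <- fit_reference_compliance(pts)
  expect_equal(fit$phir, 60, tolerance = 1e-4)
  expect_equal(fit$gamma, 5, tolerance = 1e-3)
  expect_equal(fit$gamma_flag, "ok")
  # at P = Pr_phi the fitted curve returns exactly phir
  expect_equal(predict_compliance(fit, 13), fit$phir, tolerance = 1e-10)

  oracle <- compliance_grid_oracle(pts)
  expect_equal(fit$phir, oracle$phir, tolerance = 0.01)
})

test_that("constant compliance pins gamma at its bound and is flagged", {
  P <- c(6, 9, 12, 15, 18)
  pts <- data.frame(pressure_mmHg = P, phi_nl_mmHg = rep(60, 5))
  fit <- fit_reference_compliance(pts)
  expect_equal(fit$phir, 60, tolerance = 0.01)
  expect_equal(fit$gamma_flag, "unidentifiable")
})

test_that("compliance fit enforces its preconditions", {
  expect_error(fit_reference_compliance(
    data.frame(pressure_mmHg = c(6, 9), phi_nl_mmHg = c(80, 70))), "at least 3")
  expect_error(fit_reference_compliance(
    data.frame(pressure_mmHg = c(6, 7, 8), phi_nl_mmHg = c(80, 75, 70))),
    "5 mmHg")
  # rows flagged as negative excess volume are excluded
  P <- c(6, 9, 12, 15, 18, 21)
  pts <- data.frame(pressure_mmHg = P,
                    phi_nl_mmHg = c(60 * 18 / (P[-6] + 5), -10),
                    flag = c(rep("ok", 5), "negative_vx"))
  fit <- fit_reference_compliance(pts)
  expect_equal(fit$n_points, 5)
  expect_equal(fit$phir, 60, tolerance = 1e-3)
})

test_that("small pressure steps are flagged unreliable", {
  p <- true_eye_params(Cr = 5, beta = 0, phir = 80, gamma = 5)
  proto <- perfusion_protocol(step_pressures = c(9, 9.2, 12),
                              step_duration = 360)
  tr <- simulate_perfusion_trace(p, proto, noise_model(0, 0))
  pts <- extract_stable_points(tr)
  fac <- fit_facility(pts)
  phi2 <- estimate_step_compliance(tr, pts, 2, fac)
  expect_equal(phi2$flag, "small_dp")
})
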