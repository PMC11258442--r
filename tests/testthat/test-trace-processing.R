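test_that("Savitzky-Golay filter reproduces constants and lines, smooths noise", {
  x <- rep(7.3, 300)
  expect_equal(sg_filter(x, dt = 1), x)

  line <- 0.2 * (1:300) + 5
  expect_equal(sg_filter(line, dt = 1), line, tolerance = 1e-10)

  set.seed(11)
  noisy <- 100 * (1 + rnorm(600, sd = 0.05))
  expect_lt(sd(sg_filter(noisy, dt = 1)), sd(noisy))

  expect_error(sg_filter(1:10, dt = 1, window = 60), "shorter")
})

make_flat_trace <- function(flow, duration = 300, dt = 1, pressure = 9) {
  n <- round(duration / dt)
  t <- (0:(n - 1)) * dt
  tr <- data.frame(time_s = t, pressure_mmHg = rep(pressure, n),
                   flow_nl_min = flow, step_index = rep(1L, n))
  attr(tr, "steps") <- data.frame(step_index = 1L, commanded_mmHg = pressure,
                                  start_s = 0, end_s = duration)
  attr(tr, "sampling_interval") <- dt
  class(tr) <- c("perfusion_trace", "data.frame")
  tr
}

test_that("stability detection separates flat, slow-ramp and fast-ramp steps", {
  n <- 300
  flat <- make_flat_trace(rep(45, n))
  v <- detect_stability(flat)
  expect_true(v$stable)
  expect_equal(v$first_stable_s, 0)   # stable from the earliest window

  # 5 nL/min per min ramp: always above the 3 nL/min/min threshold
  fast <- make_flat_trace(45 + 5 / 60 * (0:(n - 1)))
  expect_false(detect_stability(fast)$stable)

  # 1 nL/min per min ramp: below threshold throughout
  slow <- make_flat_trace(45 + 1 / 60 * (0:(n - 1)))
  expect_true(detect_stability(slow)$stable)

  # a ramp exactly at threshold counts as unstable (strict inequality)
  tied <- make_flat_trace(45 + 3 / 60 * (0:(n - 1)))
  expect_false(detect_stability(tied)$stable)

  # short step: indeterminate, not an error
  short <- make_flat_trace(rep(45, 100), duration = 100)
  v <- detect_stability(short)
  expect_false(v$stable)
  expect_true(v$indeterminate)
})

test_that("stability verdicts are monotone in the slope threshold", {
  set.seed(7)
  p <- true_eye_params(Cr = 5, beta = 0.3, phir = 80, gamma = 5)
  tr <- simulate_perfusion_trace(p, quick_protocol(),
                                 noise_model(0.05, 0.05, seed = 3))
  v_tight <- detect_stability(tr, slope_threshold = 1.5)
  v_loose <- detect_stability(tr, slope_threshold = 6)
  expect_true(all(v_loose$stable[v_tight$stable]))
})

test_that("stable points reproduce the pressure-flow law on noise-free traces", {
  p <- true_eye_params(Cr = 5, beta = 0, phir = 80, gamma = 5)
  tr <- simulate_perfusion_trace(p, perfusion_protocol(), noise_model(0, 0))
  pts <- extract_stable_points(tr)
  expect_equal(nrow(pts), 9)
  expect_equal(pts$flow_nl_min, 5 * pts$pressure_mmHg, tolerance = 2e-3)
  # filtering + averaging is exact on settled constants
  expect_lt(max(pts$flow_sd), 1e-2)
})

test_that("unstable or late-stabilizing steps are dropped with a warning", {
  n <- 300
  ramp <- make_flat_trace(45 + 5 / 60 * (0:(n - 1)))
  expect_warning(pts <- extract_stable_points(ramp), "no stable steps")
  expect_equal(nrow(pts), 0)
  expect_true(isTRUE(attr(pts, "unfittable")))

  # averaging window longer than the post-stability residue: dropped
  flat <- make_flat_trace(rep(45, n))
  v <- detect_stability(flat)
  v$first_stable_s <- 200  # pretend stability began late
  w <- capture_warnings(pts2 <- extract_stable_points(flat, v, averaging = 240))
  expect_match(w, "averaging window", all = FALSE)
  expect_equal(nrow(pts2), 0)
})

test_that("stable point count never exceeds the number of protocol steps", {
  p <- true_eye_params()
  tr <- simulate_perfusion_trace(p, quick_protocol(),
                                 noise_model(0.05, 0.05, seed = 5))
  pts <- suppressWarnings(extract_stable_points(tr, averaging = 60))
  expect_lte(nrow(pts), 9)
})
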