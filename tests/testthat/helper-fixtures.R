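# Shared fixtures: small, fast configurations used across the test files.

# nine-step protocol with short steps for speed in unit tests; the default
# 360-s protocol is used where timing realism matters
quick_protocol <- function(step_duration = 150) {
  perfusion_protocol(step_duration = step_duration)
}

quick_config <- function(...) {
  run_config(averaging = 60, ...)
}

# noise-free steady-state points generated directly from the power law
powerlaw_points <- function(Cr, beta, Pr_C = 8,
                            P = c(4.5, 6, 7.5, 9, 10.5, 12, 15, 18, 21)) {
  data.frame(pressure_mmHg = P, flow_nl_min = Cr * (P / Pr_C)^beta * P)
}

# brute-force oracle: grid search over (log Cr, beta) minimizing squared
# log-flow residuals; independent of the regression-based estimator
facility_grid_oracle <- function(points, Pr_C = 8,
                                 logCr_range = log(c(0.5, 50)),
                                 beta_range = c(-1, 2), n_grid = 401) {
  lg <- seq(logCr_range[1], logCr_range[2], length.out = n_grid)
  bb <- seq(beta_range[1], beta_range[2], length.out = n_grid)
  x <- log(points$pressure_mmHg / Pr_C)
  y <- log(points$flow_nl_min / points$pressure_mmHg)
  # SSE(lg, b) = sum over points of (y - lg - b x)^2; for fixed b this is
  # quadratic in lg, so the whole lg grid is evaluated in closed form
  np <- length(y)
  best <- c(NA, NA); best_sse <- Inf
  for (b in bb) {
    r <- y - b * x
    sse <- sum(r^2) - 2 * lg * sum(r) + np * lg^2
    i <- which.min(sse)
    if (sse[i] < best_sse) {
      best_sse <- sse[i]
      best <- c(lg[i], b)
    }
  }
  list(Cr = exp(best[1]), beta = best[2],
       resolution = c(Cr_rel = diff(logCr_range) / (n_grid - 1),
                      beta = diff(beta_range) / (n_grid - 1)))
}

# brute-force oracle for the compliance-pressure model
compliance_grid_oracle <- function(phi_points, Pr_phi = 13,
                                   phir_range = NULL, gamma_range = c(0.5, 50),
                                   n_grid = 301) {
  P <- phi_points$pressure_mmHg
  phi <- phi_points$phi_nl_mmHg
  if (is.null(phir_range)) phir_range <- range(phi) * c(0.5, 2)
  pr <- seq(phir_range[1], phir_range[2], length.out = n_grid)
  gg <- seq(gamma_range[1], gamma_range[2], length.out = n_grid)
  best <- c(NA, NA); best_sse <- Inf
  for (g in gg) {
    shape <- (Pr_phi + g) / (P + g)
    # optimal phir for this gamma in closed form, then snap to grid
    opt <- sum(phi * shape) / sum(shape^2)
    for (p0 in c(pr[which.min(abs(pr - opt))], opt)) {
      sse <- sum((phi - p0 * shape)^2)
      if (sse < best_sse) { best_sse <- sse; best <- c(p0, g) }
    }
  }
  list(phir = best[1], gamma = best[2])
}
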