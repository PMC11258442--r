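#' Step-response estimate of ocular compliance at one pressure step
#'
#' During a pressure step the eye stores (or releases) volume; the excess of
#' injected volume over the volume drained through the outflow pathway equals
#' the stored-volume change. Integrating the measured flow minus the
#' model-predicted outflow over the step gives the excess volume
#' \eqn{V_x = \int (Q(t) - Q_{out}(P(t)))\,dt}, and
#' \eqn{\hat\phi = V_x / \Delta P}, assigned to the midpoint pressure of the
#' step, estimates the compliance there. \eqn{\Delta P} is the steady
#' pressure change between the step and its predecessor.
#'
#' @param trace A `perfusion_trace`.
#' @param points `stable_points` for the trace (both the step and its
#'   predecessor must have stable points).
#' @param step_index Index of the step whose transient is integrated.
#' @param facility A `facility_fit` supplying the outflow model.
#' @return A one-row data frame: `step_index`, `pressure_mmHg` (midpoint),
#'   `phi_nl_mmHg`, `delta_p_mmHg`, `excess_volume_nl`, `flag`
#'   (`"ok"`, `"small_dp"` when |dP| < 0.5 mmHg, or `"negative_vx"`).
#' @export
estimate_step_compliance <- function(trace, points, step_index, facility) {
  stopifnot(inherits(trace, "perfusion_trace"), inherits(facility, "facility_fit"))
  steps <- attr(trace, "steps")
  cur <- points[points$step_index == step_index, ]
  prev <- points[points$step_index == step_index - 1, ]
  if (nrow(cur) != 1 || nrow(prev) != 1)
    stop(sprintf("step %d: both the step and its predecessor must be stable",
                 step_index))
  idx <- which(trace$step_index == step_index)
  t <- trace$time_s[idx]
  q_meas <- trace$flow_nl_min[idx]
  p_meas <- trace$pressure_mmHg[idx]
  q_out <- predict_flow(facility, pmax(p_meas, 1e-6))
  vx <- trapz(t / 60, q_meas - q_out)        # nL (flow in nL/min, time in min)
  dp <- cur$pressure_mmHg - prev$pressure_mmHg
  phi <- vx / dp
  flag <- "ok"
  if (abs(dp) < 0.5) flag <- "small_dp"
  else if (phi < 0) flag <- "negative_vx"
  data.frame(step_index = step_index,
             pressure_mmHg = (cur$pressure_mmHg + prev$pressure_mmHg) / 2,
             phi_nl_mmHg = phi,
             delta_p_mmHg = dp,
             excess_volume_nl = vx,
             flag = flag)
}

# trapezoidal rule on possibly non-uniform grid
trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

#' Per-step compliance estimates for a whole trace
#'
#' Applies [estimate_step_compliance()] to every step whose predecessor also
#' produced a stable point (the first step has no recorded predecessor and is
#' skipped).
#'
#' @inheritParams estimate_step_compliance
#' @return A data frame of per-step compliance estimates (possibly flagged).
#' @export
estimate_compliance_points <- function(trace, points, facility) {
  usable <- intersect(points$step_index, points$step_index + 1)
  out <- lapply(usable, function(k)
    estimate_step_compliance(trace, points, k, facility))
  do.call(rbind, out)
}

#' Fit the compliance-pressure model to per-step estimates
#'
#' Nonlinear least squares of
#' \deqn{\phi(P) = \phi_r (P_{r,\phi} + \gamma)/(P + \gamma)}
#' for the reference compliance \eqn{\phi_r} and shape parameter
#' \eqn{\gamma}. Because the model is ill-conditioned when \eqn{\gamma} is
#' large, the optimizer is multi-started from gamma = 1, 10 and 100 with
#' gamma bounded to (-min(P) + 0.1, 1000) mmHg; a gamma pinned at a bound is
#' flagged as unidentifiable (the large-gamma limit is a constant
#' compliance). The 95% CI for \eqn{\phi_r} is formed in the log domain
#' (compliance is log-normally distributed) via the delta method on the fit
#' covariance.
#'
#' @param phi_points Data frame with columns `pressure_mmHg` and
#'   `phi_nl_mmHg`; rows flagged `"negative_vx"` in a `flag` column are
#'   excluded.
#' @param Pr_phi Reference pressure, mmHg (default 13, consistent with
#'   earlier compliance studies).
#' @param conf_level Confidence level (default 0.95).
#' @return An object of class `compliance_fit`: `phir`, `gamma`, `Pr_phi`,
#'   `CI_phir`, `se_log_phir`, `gamma_flag` (`"ok"` or `"unidentifiable"`),
#'   `phi_points`, `n_points`.
#' @examples
#' P <- c(6, 9, 12, 15, 18)
#' phi <- 60 * (13 + 5) / (P + 5)
#' fit_reference_compliance(data.frame(pressure_mmHg = P, phi_nl_mmHg = phi))
#' @export
fit_reference_compliance <- function(phi_points, Pr_phi = 13, conf_level = 0.95) {
  stopifnot(is.data.frame(phi_points), Pr_phi > 0)
  if (!is.null(phi_points$flag))
    phi_points <- phi_points[phi_points$flag != "negative_vx", ]
  P <- phi_points$pressure_mmHg
  phi <- phi_points$phi_nl_mmHg
  if (length(P) < 3)
    stop("compliance fit requires at least 3 per-step estimates")
  if (max(P) - min(P) < 5)
    stop("compliance fit requires points spanning at least 5 mmHg")
  if (any(phi <= 0))
    stop("non-positive compliance estimates cannot be fit (filter flagged steps)")

  lower_gamma <- -min(P) + 0.1
  upper_gamma <- 1000
  dat <- data.frame(P = P, phi = phi)
  best <- NULL
  for (g0 in c(1, 10, 100)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        phi ~ phir * (Pr_phi + gamma) / (P + gamma),
        data = dat,
        start = list(phir = stats::median(phi), gamma = g0),
        lower = c(phir = 1e-9, gamma = lower_gamma),
        upper = c(phir = Inf, gamma = upper_gamma),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::resid(fit)^2)
      if (is.null(best) || rss < best$rss - 1e-12) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best))
    stop("compliance fit failed to converge from all starting values")
  fit <- best$fit
  cf <- stats::coef(fit)
  phir <- unname(cf["phir"])
  gam <- unname(cf["gamma"])
  gamma_flag <- if (gam >= upper_gamma - 1e-6 || gam <= lower_gamma + 1e-6)
    "unidentifiable" else "ok"

  # delta-method SE of log(phir) from the fit covariance
  se_phir <- tryCatch(summary(fit)$coefficients["phir", "Std. Error"],
                      error = function(e) NA_real_)
  se_log <- if (is.finite(se_phir)) se_phir / phir else NA_real_
  df <- length(P) - 2
  tq <- stats::qt(1 - (1 - conf_level) / 2, df)
  ci <- if (is.finite(se_log)) phir * exp(c(-1, 1) * tq * se_log)
        else c(NA_real_, NA_real_)

  structure(list(phir = phir, gamma = gam, Pr_phi = Pr_phi,
                 CI_phir = ci, se_log_phir = se_log,
                 gamma_flag = gamma_flag,
                 phi_points = phi_points, n_points = length(P),
                 conf_level = conf_level),
            class = "compliance_fit")
}

#' @export
print.compliance_fit <- function(x, ...) {
  cat(sprintf("Ocular compliance fit (n = %d, Pr_phi = %g mmHg)\n",
              x$n_points, x$Pr_phi))
  cat(sprintf("  phir  = %.2f nL/mmHg  [%.2f, %.2f]\n",
              x$phir, x$CI_phir[1], x$CI_phir[2]))
  cat(sprintf("  gamma = %.2f mmHg%s\n", x$gamma,
              if (x$gamma_flag != "ok") "  (unidentifiable)" else ""))
  invisible(x)
}

#' Predicted compliance at a given pressure
#'
#' @param fit A `compliance_fit` (or list with `phir`, `gamma`, `Pr_phi`).
#' @param P Pressure(s), mmHg.
#' @return Compliance, nL/mmHg.
#' @export
predict_compliance <- function(fit, P) {
  if (any(P + fit$gamma <= 0)) stop("P + gamma must be positive")
  fit$phir * (fit$Pr_phi + fit$gamma) / (P + fit$gamma)
}
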