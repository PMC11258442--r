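#' Fit the power-law pressure-flow model to steady-state points
#'
#' Estimates the reference outflow facility \eqn{C_r} and nonlinearity factor
#' \eqn{\beta} of the model
#' \deqn{Q = C_r (P/P_{r,C})^\beta P}
#' from steady-state (P, Q) pairs. Because facility errors are multiplicative
#' (log-normal), the fit is performed in the logarithmic domain, where the
#' model is exactly linear: regressing \eqn{y = \ln(Q/P)} on
#' \eqn{x = \ln(P/P_{r,C})} gives intercept \eqn{\ln C_r} and slope
#' \eqn{\beta}. 95% confidence intervals come from the t-based standard
#' errors of this regression, exponentiated for \eqn{C_r}.
#'
#' @param points A `stable_points` data frame (columns `pressure_mmHg`,
#'   `flow_nl_min`), or any data frame with those columns.
#' @param Pr_C Reference pressure, mmHg (default 8, a physiological pressure
#'   drop across the conventional outflow pathway).
#' @param conf_level Confidence level for the intervals (default 0.95).
#' @return An object of class `facility_fit` with elements `Cr`, `beta`,
#'   `Pr_C`, `CI_Cr`, `CI_beta`, `se_log_Cr`, `se_beta`, `sigma` (residual SD
#'   of log flow), `r_squared`, `n_points`.
#' @examples
#' P <- c(4.5, 6, 7.5, 9, 10.5, 12, 15, 18, 21)
#' Q <- 5 * (P / 8)^0.4 * P
#' fit_facility(data.frame(pressure_mmHg = P, flow_nl_min = Q))
#' @export
fit_facility <- function(points, Pr_C = 8, conf_level = 0.95) {
  stopifnot(is.data.frame(points), Pr_C > 0)
  P <- points$pressure_mmHg
  Q <- points$flow_nl_min
  if (length(P) < 3)
    stop("facility fit requires at least 3 steady-state points")
  if (any(P <= 0))
    stop("pressures must be positive")
  if (any(Q <= 0))
    stop("flows must be positive for the log-domain fit")
  x <- log(P / Pr_C)
  if (max(x) - min(x) < sqrt(.Machine$double.eps))
    stop("singular fit: pressures do not span a range")
  y <- log(Q / P)
  fit <- stats::lm(y ~ x)
  cf <- stats::coef(fit)
  # noise-free inputs give an exact fit; the "perfect fit" warning from
  # summary.lm is expected there and carries no information
  ci <- suppressWarnings(stats::confint(fit, level = conf_level))
  sm <- suppressWarnings(summary(fit))
  structure(list(
    Cr = exp(unname(cf[1])),
    beta = unname(cf[2]),
    Pr_C = Pr_C,
    CI_Cr = exp(unname(ci[1, ])),
    CI_beta = unname(ci[2, ]),
    se_log_Cr = sm$coefficients[1, 2],
    se_beta = sm$coefficients[2, 2],
    sigma = sm$sigma,
    r_squared = sm$r.squared,
    n_points = length(P),
    conf_level = conf_level
  ), class = "facility_fit")
}

#' @export
print.facility_fit <- function(x, ...) {
  cat(sprintf("Outflow facility fit (n = %d, Pr_C = %g mmHg)\n",
              x$n_points, x$Pr_C))
  cat(sprintf("  Cr   = %.3f nL/min/mmHg  [%.3f, %.3f]\n",
              x$Cr, x$CI_Cr[1], x$CI_Cr[2]))
  cat(sprintf("  beta = %.3f             [%.3f, %.3f]\n",
              x$beta, x$CI_beta[1], x$CI_beta[2]))
  invisible(x)
}

#' Predicted steady outflow at a given pressure
#'
#' Evaluates the fitted power-law model \eqn{Q = C_r (P/P_{r,C})^\beta P}.
#'
#' @param fit A `facility_fit`, or a list with elements `Cr`, `beta`, `Pr_C`.
#' @param P Pressure(s), mmHg; must be positive.
#' @return Predicted flow(s), nL/min.
#' @examples
#' predict_flow(list(Cr = 4, beta = 0.5, Pr_C = 8), 8)  # 32
#' @export
predict_flow <- function(fit, P) {
  if (any(P <= 0)) stop("pressure must be positive")
  fit$Cr * (P / fit$Pr_C)^fit$beta * P
}
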