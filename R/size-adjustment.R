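#' Fit the ocular diameter vs age growth model
#'
#' Eye size in mice grows quickly early in life and slowly thereafter; the
#' empirical model \eqn{d = a_1\,\mathrm{Age}^{a_2} + a_3} captures this.
#' Fitted by nonlinear least squares with multi-start on the exponent
#' (\eqn{a_2 \in \{0.1, 0.3, 0.5, 1\}}). A near-constant diameter gives a
#' degenerate fit (\eqn{a_1 \approx 0}), which is flagged rather than
#' rejected.
#'
#' @param ages Ages, months.
#' @param diameters Measured diameters, mm.
#' @return An object of class `diameter_model`: `a1` (mm/month^a2), `a2`,
#'   `a3` (mm), `r_squared`, `sigma` (residual SD, mm), `age_range`,
#'   `degenerate` flag.
#' @export
fit_diameter_model <- function(ages, diameters) {
  stopifnot(length(ages) == length(diameters))
  if (length(ages) < 4)
    stop("diameter model requires at least 4 (age, diameter) pairs")
  if (diff(range(ages)) < 6)
    stop("diameter model requires ages spanning at least 6 months")
  dat <- data.frame(age = ages, d = diameters)
  if (stats::sd(diameters) < sqrt(.Machine$double.eps)) {
    # constant diameters: degenerate flat model
    return(structure(list(a1 = 0, a2 = 1, a3 = mean(diameters),
                          r_squared = NA_real_, sigma = 0,
                          age_range = range(ages), degenerate = TRUE),
                     class = "diameter_model"))
  }
  best <- NULL
  for (a2_0 in c(0.1, 0.3, 0.5, 1)) {
    a1_0 <- (max(diameters) - min(diameters)) /
      max(max(ages)^a2_0 - min(ages)^a2_0, 1e-6)
    fit <- tryCatch(
      minpack.lm::nlsLM(d ~ a1 * age^a2 + a3, data = dat,
                        start = list(a1 = max(a1_0, 1e-3), a2 = a2_0,
                                     a3 = min(diameters)),
                        lower = c(a1 = 0, a2 = 1e-3, a3 = 0),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::resid(fit)^2)
      if (is.null(best) || rss < best$rss - 1e-12) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best))
    stop("diameter model failed to converge from all starting values")
  cf <- stats::coef(best$fit)
  tss <- sum((diameters - mean(diameters))^2)
  structure(list(a1 = unname(cf["a1"]), a2 = unname(cf["a2"]),
                 a3 = unname(cf["a3"]),
                 r_squared = 1 - best$rss / tss,
                 sigma = sqrt(best$rss / max(length(ages) - 3, 1)),
                 age_range = range(ages),
                 degenerate = unname(cf["a1"]) < 1e-6),
            class = "diameter_model")
}

#' @export
print.diameter_model <- function(x, ...) {
  cat(sprintf("Diameter model: d = %.4f * age^%.4f + %.4f mm (R^2 = %.3f)%s\n",
              x$a1, x$a2, x$a3, x$r_squared,
              if (x$degenerate) "  [degenerate: a1 ~ 0]" else ""))
  invisible(x)
}

#' Impute an ocular diameter from the growth model
#'
#' Used for eyes whose aqueous humor dynamics were measured but whose
#' diameter was not. Ages outside the fitted range are allowed but flagged
#' with a warning (extrapolation).
#'
#' @param model A `diameter_model`.
#' @param age Age(s), months (non-negative).
#' @return Predicted diameter(s), mm.
#' @examples
#' m <- structure(list(a1 = 0.5, a2 = 0.25, a3 = 2.5, age_range = c(2, 32)),
#'                class = "diameter_model")
#' impute_diameter(m, 16)  # 3.5
#' @export
impute_diameter <- function(model, age) {
  stopifnot(inherits(model, "diameter_model"))
  if (any(age < 0)) stop("age must be non-negative")
  if (!is.null(model$age_range) &&
      any(age < model$age_range[1] | age > model$age_range[2]))
    warning("imputing diameter outside the fitted age range (extrapolation)")
  model$a1 * age^model$a2 + model$a3
}

#' Adjust outflow facility to a common eye size
#'
#' Facility scales with the filtering area of Schlemm's canal's inner wall,
#' which tracks the globe circumference, hence linearly with diameter. The
#' adjusted reference facility of eye i with diameter d is
#' \eqn{C_{r}^{a} = C_r\,\bar d / d}: the facility the eye would have at the
#' cohort reference diameter \eqn{\bar d}. Confidence bounds are transformed
#' by the same deterministic factor (diameter is treated as known).
#'
#' @param Cr Facility (nL/min/mmHg); may be a vector.
#' @param d Eye diameter, mm.
#' @param dbar Reference diameter, mm (default 3.4, the cohort average).
#' @return Adjusted facility, same units.
#' @examples
#' adjust_facility(4, d = 1.7)  # 8
#' @export
adjust_facility <- function(Cr, d, dbar = 3.4) {
  if (any(d <= 0) || any(dbar <= 0)) stop("diameters must be positive")
  Cr * dbar / d
}

#' Adjust ocular compliance to a common eye size
#'
#' Compliance scales with ocular volume (\eqn{\pi d^3/6}), hence cubically
#' with diameter: \eqn{\phi_r^{a} = \phi_r (\bar d/d)^3}.
#'
#' @param phir Compliance (nL/mmHg); may be a vector.
#' @param d Eye diameter, mm.
#' @param dbar Reference diameter, mm (default 3.4).
#' @return Adjusted compliance, same units.
#' @examples
#' adjust_compliance(60, d = 1.7)  # 480
#' @export
adjust_compliance <- function(phir, d, dbar = 3.4) {
  if (any(d <= 0) || any(dbar <= 0)) stop("diameters must be positive")
  phir * (dbar / d)^3
}
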