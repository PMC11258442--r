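#' Schlemm's canal area relative to baseline
#'
#' Expresses segmented SC luminal cross-sectional areas at each IOP level as
#' a percentage of the area at the baseline IOP (default 10 mmHg). Units of
#' area are caller-defined but must be consistent within a series.
#'
#' @param iop IOP levels, mmHg.
#' @param area SC luminal areas at those levels (any consistent unit).
#' @param baseline_iop Baseline level, mmHg (default 10); must be present.
#' @return Data frame with `iop_mmHg` and `relative_area_pct` (baseline maps
#'   to 100).
#' @examples
#' relative_sc_area(c(10, 15, 20), c(2000, 1700, 1500))
#' @export
relative_sc_area <- function(iop, area, baseline_iop = 10) {
  stopifnot(length(iop) == length(area))
  if (any(area <= 0)) stop("areas must be positive")
  b <- which(iop == baseline_iop)
  if (length(b) != 1)
    stop(sprintf("baseline level (%g mmHg) must appear exactly once", baseline_iop))
  data.frame(iop_mmHg = iop, relative_area_pct = 100 * area / area[b])
}

#' Pressure sensitivity of relative SC area (fixed 100% intercept)
#'
#' Linear regression of relative SC area on IOP with the intercept fixed at
#' 100% at the baseline pressure: regression of (area% - 100) on
#' (IOP - baseline) through the origin. The slope (%/mmHg) quantifies
#' IOP-induced SC collapse; more negative = more collapsible.
#'
#' @param iop IOP levels, mmHg.
#' @param relative_area Relative areas, % of baseline.
#' @param baseline_iop Baseline IOP, mmHg (default 10).
#' @param conf_level Confidence level (default 0.95).
#' @return A list with `slope` (%/mmHg), `CI_slope`, `se`, `n` (non-baseline
#'   levels used).
#' @examples
#' fixed_intercept_slope(c(10, 15, 20), c(100, 90, 80))$slope  # -2
#' @export
fixed_intercept_slope <- function(iop, relative_area, baseline_iop = 10,
                                  conf_level = 0.95) {
  stopifnot(length(iop) == length(relative_area))
  x <- iop - baseline_iop
  y <- relative_area - 100
  if (sum(x != 0) < 2)
    stop("need at least 2 non-baseline levels")
  if (all(x == 0)) stop("singular: all levels at baseline")
  fit <- stats::lm(y ~ x - 1)
  sm <- suppressWarnings(summary(fit))
  ci <- suppressWarnings(stats::confint(fit, level = conf_level))
  list(slope = unname(stats::coef(fit)["x"]),
       CI_slope = unname(ci["x", ]),
       se = sm$coefficients["x", "Std. Error"],
       n = sum(x != 0))
}

#' Iridocorneal angle from two image segments
#'
#' Computes the angle subtended at the apex of the iridocorneal angle by a
#' segment to the anterior iris surface and a segment to the posterior
#' cornea surface, drawn on an image with anisotropic pixels. Pixel offsets
#' are converted to physical units with per-axis scale factors before the
#' angle is taken, so the result is invariant to uniform rescaling.
#'
#' @param apex,iris_point,cornea_point Numeric length-2 vectors, (x, y) in
#'   pixels.
#' @param scale Length-2 vector of physical units per pixel (horizontal,
#'   vertical), e.g. mm/px.
#' @return Angle in degrees, in (0, 180].
#' @examples
#' iris_angle_from_segments(c(0, 0), c(1, 0), c(0, 1), scale = c(1, 1))  # 90
#' @export
iris_angle_from_segments <- function(apex, iris_point, cornea_point,
                                     scale = c(1, 1)) {
  stopifnot(length(apex) == 2, length(iris_point) == 2,
            length(cornea_point) == 2, length(scale) == 2)
  if (any(scale <= 0)) stop("scale factors must be positive")
  v1 <- (iris_point - apex) * scale
  v2 <- (cornea_point - apex) * scale
  if (sqrt(sum(v1^2)) == 0 || sqrt(sum(v2^2)) == 0)
    stop("segment endpoints must be distinct from the apex")
  cosang <- sum(v1 * v2) / (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))
  acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
}

#' Sensitivity of the iridocorneal angle to pressure
#'
#' Fits the empirical log law \eqn{\theta - \theta_0 = \zeta \ln(P - P_0)}
#' relating the increase in iridocorneal angle to the logarithm of the IOP
#' elevation above baseline (\eqn{P_0} = 10 mmHg). The model has no
#' intercept, so the fit is through the origin by default; `allow_intercept`
#' relaxes this.
#'
#' @param iop IOP levels, mmHg; all must exceed `baseline_iop`.
#' @param theta Angles at those levels, degrees.
#' @param theta0 Baseline angle at `baseline_iop`, degrees.
#' @param baseline_iop Baseline IOP, mmHg (default 10).
#' @param allow_intercept Fit a free intercept as well (default FALSE).
#' @param conf_level Confidence level (default 0.95).
#' @return A list with `zeta` (degrees per log-mmHg), `CI_zeta`, `se`,
#'   `theta0`, `n`.
#' @examples
#' fit_iris_sensitivity(c(12, 15, 20), 20 + 5 * log(c(2, 5, 10)), theta0 = 20)
#' @export
fit_iris_sensitivity <- function(iop, theta, theta0, baseline_iop = 10,
                                 allow_intercept = FALSE, conf_level = 0.95) {
  stopifnot(length(iop) == length(theta), length(theta0) == 1)
  if (any(iop <= baseline_iop))
    stop("all fitted levels must exceed the baseline IOP")
  if (length(iop) < 2) stop("need at least 2 levels above baseline")
  x <- log(iop - baseline_iop)
  y <- theta - theta0
  fit <- if (allow_intercept) stats::lm(y ~ x) else stats::lm(y ~ x - 1)
  sm <- suppressWarnings(summary(fit))
  ci <- suppressWarnings(stats::confint(fit, level = conf_level))
  list(zeta = unname(stats::coef(fit)["x"]),
       CI_zeta = unname(ci["x", ]),
       se = sm$coefficients["x", "Std. Error"],
       theta0 = theta0,
       n = length(iop))
}

#' Normalized SC-area discrepancy between experiment and model
#'
#' \deqn{\Delta nSCLA = (SCLA_{exp} - SCLA_{comp}) / SCLA_{baseline}}
#' measures how closely a computed collapse of the SC lumen agrees with the
#' experimentally observed collapse; 0 is perfect agreement, negative values
#' mean the computation collapsed less than observed.
#'
#' @param scla_exp Experimental SC luminal area.
#' @param scla_comp Computed SC luminal area (same units).
#' @param scla_baseline Reference area at baseline IOP (10 mmHg); positive.
#' @return Dimensionless discrepancy.
#' @examples
#' delta_nSCLA(0.8, 0.6, 1)  # 0.2
#' @export
delta_nSCLA <- function(scla_exp, scla_comp, scla_baseline) {
  if (any(scla_baseline <= 0)) stop("baseline area must be positive")
  (scla_exp - scla_comp) / scla_baseline
}
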