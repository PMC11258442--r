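#' Robust outlier screen using the median absolute deviation
#'
#' Screens parameter estimates per age group: a value is rejected only when
#' its entire confidence interval lies farther than `k` raw median absolute
#' deviations (no consistency factor) from the group median -- i.e. even the
#' CI bound nearest the median is outside the band. Facility and compliance
#' are log-normally distributed, so they are screened on the log scale
#' (`log_domain = TRUE`). Groups smaller than 4 are passed through
#' unfiltered with a warning.
#'
#' @param values Parameter estimates.
#' @param ci_low,ci_high 95% CI bounds (default: the values themselves,
#'   i.e. negligible CIs).
#' @param group Optional grouping factor (e.g. age group); default one group.
#' @param k Rejection threshold in MAD units (default 2.5).
#' @param log_domain Screen on the log scale (requires positive values).
#' @return A list with `keep` (logical vector), `rejected` (indices),
#'   and `diagnostics` (per-group median and MAD, on the screening scale).
#' @examples
#' mad_outlier_filter(c(1, 1.1, 0.9, 10))$rejected  # 4
#' @export
mad_outlier_filter <- function(values, ci_low = values, ci_high = values,
                               group = NULL, k = 2.5, log_domain = TRUE) {
  n <- length(values)
  stopifnot(length(ci_low) == n, length(ci_high) == n, k > 0)
  if (is.null(group)) group <- rep(1L, n)
  if (log_domain) {
    if (any(values <= 0 | ci_low <= 0 | ci_high <= 0))
      stop("log-domain screening requires positive values and CI bounds")
    v <- log(values); lo <- log(ci_low); hi <- log(ci_high)
  } else {
    v <- values; lo <- ci_low; hi <- ci_high
  }
  keep <- rep(TRUE, n)
  diag_rows <- list()
  for (g in unique(group)) {
    idx <- which(group == g)
    if (length(idx) < 4) {
      warning(sprintf("group '%s' has fewer than 4 values; passed through unfiltered", g))
      diag_rows[[length(diag_rows) + 1]] <-
        data.frame(group = as.character(g), n = length(idx),
                   median = NA_real_, mad = NA_real_)
      next
    }
    m <- stats::median(v[idx])
    mad <- stats::median(abs(v[idx] - m))
    # distance of the CI bound nearest the median (0 if the CI straddles it)
    d_near <- pmax(pmax(lo[idx] - m, m - hi[idx]), 0)
    keep[idx] <- !(d_near > k * mad)
    diag_rows[[length(diag_rows) + 1]] <-
      data.frame(group = as.character(g), n = length(idx), median = m, mad = mad)
  }
  list(keep = keep, rejected = which(!keep),
       diagnostics = do.call(rbind, diag_rows))
}

#' Interocular correlation of a paired parameter
#'
#' Pearson correlation between left- and right-eye values of the same
#' animals, used to decide whether eyes can be treated as independent.
#' Facility and compliance should be supplied on the log scale
#' (`log_domain = TRUE`).
#'
#' @param left,right Paired per-eye values (same animals, same order).
#' @param log_domain Correlate the logarithms.
#' @return A list with `r`, `p` (two-sided), `n_pairs`.
#' @export
interocular_correlation <- function(left, right, log_domain = FALSE) {
  ok <- stats::complete.cases(left, right)
  left <- left[ok]; right <- right[ok]
  if (length(left) < 3)
    stop("interocular correlation requires at least 3 complete pairs")
  if (log_domain) {
    if (any(left <= 0 | right <= 0)) stop("log domain requires positive values")
    left <- log(left); right <- log(right)
  }
  ct <- stats::cor.test(left, right, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n_pairs = length(left))
}

#' Bilateral average of a paired parameter with quadrature CI
#'
#' Eyes of one animal are correlated, so the animal -- not the eye -- is the
#' statistical unit. Facility and compliance are averaged in the log domain
#' (geometric mean); beta, which can be zero or negative, arithmetically.
#' CI half-widths h1, h2 (in the averaging domain) combine in quadrature to
#' \eqn{\sqrt{h_1^2 + h_2^2}/2}. Single-eye animals pass through unchanged.
#'
#' @param values One or two per-eye estimates.
#' @param ci_low,ci_high Matching CI bounds.
#' @param log_domain Average geometrically with log-domain quadrature.
#' @return A list with `value`, `ci_low`, `ci_high`, `n_eyes`.
#' @examples
#' bilateral_average(c(4, 9), c(3, 7), c(5, 11), log_domain = TRUE)$value  # 6
#' @export
bilateral_average <- function(values, ci_low = values, ci_high = values,
                              log_domain = FALSE) {
  n <- length(values)
  stopifnot(n %in% c(1L, 2L), length(ci_low) == n, length(ci_high) == n)
  if (n == 1)
    return(list(value = values, ci_low = ci_low, ci_high = ci_high, n_eyes = 1L))
  if (log_domain) {
    if (any(c(values, ci_low, ci_high) <= 0))
      stop("log-domain averaging requires positive values and CI bounds")
    v <- log(values); lo <- log(ci_low); hi <- log(ci_high)
  } else {
    v <- values; lo <- ci_low; hi <- ci_high
  }
  h <- (hi - lo) / 2
  m <- mean(v)
  hc <- sqrt(sum(h^2)) / 2
  out <- c(m, m - hc, m + hc)
  if (log_domain) out <- exp(out)
  list(value = out[1], ci_low = out[2], ci_high = out[3], n_eyes = 2L)
}

#' Ordinary least-squares regression of an outcome on age
#'
#' Age is treated as a continuous variable. The outcome may be
#' log-transformed first (facility and compliance). Reports the slope with
#' t-based 95% CI, intercept, R-squared, two-sided p, and the
#' Bonferroni-adjusted \eqn{p_B = \min(1, m\,p)} when `bonferroni_m > 1`
#' (m = 3 for facility, beta and compliance, which are tested on the same
#' data).
#'
#' @param ages Ages, months.
#' @param y Outcome values.
#' @param log_y Regress the natural log of `y`.
#' @param bonferroni_m Number of comparisons for the correction (default 1).
#' @param weights Optional OLS weights (default unweighted).
#' @param conf_level Confidence level (default 0.95).
#' @return An object of class `age_regression`: `slope`, `CI_slope`,
#'   `intercept`, `CI_intercept`, `r_squared`, `p`, `p_B`, `n`, `log_y`.
#' @examples
#' regress_on_age(1:4, c(1, 3, 2, 4))
#' @export
regress_on_age <- function(ages, y, log_y = FALSE, bonferroni_m = 1,
                           weights = NULL, conf_level = 0.95) {
  ok <- stats::complete.cases(ages, y)
  ages <- ages[ok]; y <- y[ok]
  if (!is.null(weights)) weights <- weights[ok]
  if (length(ages) < 3) stop("age regression requires at least 3 points")
  if (stats::sd(ages) < sqrt(.Machine$double.eps))
    stop("singular regression: ages are constant")
  if (log_y) {
    if (any(y <= 0)) stop("log transform requires positive outcome values")
    y <- log(y)
  }
  fit <- stats::lm(y ~ ages, weights = weights)
  sm <- suppressWarnings(summary(fit))
  ci <- suppressWarnings(stats::confint(fit, level = conf_level))
  p <- sm$coefficients["ages", "Pr(>|t|)"]
  structure(list(
    slope = unname(stats::coef(fit)["ages"]),
    CI_slope = unname(ci["ages", ]),
    intercept = unname(stats::coef(fit)["(Intercept)"]),
    CI_intercept = unname(ci["(Intercept)", ]),
    r_squared = sm$r.squared,
    p = p,
    p_B = if (bonferroni_m > 1) min(1, bonferroni_m * p) else p,
    bonferroni_m = bonferroni_m,
    n = length(ages),
    log_y = log_y,
    conf_level = conf_level
  ), class = "age_regression")
}

#' @export
print.age_regression <- function(x, ...) {
  cat(sprintf("Age regression (n = %d%s)\n", x$n,
              if (x$log_y) ", log outcome" else ""))
  cat(sprintf("  slope = %.4g [%.4g, %.4g] per month, R^2 = %.2f, p = %.3g",
              x$slope, x$CI_slope[1], x$CI_slope[2], x$r_squared, x$p))
  if (x$bonferroni_m > 1) cat(sprintf(", p_B = %.3g", x$p_B))
  cat("\n")
  invisible(x)
}

#' Default age-group boundaries
#'
#' Young < 8 months, middle-aged 8--16 months, elderly > 16 months.
#'
#' @param age Ages, months.
#' @return Factor with levels `young`, `middle`, `elderly`.
#' @export
age_group <- function(age) {
  factor(ifelse(age < 8, "young", ifelse(age <= 16, "middle", "elderly")),
         levels = c("young", "middle", "elderly"))
}
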