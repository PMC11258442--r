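#' Configuration of a synthetic mouse cohort
#'
#' Defines the statistical structure of a simulated aging cohort: uniform
#' ages, log-normally distributed facility and compliance around age trends,
#' a normally distributed nonlinearity factor beta with a linear age trend,
#' correlated eyes within an animal, a power-law diameter growth model, and
#' linear age trends with Gaussian residuals for the morphometric outcomes
#' (TM cell density, juxtacanalicular pigment density, p21 intensity,
#' baseline iridocorneal angle, angle sensitivity zeta, SC-area collapse
#' slope). All trend baselines are stated at `ref_age` (2 months).
#'
#' Trend defaults are the cohort-level estimates this pipeline is designed to
#' recover: beta falls by 0.027 per month, TM cell density by 2.0
#' cells/mm2/month, pigment density rises by 6.8 granules/mm2/month, and the
#' baseline iridocorneal angle by 1.2 degrees/month. Facility carries no age
#' trend (it is stable with age). Residual SDs are set so the age
#' regressions have realistic coefficients of determination (about 0.66 for
#' cellularity, 0.32 for pigment, 0.78 for p21, 0.64 for the baseline angle,
#' 0.38 for zeta, 0.5 for beta at the animal level, 0.82 for log adjusted
#' compliance).
#'
#' @param n_animals Number of animals (two eyes each).
#' @param age_range Age range, months (default 2--32).
#' @param ref_age Age at which baselines are stated, months (default 2).
#' @param Cr_ref Median reference facility at `ref_age`, nL/min/mmHg.
#' @param Cr_log_slope Age trend of log facility, per month (default 0).
#' @param Cr_log_sd Eye-level SD of log facility.
#' @param beta_ref Mean beta at `ref_age`.
#' @param beta_age_slope Age trend of beta, per month.
#' @param beta_sd Eye-level SD of beta.
#' @param phir_ref Median reference compliance at `ref_age`, nL/mmHg.
#' @param phir_log_slope Age trend of log compliance, per month.
#' @param phir_log_sd Eye-level SD of log compliance.
#' @param gamma_meanlog,gamma_sdlog Log-normal parameters of the compliance
#'   shape parameter gamma (mmHg).
#' @param interocular_correlation Correlation between eyes of one animal for
#'   facility, beta and compliance (in their analysis domains).
#' @param diameter_a1,diameter_a2,diameter_a3 Growth model
#'   d = a1 age^a2 + a3 (mm, months); defaults give a cohort mean diameter
#'   of 3.4 mm over ages 2--32.
#' @param diameter_sd Animal-level SD of diameter, mm.
#' @param cell_density_ref,cell_density_slope,cell_density_sd TM cell
#'   density: baseline (cells/mm2 at `ref_age`), slope (cells/mm2/month),
#'   residual SD.
#' @param pigment_ref,pigment_slope,pigment_sd JCT pigment granule density
#'   (granules/mm2, granules/mm2/month).
#' @param p21_ref,p21_slope,p21_sd p21 fluorescence intensity (a.u.).
#' @param iris_angle_ref,iris_angle_slope,iris_angle_sd Baseline
#'   iridocorneal angle at 10 mmHg (degrees, degrees/month).
#' @param zeta_ref,zeta_slope,zeta_sd Angle-pressure sensitivity zeta
#'   (degrees per log-mmHg).
#' @param sc_slope_ref,sc_slope_age_slope,sc_slope_sd Relative SC-area
#'   collapse slope (%/mmHg) and its age trend.
#' @param iop_levels IOP levels of the imaging protocol, mmHg.
#' @param baseline_iop Baseline imaging IOP, mmHg.
#' @param flow_cv,pressure_sd Trace measurement noise (see [noise_model()]).
#' @param seed Integer seed; per-eye trace seeds are derived from it
#'   deterministically.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_animals = 60,
                          age_range = c(2, 32),
                          ref_age = 2,
                          Cr_ref = 5, Cr_log_slope = 0, Cr_log_sd = 0.25,
                          beta_ref = 0.80, beta_age_slope = -0.027, beta_sd = 0.25,
                          phir_ref = 80, phir_log_slope = -0.035, phir_log_sd = 0.15,
                          gamma_meanlog = log(5), gamma_sdlog = 0.2,
                          interocular_correlation = 0.7,
                          diameter_a1 = 0.34, diameter_a2 = 0.25, diameter_a3 = 2.73,
                          diameter_sd = 0.05,
                          cell_density_ref = 400, cell_density_slope = -2.0,
                          cell_density_sd = 12.5,
                          pigment_ref = 250, pigment_slope = 6.8, pigment_sd = 85,
                          p21_ref = 20, p21_slope = 1.0, p21_sd = 4.5,
                          iris_angle_ref = 25, iris_angle_slope = 1.2,
                          iris_angle_sd = 7.8,
                          zeta_ref = 6, zeta_slope = -0.15, zeta_sd = 1.65,
                          sc_slope_ref = -2.4, sc_slope_age_slope = 0.06,
                          sc_slope_sd = 0.45,
                          iop_levels = c(10, 12, 15, 17, 20), baseline_iop = 10,
                          flow_cv = 0.05, pressure_sd = 0.05,
                          seed = 1L) {
  if (n_animals < 1) stop("n_animals must be at least 1")
  stopifnot(length(age_range) == 2, age_range[1] <= age_range[2],
            age_range[1] >= 0)
  if (interocular_correlation < 0 || interocular_correlation > 1)
    stop("interocular_correlation must lie in [0, 1]")
  stopifnot(Cr_ref > 0, phir_ref > 0)
  cfg <- as.list(environment())
  class(cfg) <- "cohort_config"
  cfg
}

# linear trend helper: baseline at ref_age plus slope * (age - ref_age)
trend_at <- function(ref, slope, age, ref_age) ref + slope * (age - ref_age)

# correlated pair of standard normal deviates per animal, correlation rho
paired_normal <- function(n_animals, rho) {
  za <- stats::rnorm(n_animals)
  ze <- matrix(stats::rnorm(2 * n_animals), n_animals, 2)
  sqrt(rho) * za + sqrt(1 - rho) * ze
}

#' Generate a synthetic perfusion cohort
#'
#' Draws per-eye ground-truth parameters from the configured age trends
#' (ages uniform over the age range; facility and compliance log-normal;
#' beta normal; eyes of one animal share a latent effect giving the
#' configured interocular correlation; diameters follow the growth model
#' with animal-level noise) and, optionally, forward-simulates a perfusion
#' trace for every eye.
#'
#' @param config A [cohort_config()].
#' @param protocol A [perfusion_protocol()] for the simulated traces.
#' @param traces Simulate traces (default TRUE); `FALSE` returns the truth
#'   table only.
#' @param r_sys Perfusion-system resistance, mmHg/(nL/min).
#' @return A list with `truth` (data frame, one row per eye: `animal_id`,
#'   `eye`, `age_months`, `sex`, `diameter_mm`, `Cr_true`, `beta_true`,
#'   `phir_true`, `gamma_true`, `trace_seed`) and `traces` (named list of
#'   `perfusion_trace`, or `NULL`).
#' @export
generate_cohort <- function(config = cohort_config(),
                            protocol = perfusion_protocol(),
                            traces = TRUE, r_sys = 0.001) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_animals
  ages <- stats::runif(n, config$age_range[1], config$age_range[2])
  sexes <- sample(c("M", "F"), n, replace = TRUE)
  rho <- config$interocular_correlation

  z_c <- paired_normal(n, rho)   # log facility
  z_b <- paired_normal(n, rho)   # beta
  z_p <- paired_normal(n, rho)   # log compliance
  d_anim <- config$diameter_a1 * ages^config$diameter_a2 + config$diameter_a3 +
    stats::rnorm(n, sd = config$diameter_sd)
  gamma_anim <- stats::rlnorm(n, config$gamma_meanlog, config$gamma_sdlog)
  trace_seeds <- sample.int(.Machine$integer.max, 2 * n)

  rows <- vector("list", 2 * n)
  i <- 0
  for (a in seq_len(n)) {
    for (e in 1:2) {
      i <- i + 1
      logCr <- log(config$Cr_ref) +
        config$Cr_log_slope * (ages[a] - config$ref_age) +
        config$Cr_log_sd * z_c[a, e]
      beta <- trend_at(config$beta_ref, config$beta_age_slope, ages[a],
                       config$ref_age) + config$beta_sd * z_b[a, e]
      logphi <- log(config$phir_ref) +
        config$phir_log_slope * (ages[a] - config$ref_age) +
        config$phir_log_sd * z_p[a, e]
      rows[[i]] <- data.frame(
        animal_id = sprintf("M%03d", a),
        eye = c("OD", "OS")[e],
        age_months = ages[a],
        sex = sexes[a],
        diameter_mm = d_anim[a],
        Cr_true = exp(logCr),
        beta_true = beta,
        phir_true = exp(logphi),
        gamma_true = gamma_anim[a],
        trace_seed = trace_seeds[i])
    }
  }
  truth <- do.call(rbind, rows)

  trace_list <- NULL
  if (traces) {
    trace_list <- vector("list", nrow(truth))
    for (i in seq_len(nrow(truth))) {
      params <- true_eye_params(Cr = truth$Cr_true[i], beta = truth$beta_true[i],
                                phir = truth$phir_true[i],
                                gamma = truth$gamma_true[i],
                                diameter = truth$diameter_mm[i],
                                age = truth$age_months[i], sex = truth$sex[i])
      nm <- noise_model(config$flow_cv, config$pressure_sd,
                        seed = truth$trace_seed[i])
      trace_list[[i]] <- simulate_perfusion_trace(params, protocol, nm,
                                                  r_sys = r_sys)
    }
    names(trace_list) <- paste(truth$animal_id, truth$eye, sep = "_")
  }
  list(truth = truth, traces = trace_list)
}

#' Generate a synthetic morphometry and imaging table
#'
#' One eye per animal. Each scalar outcome is a linear age trend plus a
#' Gaussian residual with the configured SD. Iris angles are generated
#' exactly from the log law theta = theta0(age) + zeta(age) ln(P - P0) at
#' the imaging IOP levels above baseline; relative SC areas are generated
#' exactly from a per-eye collapse slope through 100% at the baseline IOP.
#'
#' @param config A [cohort_config()]; `n_animals` sets the number of eyes.
#' @return A list with `summary` (per-eye: `eye_id`, `age_months`,
#'   `cell_density_mm2`, `pigment_density_mm2`, `p21_intensity`,
#'   `theta0_deg`, `zeta_true`, `sc_slope_true`) and `pressure_series`
#'   (long format: `eye_id`, `iop_mmHg`, `sc_area_rel_pct`,
#'   `iris_angle_deg`).
#' @export
generate_morphometry_tables <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_animals
  ages <- stats::runif(n, config$age_range[1], config$age_range[2])
  ra <- config$ref_age

  summary_tab <- data.frame(
    eye_id = sprintf("E%03d", seq_len(n)),
    age_months = ages,
    cell_density_mm2 = trend_at(config$cell_density_ref,
                                config$cell_density_slope, ages, ra) +
      stats::rnorm(n, sd = config$cell_density_sd),
    pigment_density_mm2 = trend_at(config$pigment_ref, config$pigment_slope,
                                   ages, ra) +
      stats::rnorm(n, sd = config$pigment_sd),
    p21_intensity = trend_at(config$p21_ref, config$p21_slope, ages, ra) +
      stats::rnorm(n, sd = config$p21_sd),
    theta0_deg = trend_at(config$iris_angle_ref, config$iris_angle_slope,
                          ages, ra) +
      stats::rnorm(n, sd = config$iris_angle_sd),
    zeta_true = trend_at(config$zeta_ref, config$zeta_slope, ages, ra) +
      stats::rnorm(n, sd = config$zeta_sd),
    sc_slope_true = trend_at(config$sc_slope_ref, config$sc_slope_age_slope,
                             ages, ra) +
      stats::rnorm(n, sd = config$sc_slope_sd))

  series <- lapply(seq_len(n), function(i) {
    p <- config$iop_levels
    above <- p > config$baseline_iop
    theta <- rep(summary_tab$theta0_deg[i], length(p))
    theta[above] <- summary_tab$theta0_deg[i] +
      summary_tab$zeta_true[i] * log(p[above] - config$baseline_iop)
    data.frame(eye_id = summary_tab$eye_id[i],
               iop_mmHg = p,
               sc_area_rel_pct = 100 + summary_tab$sc_slope_true[i] *
                 (p - config$baseline_iop),
               iris_angle_deg = theta)
  })
  list(summary = summary_tab, pressure_series = do.call(rbind, series))
}
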