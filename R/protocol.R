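#' Pressure-step perfusion protocol
#'
#' Describes the commanded reservoir-pressure schedule of a multi-step
#' perfusion experiment: an acclimatization hold followed by a sequence of
#' constant-pressure steps. The default is the standard nine-step mouse
#' protocol (4.5--21 mmHg) with a 30-min acclimatization at 9 mmHg.
#'
#' @param step_pressures Commanded pressures for the sequential steps, mmHg.
#' @param step_duration Duration of each step, seconds.
#' @param acclimatization_pressure Pressure held before the first step, mmHg.
#' @param acclimatization_duration Duration of the acclimatization hold, seconds.
#' @param sampling_interval Sampling interval of the recorded channels, seconds.
#' @return An object of class `perfusion_protocol`.
#' @examples
#' perfusion_protocol()
#' @export
perfusion_protocol <- function(step_pressures = c(4.5, 6, 7.5, 9, 10.5, 12, 15, 18, 21),
                               step_duration = 360,
                               acclimatization_pressure = 9,
                               acclimatization_duration = 1800,
                               sampling_interval = 1) {
  stopifnot(length(step_pressures) >= 1, is.numeric(step_pressures))
  if (any(step_pressures <= 0))
    stop("all commanded step pressures must be positive (mmHg)")
  if (acclimatization_pressure <= 0)
    stop("acclimatization pressure must be positive (mmHg)")
  if (step_duration <= 0 || sampling_interval <= 0)
    stop("step_duration and sampling_interval must be positive (s)")
  if (step_duration < 2 * sampling_interval)
    stop("step_duration must cover at least two samples")
  structure(
    list(
      step_pressures = as.numeric(step_pressures),
      step_duration = step_duration,
      acclimatization_pressure = acclimatization_pressure,
      acclimatization_duration = acclimatization_duration,
      sampling_interval = sampling_interval
    ),
    class = "perfusion_protocol"
  )
}

#' @export
print.perfusion_protocol <- function(x, ...) {
  cat("Perfusion protocol\n")
  cat("  acclimatization:", x$acclimatization_pressure, "mmHg for",
      x$acclimatization_duration, "s\n")
  cat("  steps (mmHg):", paste(x$step_pressures, collapse = ", "), "\n")
  cat("  step duration:", x$step_duration, "s; sampling:",
      x$sampling_interval, "s\n")
  invisible(x)
}

#' Measurement-noise model for simulated perfusions
#'
#' Flow sensors in the nL/min regime show signal-proportional error, so flow
#' noise is multiplicative (Gaussian with coefficient of variation
#' `flow_cv`); pressure noise is additive Gaussian with SD `pressure_sd`.
#'
#' @param flow_cv Coefficient of variation of the multiplicative flow noise.
#' @param pressure_sd SD of the additive pressure noise, mmHg.
#' @param seed Integer seed making the simulated noise reproducible, or `NULL`.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(flow_cv = 0.05, pressure_sd = 0.05, seed = NULL) {
  stopifnot(flow_cv >= 0, pressure_sd >= 0)
  if (!is.null(seed)) seed <- as.integer(seed)
  structure(list(flow_cv = flow_cv, pressure_sd = pressure_sd, seed = seed),
            class = "noise_model")
}

#' Ground-truth aqueous humor dynamics parameters of one eye
#'
#' The forward model of an eye used by the simulator: reference outflow
#' facility `Cr` and nonlinearity `beta` set the pressure-flow relation
#' \deqn{Q(P) = C_r (P/P_{r,C})^\beta P,}
#' and reference compliance `phir` with shape parameter `gamma` set the
#' pressure-dependent ocular compliance
#' \deqn{\phi(P) = \phi_r (P_{r,\phi} + \gamma) / (P + \gamma).}
#'
#' @param Cr Reference outflow facility at `Pr_C`, nL/min/mmHg (> 0).
#' @param beta Dimensionless nonlinearity factor (0 = pressure-independent).
#' @param phir Reference ocular compliance at `Pr_phi`, nL/mmHg (> 0).
#' @param gamma Compliance shape parameter, mmHg; `P + gamma` must stay
#'   positive over the protocol.
#' @param diameter Ocular diameter at the equator, mm.
#' @param age Age, months.
#' @param sex `"M"` or `"F"`.
#' @param Pr_C Reference pressure for facility, mmHg (default 8).
#' @param Pr_phi Reference pressure for compliance, mmHg (default 13).
#' @return An object of class `true_eye_params`.
#' @export
true_eye_params <- function(Cr = 5, beta = 0.5, phir = 80, gamma = 5,
                            diameter = 3.4, age = 6, sex = "F",
                            Pr_C = 8, Pr_phi = 13) {
  stopifnot(Cr > 0, phir > 0, diameter > 0, age >= 0, Pr_C > 0, Pr_phi > 0)
  if (!sex %in% c("M", "F")) stop("sex must be 'M' or 'F'")
  if (Pr_phi + gamma <= 0) stop("Pr_phi + gamma must be positive")
  structure(list(Cr = Cr, beta = beta, phir = phir, gamma = gamma,
                 diameter = diameter, age = age, sex = sex,
                 Pr_C = Pr_C, Pr_phi = Pr_phi),
            class = "true_eye_params")
}

# true compliance at pressure P (nL/mmHg)
phi_true <- function(params, P) {
  params$phir * (params$Pr_phi + params$gamma) / (P + params$gamma)
}

# true pressure-flow relation (nL/min)
q_true <- function(params, P) {
  params$Cr * (P / params$Pr_C)^params$beta * P
}

# antiderivative of phi(P): stored volume potential (nL)
phi_volume_potential <- function(params, P) {
  params$phir * (params$Pr_phi + params$gamma) * log(P + params$gamma)
}
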