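#' Simulate one pressure-step perfusion experiment
#'
#' Forward-simulates the hydraulics of an enucleated eye connected to a
#' constant-pressure reservoir through a series hydraulic resistance
#' `r_sys`. The intraocular pressure P obeys the volume balance
#' \deqn{\phi(P)\,dP/dt = Q_{in} - Q_{out}(P),}
#' with inflow \eqn{Q_{in} = (P_a - P)/R_{sys}} driven by the commanded
#' reservoir pressure \eqn{P_a(t)} (piecewise-constant per protocol step) and
#' outflow given by the power-law pressure-flow relation of the eye.
#' Unconventional outflow and aqueous production are absent (enucleated-eye
#' setting): steady flow at each step converges to the eye's pressure-flow
#' curve evaluated at the commanded pressure.
#'
#' The recorded trace mimics the instrument: measured flow is the inflow
#' with multiplicative Gaussian noise, measured pressure is IOP with additive
#' Gaussian noise. Simulation starts from the steady state reached during
#' acclimatization, which is therefore not part of the recorded trace.
#'
#' @param params A [true_eye_params()] object.
#' @param protocol A [perfusion_protocol()] object.
#' @param noise A [noise_model()] object; use `flow_cv = 0, pressure_sd = 0`
#'   for noise-free traces.
#' @param r_sys Series hydraulic resistance between reservoir and eye,
#'   mmHg/(nL/min). The default (0.001) makes step transients settle well
#'   within two minutes for mouse-scale parameters.
#' @param rtol,atol Integrator tolerances passed to [deSolve::lsoda()].
#' @return A `perfusion_trace`: a data frame with columns `time_s`,
#'   `pressure_mmHg`, `flow_nl_min`, `step_index`, carrying attributes
#'   `steps` (step annotation table), `balance` (noise-free volume ledger:
#'   injected, drained, stored volumes in nL), and `truth` (the input
#'   parameters).
#' @examples
#' tr <- simulate_perfusion_trace(true_eye_params(beta = 0),
#'                                perfusion_protocol(step_duration = 120),
#'                                noise_model(0, 0))
#' head(tr)
#' @export
simulate_perfusion_trace <- function(params, protocol = perfusion_protocol(),
                                     noise = noise_model(), r_sys = 0.001,
                                     rtol = 1e-8, atol = 1e-8) {
  stopifnot(inherits(params, "true_eye_params"),
            inherits(protocol, "perfusion_protocol"),
            inherits(noise, "noise_model"))
  if (r_sys <= 0) stop("r_sys must be positive")
  if (min(protocol$step_pressures) + params$gamma <= 0)
    stop("compliance model undefined: P + gamma must stay positive over the protocol")

  dt <- protocol$sampling_interval
  n_steps <- length(protocol$step_pressures)
  n_per <- round(protocol$step_duration / dt)

  # steady state under the acclimatization pressure: (Pa - P)/R = Q_out(P)
  p0 <- steady_pressure(params, protocol$acclimatization_pressure, r_sys)

  deriv <- function(t, y, parms) {
    P <- y[1]
    q_in <- (parms$pa - P) / r_sys            # nL/min
    q_out <- q_true(params, P)                # nL/min
    dP <- (q_in - q_out) / phi_true(params, P) / 60   # mmHg/s
    list(c(dP, q_in / 60, q_out / 60))        # volumes in nL, time in s
  }

  state <- c(P = p0, Vin = 0, Vout = 0)
  time_s <- numeric(0); pressure <- numeric(0); step_idx <- integer(0)
  starts <- numeric(n_steps); ends <- numeric(n_steps)

  for (k in seq_len(n_steps)) {
    start <- (k - 1) * protocol$step_duration
    times <- start + dt * (0:n_per)
    out <- deSolve::lsoda(state, times, deriv,
                          parms = list(pa = protocol$step_pressures[k]),
                          rtol = rtol, atol = atol)
    if (any(!is.finite(out)))
      stop(sprintf("integration failure at step %d (commanded %.2f mmHg)",
                   k, protocol$step_pressures[k]))
    # samples [start, end); the terminal point seeds the next step
    keep <- seq_len(n_per)
    time_s <- c(time_s, out[keep, "time"])
    pressure <- c(pressure, out[keep, "P"])
    step_idx <- c(step_idx, rep.int(k, n_per))
    starts[k] <- start
    ends[k] <- start + protocol$step_duration
    state <- c(P = unname(out[n_per + 1, "P"]),
               Vin = unname(out[n_per + 1, "Vin"]),
               Vout = unname(out[n_per + 1, "Vout"]))
  }

  # flow recorded at the inflow sensor, under the step's commanded pressure
  pa_of_sample <- protocol$step_pressures[step_idx]
  flow <- (pa_of_sample - pressure) / r_sys

  if (!is.null(noise$seed)) set.seed(noise$seed)
  flow_meas <- flow
  pressure_meas <- pressure
  if (noise$flow_cv > 0)
    flow_meas <- flow * (1 + stats::rnorm(length(flow), sd = noise$flow_cv))
  if (noise$pressure_sd > 0)
    pressure_meas <- pressure + stats::rnorm(length(pressure), sd = noise$pressure_sd)

  trace <- data.frame(time_s = time_s,
                      pressure_mmHg = pressure_meas,
                      flow_nl_min = flow_meas,
                      step_index = step_idx)
  attr(trace, "steps") <- data.frame(step_index = seq_len(n_steps),
                                     commanded_mmHg = protocol$step_pressures,
                                     start_s = starts, end_s = ends)
  stored_true <- phi_volume_potential(params, state[["P"]]) -
    phi_volume_potential(params, p0)
  attr(trace, "balance") <- c(injected_nl = state[["Vin"]],
                              drained_nl = state[["Vout"]],
                              stored_nl = stored_true)
  attr(trace, "truth") <- params
  attr(trace, "r_sys") <- r_sys
  attr(trace, "sampling_interval") <- dt
  class(trace) <- c("perfusion_trace", "data.frame")
  trace
}

# IOP at which reservoir inflow balances outflow for commanded pressure pa
steady_pressure <- function(params, pa, r_sys) {
  f <- function(P) (pa - P) / r_sys - q_true(params, P)
  stats::uniroot(f, interval = c(pa * 1e-6, pa), tol = 1e-12)$root
}

#' @export
print.perfusion_trace <- function(x, ...) {
  steps <- attr(x, "steps")
  cat(sprintf("Perfusion trace: %d samples, %d steps (%.1f-%.1f mmHg)\n",
              nrow(x), nrow(steps), min(steps$commanded_mmHg),
              max(steps$commanded_mmHg)))
  bal <- attr(x, "balance")
  if (!is.null(bal))
    cat(sprintf("  volume ledger (nL): injected %.1f = drained %.1f + stored %.1f\n",
                bal["injected_nl"], bal["drained_nl"], bal["stored_nl"]))
  NextMethod()
}

#' Check the volume ledger of a simulated trace
#'
#' Mass balance of the governing ODE: injected volume must equal drained
#' plus stored volume. Returns the relative imbalance
#' `|injected - drained - stored| / injected`.
#'
#' @param trace A simulated `perfusion_trace`.
#' @return Relative volume imbalance (dimensionless).
#' @export
mass_balance_error <- function(trace) {
  bal <- attr(trace, "balance")
  if (is.null(bal)) stop("trace carries no volume ledger (not simulated?)")
  abs(bal["injected_nl"] - bal["drained_nl"] - bal["stored_nl"]) /
    abs(bal["injected_nl"])
}
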