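#' Savitzky-Golay smoothing of a sampled channel
#'
#' Least-squares polynomial smoothing with a moving window, the standard
#' pre-filter for steady-state detection on perfusion channels. The window is
#' given in seconds and converted to an odd number of samples; edges are
#' handled by evaluating the polynomial fitted to the terminal full window at
#' the edge positions, so constants and straight lines pass through unchanged
#' everywhere.
#'
#' @param series Numeric vector, uniformly sampled.
#' @param dt Sampling interval, seconds.
#' @param window Filter window length, seconds (default 60).
#' @param order Polynomial order (default 2, preserving curvature).
#' @return Smoothed series of the same length.
#' @examples
#' sg_filter(sin(seq(0, 10, by = 0.1)), dt = 0.1, window = 1)
#' @export
sg_filter <- function(series, dt, window = 60, order = 2) {
  stopifnot(is.numeric(series), dt > 0, window > 0, order >= 0)
  n <- sg_window_samples(window, dt, order)
  if (length(series) < n)
    stop(sprintf("series (%d samples) shorter than filter window (%d samples)",
                 length(series), n))
  as.numeric(signal::sgolayfilt(series, p = order, n = n))
}

# odd sample count covering `window` seconds, > order
sg_window_samples <- function(window, dt, order) {
  n <- max(round(window / dt), order + 1)
  if (n %% 2 == 0) n <- n + 1
  as.integer(n)
}

#' Per-step stability detection on a perfusion trace
#'
#' Within each protocol step, the flow channel is Savitzky-Golay filtered and
#' its time derivative estimated by linear regression over a sliding window.
#' A step is declared stable when the absolute slope remains below
#' `slope_threshold` (strictly: a slope exactly at threshold counts as
#' unstable) continuously for at least `hold` seconds; the first-stable time
#' is the start of the earliest such run. Steps too short to evaluate the
#' criterion are marked indeterminate rather than raising an error.
#'
#' @param trace A `perfusion_trace` (see [simulate_perfusion_trace()] and
#'   [read_trace()]).
#' @param slope_threshold Maximum admissible flow slope, nL/min/min
#'   (default 3).
#' @param hold Required duration below threshold, seconds (default 60).
#' @param sg_window,sg_order Savitzky-Golay window (s) and polynomial order.
#' @param slope_window Sliding regression window for the slope, seconds
#'   (default 60).
#' @return A data frame with one row per step: `step_index`, `stable`,
#'   `indeterminate`, `first_stable_s` (NA when unstable), `stable_to_end`
#'   (whether the final below-threshold run reaches the end of the step), and
#'   `stable_from_s` (time from which the slope stays below threshold through
#'   the end of the step; NA if it does not).
#' @export
detect_stability <- function(trace, slope_threshold = 3, hold = 60,
                             sg_window = 60, sg_order = 2, slope_window = 60) {
  stopifnot(inherits(trace, "perfusion_trace"), slope_threshold > 0, hold > 0)
  steps <- attr(trace, "steps")
  dt <- attr(trace, "sampling_interval")
  nw <- sg_window_samples(slope_window, dt, 1)

  res <- lapply(seq_len(nrow(steps)), function(k) {
    idx <- which(trace$step_index == steps$step_index[k])
    flow <- trace$flow_nl_min[idx]
    n <- length(flow)
    if (n * dt < hold + slope_window || n < sg_window_samples(sg_window, dt, sg_order)) {
      return(data.frame(step_index = steps$step_index[k], stable = FALSE,
                        indeterminate = TRUE, first_stable_s = NA_real_,
                        stable_to_end = FALSE, stable_from_s = NA_real_))
    }
    sm <- sg_filter(flow, dt, sg_window, sg_order)
    slope <- sliding_slope(sm, dt, nw) * 60    # nL/min per s -> per min
    below <- abs(slope) < slope_threshold      # strict: ties are unstable
    runs <- rle(below)
    run_end <- cumsum(runs$lengths)
    run_start <- run_end - runs$lengths + 1
    # slope index i corresponds to the window covering
    # [start + (i - 1) dt, start + (i + nw - 2) dt]
    win_start_time <- function(i) steps$start_s[k] + (i - 1) * dt
    ok <- runs$values & (runs$lengths - 1) * dt >= hold
    if (!any(ok)) {
      return(data.frame(step_index = steps$step_index[k], stable = FALSE,
                        indeterminate = FALSE, first_stable_s = NA_real_,
                        stable_to_end = FALSE, stable_from_s = NA_real_))
    }
    first_run <- which(ok)[1]
    last_run <- length(runs$values)
    reaches_end <- runs$values[last_run]
    data.frame(step_index = steps$step_index[k], stable = TRUE,
               indeterminate = FALSE,
               first_stable_s = win_start_time(run_start[first_run]),
               stable_to_end = reaches_end,
               stable_from_s = if (reaches_end) win_start_time(run_start[last_run]) else NA_real_)
  })
  do.call(rbind, res)
}

# slope of y over a sliding window of nw samples, assigned to the window end;
# returns (length(y) - nw + 1) values, units of y per second
sliding_slope <- function(y, dt, nw) {
  j <- seq_len(nw) - (nw + 1) / 2           # centred sample offsets
  denom <- sum(j^2) * dt
  as.numeric(stats::filter(y, rev(j), sides = 1))[nw:length(y)] / denom
}

#' Extract steady-state points from a perfusion trace
#'
#' For each stable step, the pressure and flow channels are Savitzky-Golay
#' filtered and averaged over the final `averaging` seconds of the step; the
#' step contributes a point only if stability is established (a minute-long
#' run of sub-threshold slope) before the averaging window opens. Transient
#' noise excursions of the slope inside the window do not disqualify an
#' already-stable step: they are zero-mean measurement noise, not residual
#' equilibration, and the average remains unbiased. SDs of the filtered
#' channels over the same window are reported as dispersion.
#'
#' @param trace A `perfusion_trace`.
#' @param verdicts Output of [detect_stability()]; computed internally when
#'   omitted.
#' @param averaging Averaging window, seconds (default 240, i.e. 4 min).
#' @param sg_window,sg_order Savitzky-Golay settings (defaults 60 s, order 2).
#' @param ... Passed on to [detect_stability()] when `verdicts` is missing.
#' @return A data frame of class `stable_points`: `step_index`,
#'   `pressure_mmHg`, `flow_nl_min`, `pressure_sd`, `flow_sd`,
#'   `window_start_s`, `window_end_s`. Steps that are unstable, indeterminate,
#'   or stabilize too late are dropped with a warning.
#' @export
extract_stable_points <- function(trace, verdicts = NULL, averaging = 240,
                                  sg_window = 60, sg_order = 2, ...) {
  stopifnot(inherits(trace, "perfusion_trace"), averaging > 0)
  if (is.null(verdicts)) verdicts <- detect_stability(trace, ...)
  steps <- attr(trace, "steps")
  dt <- attr(trace, "sampling_interval")

  pts <- lapply(seq_len(nrow(steps)), function(k) {
    v <- verdicts[verdicts$step_index == steps$step_index[k], ]
    if (nrow(v) != 1 || !isTRUE(v$stable)) return(NULL)
    w_start <- steps$end_s[k] - averaging
    if (is.na(v$first_stable_s) || v$first_stable_s > w_start) {
      warning(sprintf(
        "step %d: stability not maintained over the %ds averaging window; step dropped",
        steps$step_index[k], averaging))
      return(NULL)
    }
    idx <- which(trace$step_index == steps$step_index[k])
    flow <- sg_filter(trace$flow_nl_min[idx], dt, sg_window, sg_order)
    pres <- sg_filter(trace$pressure_mmHg[idx], dt, sg_window, sg_order)
    t_rel <- trace$time_s[idx]
    in_win <- t_rel >= w_start & t_rel < steps$end_s[k]
    data.frame(step_index = steps$step_index[k],
               pressure_mmHg = mean(pres[in_win]),
               flow_nl_min = mean(flow[in_win]),
               pressure_sd = stats::sd(pres[in_win]),
               flow_sd = stats::sd(flow[in_win]),
               window_start_s = w_start,
               window_end_s = steps$end_s[k])
  })
  pts <- do.call(rbind, Filter(Negate(is.null), pts))
  if (is.null(pts) || nrow(pts) == 0) {
    warning("no stable steps in trace")
    pts <- data.frame(step_index = integer(0), pressure_mmHg = numeric(0),
                      flow_nl_min = numeric(0), pressure_sd = numeric(0),
                      flow_sd = numeric(0), window_start_s = numeric(0),
                      window_end_s = numeric(0))
  }
  if (nrow(pts) < 2)
    attr(pts, "unfittable") <- TRUE
  class(pts) <- c("stable_points", "data.frame")
  pts
}
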