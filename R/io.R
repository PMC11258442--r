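#' Read a perfusion trace from delimited text
#'
#' Expects a CSV with header columns `time_s`, `pressure_mmHg`,
#' `flow_nl_min` and optionally `step_index`. Time must be strictly
#' increasing; non-uniform sampling is resampled onto a uniform grid (linear
#' interpolation) with a warning. When `step_index` is absent, step windows
#' are taken from `protocol`.
#'
#' @param path Path to the file.
#' @param protocol Optional [perfusion_protocol()] used to annotate steps
#'   when the file has no `step_index` column.
#' @return A `perfusion_trace`.
#' @export
read_trace <- function(path, protocol = NULL) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "pressure_mmHg", "flow_nl_min")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0)
    stop(sprintf("%s: missing column(s): %s", path,
                 paste(missing_cols, collapse = ", ")))
  for (col in intersect(c(need, "step_index"), names(raw))) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(raw[[col]]))))
    if (length(bad) > 0)
      stop(sprintf("%s: non-numeric value in column '%s' at data line %d",
                   path, col, bad[1]))
    raw[[col]] <- as.numeric(raw[[col]])
  }
  t <- raw$time_s
  if (any(diff(t) <= 0)) {
    bad <- which(diff(t) <= 0)[1] + 1
    stop(sprintf("%s: time not strictly increasing at data line %d", path, bad))
  }
  dts <- diff(t)
  dt <- stats::median(dts)
  if (length(t) > 2 && max(abs(dts - dt)) > 1e-6 * dt) {
    warning(sprintf("%s: non-uniform sampling; resampled at %g s", path, dt))
    grid <- seq(t[1], t[length(t)], by = dt)
    p <- stats::approx(t, raw$pressure_mmHg, grid)$y
    q <- stats::approx(t, raw$flow_nl_min, grid)$y
    s <- if ("step_index" %in% names(raw))
      as.integer(stats::approx(t, raw$step_index, grid, method = "constant")$y)
    else NULL
    raw <- data.frame(time_s = grid, pressure_mmHg = p, flow_nl_min = q)
    if (!is.null(s)) raw$step_index <- s
    t <- grid
  }

  if (!"step_index" %in% names(raw)) {
    if (is.null(protocol))
      stop(sprintf("%s: no step_index column and no protocol supplied", path))
    starts <- (seq_along(protocol$step_pressures) - 1) * protocol$step_duration
    raw$step_index <- findInterval(t - t[1], starts)
  }
  raw$step_index <- as.integer(raw$step_index)
  steps <- unique(raw$step_index)
  ann <- data.frame(step_index = steps,
                    commanded_mmHg = if (!is.null(protocol) &&
                                         length(protocol$step_pressures) >= max(steps))
                      protocol$step_pressures[steps] else NA_real_,
                    start_s = vapply(steps, function(k)
                      min(t[raw$step_index == k]), numeric(1)),
                    end_s = vapply(steps, function(k)
                      max(t[raw$step_index == k]) + dt, numeric(1)))
  attr(raw, "steps") <- ann
  attr(raw, "sampling_interval") <- dt
  class(raw) <- c("perfusion_trace", "data.frame")
  raw
}

#' Write a perfusion trace to delimited text
#'
#' @param trace A `perfusion_trace`.
#' @param path Output path (CSV).
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "perfusion_trace"))
  utils::write.csv(as.data.frame(trace)[, c("time_s", "pressure_mmHg",
                                            "flow_nl_min", "step_index")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Pipeline run configuration
#'
#' Collects every tunable of the pipeline with its standard default:
#' filter/stability settings (60-s Savitzky-Golay window, order 2, 3
#' nL/min/min slope threshold, 60-s hold, 4-min averaging), reference
#' pressures (Pr_C = 8 mmHg, Pr_phi = 13 mmHg), reference diameter
#' (3.4 mm), outlier threshold (k = 2.5 MADs), Bonferroni m = 3, and
#' age-group boundaries (8 and 16 months).
#'
#' @param ... Overrides of the defaults (named).
#' @return A list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    sg_window = 60, sg_order = 2,
    slope_threshold = 3, hold = 60, slope_window = 60,
    averaging = 240,
    Pr_C = 8, Pr_phi = 13,
    dbar = 3.4,
    outlier_k = 2.5,
    bonferroni_m = 3,
    age_breaks = c(8, 16),
    r_sys = 0.001,
    seed = 1L)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0)
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  class(cfg) <- "run_config"
  cfg
}

#' Read / write a run configuration (YAML)
#'
#' Configurations round-trip losslessly through YAML.
#'
#' @param path File path.
#' @param config A `run_config`.
#' @return `read_run_config` returns a `run_config`; `write_run_config`
#'   returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Write pipeline result tables and a run manifest
#'
#' Writes the per-eye table, per-animal table and regression summary as CSV,
#' plus a machine-readable JSON manifest recording the configuration, seed,
#' package version and QC flags. Rejected outliers stay in the per-eye table
#' (with their rejection reason) but are absent from the regressions.
#'
#' @param eyes Per-eye data frame.
#' @param animals Per-animal data frame.
#' @param regressions Regression-summary data frame.
#' @param dir Output directory (created if needed).
#' @param config The `run_config` used.
#' @return Named character vector of file paths, invisibly.
#' @export
write_results <- function(eyes, animals, regressions, dir, config = run_config()) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(eyes = file.path(dir, "eyes.csv"),
             animals = file.path(dir, "animals.csv"),
             regressions = file.path(dir, "regressions.csv"),
             manifest = file.path(dir, "manifest.json"))
  utils::write.csv(eyes, paths["eyes"], row.names = FALSE)
  utils::write.csv(animals, paths["animals"], row.names = FALSE)
  utils::write.csv(regressions, paths["regressions"], row.names = FALSE)
  manifest <- list(
    package = "outflowr",
    version = as.character(utils::packageVersion("outflowr")),
    config = unclass(config),
    n_eyes = nrow(eyes),
    n_animals = nrow(animals),
    qc = list(rejected_eyes = if ("qc_flag" %in% names(eyes))
      sum(eyes$qc_flag != "ok") else 0L))
  jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(paths)
}
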