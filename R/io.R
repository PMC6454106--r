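config_error <- function(msg) {
  stop(errorCondition(msg, class = c("percsim_config_error", "error")))
}

#' Write a simulation result to tidy CSV
#'
#' Columns: time_h, n_p_pct, n_a_pct, n_t_pct, perchlorate_mM, sulfide_mM.
#'
#' @param sim a \code{sim_result}.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_sim_csv <- function(sim, path) {
  stopifnot(inherits(sim, "sim_result"))
  utils::write.csv(as.data.frame(sim), path, row.names = FALSE)
  invisible(path)
}

#' Read an endpoint plate CSV
#'
#' Expects columns \code{concentration_mM}, \code{replicate},
#' \code{response}.
#'
#' @param path CSV file path.
#' @return A [gradient_plate()].
#' @export
read_plate_csv <- function(path) {
  d <- utils::read.csv(path)
  req <- c("concentration_mM", "replicate", "response")
  if (!all(req %in% names(d)))
    config_error(paste0(path, ": plate CSV needs columns ",
                        paste(req, collapse = ", ")))
  gradient_plate(d$concentration_mM, d$response, d$replicate)
}

#' Read a growth-curve CSV
#'
#' Expects columns \code{time_h}, \code{perchlorate_mM}, \code{replicate},
#' \code{measurement}.
#'
#' @param path CSV file path.
#' @return A [growth_curve_set()].
#' @export
read_growth_csv <- function(path) {
  d <- utils::read.csv(path)
  req <- c("time_h", "perchlorate_mM", "replicate", "measurement")
  if (!all(req %in% names(d)))
    config_error(paste0(path, ": growth CSV needs columns ",
                        paste(req, collapse = ", ")))
  growth_curve_set(d$time_h, d$perchlorate_mM, d$measurement, d$replicate)
}

#' Read a calibration CSV
#'
#' Expects columns \code{srm_pct}, \code{sulfide_mM}.
#'
#' @param path CSV file path.
#' @return Data frame with the two columns.
#' @export
read_calibration_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("srm_pct", "sulfide_mM") %in% names(d)))
    config_error(paste0(path, ": calibration CSV needs columns ",
                        "srm_pct, sulfide_mM"))
  d
}

#' Read a run configuration (YAML or JSON)
#'
#' A run config describes a chemostat simulation or synthetic-data run.
#' Recognized keys (units embedded in the names to prevent unit bugs):
#' \code{preset} (or a \code{strain} block with \code{name},
#' \code{mu_max_per_h}, \code{log_ic50_log10M}, \code{hill_slope}),
#' \code{volume_ml}, \code{flow_ml_per_h}, \code{k_p_pct}, \code{k_a_pct},
#' \code{t_end_h}, \code{schedule} (list of \code{t_start_h} /
#' \code{inflow_perchlorate_mM} entries), \code{calibration}
#' (\code{slope}, \code{intercept}, \code{r_squared}) and a \code{noise}
#' block (\code{kind}, \code{sd}, \code{seed}).
#'
#' @param path YAML or JSON file.
#' @return List with a resolved \code{config} ([chemostat_config()]),
#'   \code{noise} ([noise_model()] or NULL if no noise block), and the
#'   raw parsed list.
#' @export
read_run_config <- function(path) {
  raw <- tryCatch(
    if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
    else yaml::read_yaml(path),
    error = function(e) config_error(paste0(path, ": cannot parse: ",
                                            conditionMessage(e))))
  strain <- if (!is.null(raw$preset)) {
    tryCatch(strain_preset(raw$preset),
             error = function(e) config_error(paste0("unknown preset: ",
                                                     raw$preset)))
  } else if (!is.null(raw$strain)) {
    s <- raw$strain
    tryCatch(strain_params(s$name, s$mu_max_per_h, s$log_ic50_log10M,
                           s$hill_slope),
             error = function(e) config_error(conditionMessage(e)))
  } else config_error("config needs a 'preset' or a 'strain' block")
  calib <- if (is.null(raw$calibration)) sulfide_calibration() else
    sulfide_calibration(raw$calibration$slope, raw$calibration$intercept,
                        raw$calibration$r_squared %||% 0.79)
  sched <- if (is.null(raw$schedule)) {
    data.frame(t_start_h = 0, inflow_perchlorate_mM = 0)
  } else if (is.data.frame(raw$schedule)) {
    # jsonlite simplifies a list of segment objects to a data frame
    if (!all(c("t_start_h", "inflow_perchlorate_mM") %in% names(raw$schedule)))
      config_error("each schedule segment needs t_start_h and inflow_perchlorate_mM")
    raw$schedule[, c("t_start_h", "inflow_perchlorate_mM")]
  } else {
    as.data.frame(do.call(rbind, lapply(raw$schedule, function(seg) {
      if (is.null(seg$t_start_h) || is.null(seg$inflow_perchlorate_mM))
        config_error("each schedule segment needs t_start_h and inflow_perchlorate_mM")
      c(t_start_h = seg$t_start_h,
        inflow_perchlorate_mM = seg$inflow_perchlorate_mM)
    })))
  }
  config <- tryCatch(
    chemostat_config(
      volume = raw$volume_ml %||% 125,
      flow = raw$flow_ml_per_h %||% 2.6,
      compartments = compartment_params(raw$k_p_pct %||% 40,
                                        raw$k_a_pct %||% 0.5),
      strain = strain, calib = calib, schedule = sched,
      t_end = raw$t_end_h %||% 500),
    error = function(e) config_error(conditionMessage(e)))
  noise <- if (is.null(raw$noise)) NULL else {
    if (is.null(raw$noise$seed))
      config_error("noise block must carry an explicit seed")
    noise_model(raw$noise$kind %||% "multiplicative-lognormal",
                raw$noise$sd %||% 0, raw$noise$seed)
  }
  list(config = config, noise = noise, raw = raw)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# serialize the resolved configuration next to run outputs
write_resolved_config <- function(rc, path) {
  cfg <- rc$config
  resolved <- list(
    package_version = as.character(utils::packageVersion("percsim")),
    strain = list(name = cfg$strain$name,
                  mu_max_per_h = cfg$strain$mu_max,
                  log_ic50_log10M = cfg$strain$log_ic50,
                  hill_slope = cfg$strain$hill_slope),
    volume_ml = cfg$volume, flow_ml_per_h = cfg$flow,
    dilution_per_h = cfg$dilution,
    k_p_pct = cfg$compartments$k_p, k_a_pct = cfg$compartments$k_a,
    calibration = list(slope = cfg$calib$slope,
                       intercept = cfg$calib$intercept,
                       r_squared = cfg$calib$r_squared),
    schedule = lapply(seq_len(nrow(cfg$schedule)), function(i)
      as.list(cfg$schedule[i, ])),
    t_end_h = cfg$t_end,
    floor_np_pct = cfg$floor_np, floor_nt_pct = cfg$floor_nt,
    noise = if (is.null(rc$noise)) NULL else unclass(rc$noise)
  )
  yaml::write_yaml(resolved, path)
  invisible(path)
}

#' Run a chemostat simulation from a config file
#'
#' Reads the run config, simulates, and writes \code{simulation.csv} plus
#' the fully resolved configuration (\code{config_resolved.yaml}) to the
#' output directory. Outputs are deterministic given the config.
#'
#' @param config_path YAML/JSON run config.
#' @param out_dir output directory (created if needed).
#' @return The \code{sim_result}, invisibly.
#' @export
run_simulate <- function(config_path, out_dir) {
  rc <- read_run_config(config_path)
  sim <- simulate_chemostat(rc$config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_sim_csv(sim, file.path(out_dir, "simulation.csv"))
  write_resolved_config(rc, file.path(out_dir, "config_resolved.yaml"))
  invisible(sim)
}

fit_report <- function(fit) {
  list(log_ic50 = fit$log_ic50, hill_slope = fit$hill_slope,
       ic50_mM = 1000 * 10^fit$log_ic50,
       log_ic50_ci = as.numeric(fit$log_ic50_ci),
       residual_sse = fit$residual_sse,
       n_points = fit$n_points, source = fit$source)
}

#' Fit a dose-response curve from a plate CSV
#'
#' Normalizes the plate to its 0 mM control, fits the variable-slope
#' model, and (optionally) writes a JSON fit report.
#'
#' @param plate_path plate CSV (see [read_plate_csv()]).
#' @param out_json optional JSON report path.
#' @return The \code{dose_response_fit}, invisibly; report as attribute.
#' @export
run_fit_dr <- function(plate_path, out_json = NULL) {
  plate <- normalize_to_control(read_plate_csv(plate_path))
  fit <- fit_dose_response(plate$concentration_mM, plate$response_norm,
                           source = "endpoint")
  rep <- fit_report(fit)
  if (!is.null(out_json))
    jsonlite::write_json(rep, out_json, auto_unbox = TRUE, digits = NA)
  attr(fit, "report") <- rep
  invisible(fit)
}

#' Fit a dose-response curve from growth-curve data
#'
#' Estimates per-level growth rates from a growth CSV, normalizes to the
#' 0 mM control rate, fits the variable-slope model, and optionally writes
#' a JSON report.
#'
#' @param growth_path growth CSV (see [read_growth_csv()]).
#' @param out_json optional JSON report path.
#' @return The \code{dose_response_fit}, invisibly.
#' @export
run_fit_growth <- function(growth_path, out_json = NULL) {
  curves <- read_growth_csv(growth_path)
  rates <- estimate_growth_rate(curves)
  fit <- dose_response_from_growth_rates(rates)
  rep <- fit_report(fit)
  if (!is.null(out_json))
    jsonlite::write_json(rep, out_json, auto_unbox = TRUE, digits = NA)
  attr(fit, "report") <- rep
  invisible(fit)
}

#' Fit the sulfide calibration from a CSV
#'
#' @param calib_path calibration CSV (see [read_calibration_csv()]).
#' @param out_json optional JSON report path.
#' @param data_used passed to [fit_sulfide_calibration()].
#' @return The [sulfide_calibration()], invisibly.
#' @export
run_calibrate <- function(calib_path, out_json = NULL,
                          data_used = "points") {
  d <- read_calibration_csv(calib_path)
  cal <- fit_sulfide_calibration(d$srm_pct, d$sulfide_mM,
                                 data_used = data_used)
  rep <- list(slope = cal$slope, intercept = cal$intercept,
              r_squared = cal$r_squared,
              data_used = attr(cal, "data_used"), n = attr(cal, "n"))
  if (!is.null(out_json))
    jsonlite::write_json(rep, out_json, auto_unbox = TRUE, digits = NA)
  invisible(cal)
}

#' Generate a synthetic dataset bundle from a config file
#'
#' Writes noisy chemostat observation CSVs (one per replicate), a gradient
#' plate CSV, a growth-curve CSV, and a ground-truth sidecar JSON holding
#' the generating parameters and seed. The config must carry a noise block
#' with an explicit seed — silent nondeterminism is refused.
#'
#' @param config_path YAML/JSON run config with a \code{noise} block.
#' @param out_dir output directory.
#' @param replicates replicate observation series.
#' @return Named list of written paths, invisibly.
#' @export
run_synth <- function(config_path, out_dir, replicates = 3) {
  rc <- read_run_config(config_path)
  if (is.null(rc$noise))
    config_error("synthetic generation requires a noise block with a seed")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ts <- gen_chemostat_timeseries(rc$config, rc$noise, replicates = replicates)
  paths <- character(0)
  for (r in seq_len(replicates)) {
    p <- file.path(out_dir, sprintf("chemostat_rep%d.csv", r))
    utils::write.csv(ts$observations[ts$observations$replicate == r, ],
                     p, row.names = FALSE)
    paths <- c(paths, p)
  }
  plate <- gen_plate_gradient(rc$config$strain, noise = rc$noise,
                              replicates = replicates)
  plate_path <- file.path(out_dir, "plate_gradient.csv")
  utils::write.csv(as.data.frame(plate), plate_path, row.names = FALSE)
  curves <- gen_growth_curves(rc$config$strain,
                              perchlorate_levels = c(0, 6.25, 12.5, 25, 50, 100),
                              noise = rc$noise, replicates = replicates)
  growth_path <- file.path(out_dir, "growth_curves.csv")
  utils::write.csv(as.data.frame(curves), growth_path, row.names = FALSE)
  truth_path <- file.path(out_dir, "ground_truth.json")
  jsonlite::write_json(
    list(seed = rc$noise$seed, noise_kind = rc$noise$kind,
         noise_sd = rc$noise$sd,
         strain = list(name = rc$config$strain$name,
                       mu_max_per_h = rc$config$strain$mu_max,
                       log_ic50_log10M = rc$config$strain$log_ic50,
                       hill_slope = rc$config$strain$hill_slope),
         k_p_pct = rc$config$compartments$k_p,
         k_a_pct = rc$config$compartments$k_a,
         dilution_per_h = rc$config$dilution),
    truth_path, auto_unbox = TRUE, digits = NA)
  write_resolved_config(rc, file.path(out_dir, "config_resolved.yaml"))
  invisible(c(paths, plate = plate_path, growth = growth_path,
              truth = truth_path))
}
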