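# File formats: measured series and trajectories as commented CSV (UTF-8,
# '#' comments, units embedded in column names), calibrated parameters and
# run configuration as YAML.

#' Write / read a measured series
#'
#' Delimited text with '#' comment header lines carrying the scenario name
#' and replicate count; units are embedded in the column names
#' (\code{nh4_mM}, \code{nox_ppm}, ...; \code{*_sd} are the standard
#' deviations of the replicate means).  Write-read-write round trips are
#' byte-identical.
#'
#' @param series a \code{measured_series}.
#' @param path file path.
#' @return \code{read_measured_series} returns a \code{measured_series}.
#' @export
write_measured_series <- function(series, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(
    paste0("# nitrox measured series"),
    paste0("# scenario: ", attr(series, "scenario") %||% "unknown"),
    paste0("# n_replicates: ", attr(series, "n_replicates") %||% 1)
  ), con)
  df <- as.data.frame(series)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.10g", x))
  writeLines(paste(names(df), collapse = ","), con)
  writeLines(do.call(paste, c(df, sep = ",")), con)
  invisible(path)
}

#' @rdname write_measured_series
#' @export
read_measured_series <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  body <- grep("^#", lines, invert = TRUE, value = TRUE)
  df <- utils::read.csv(text = paste(body, collapse = "\n"),
                        check.names = FALSE)
  if (!"time_h" %in% names(df))
    stop("measured series is missing the time_h column")
  missing_an <- setdiff(SERIES_ANALYTES, names(df))
  if (length(missing_an))
    stop("measured series is missing analyte column(s): ",
         paste(missing_an, collapse = ", "))
  sc <- sub("^# scenario: *", "", grep("scenario:", meta, value = TRUE)[1])
  nr <- sub("^# n_replicates: *", "", grep("n_replicates:", meta, value = TRUE)[1])
  structure(df, class = c("measured_series", "data.frame"),
            scenario = if (is.na(sc)) "unknown" else sc,
            n_replicates = if (is.na(nr)) 1L else as.integer(nr))
}

#' Write a trajectory as a tidy delimited table
#'
#' Long format: \code{time_h, variable, compartment, value, units}; liquid
#' concentrations in M, headspace partial pressures in atm, biomass in
#' gDCW/L.
#'
#' @param traj a \code{nox_trajectory}.
#' @param path file path.
#' @export
write_trajectory <- function(traj, path) {
  st <- traj$states
  comp <- ifelse(colnames(st) %in% GAS_SPECIES, "gas",
                 ifelse(colnames(st) %in% c("x_ne", "x_nw"), "biomass",
                        "liquid"))
  units <- ifelse(comp == "gas", "atm", ifelse(comp == "biomass",
                                               "gDCW/L", "M"))
  long <- data.frame(
    time_h = rep(traj$time, ncol(st)),
    variable = rep(colnames(st), each = nrow(st)),
    compartment = rep(comp, each = nrow(st)),
    value = sprintf("%.10g", as.vector(st)),
    units = rep(units, each = nrow(st))
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(paste0("# nitrox trajectory: ", traj$scenario$name), con)
  writeLines(paste(names(long), collapse = ","), con)
  writeLines(do.call(paste, c(long, sep = ",")), con)
  invisible(path)
}

#' Write / read calibrated parameters
#'
#' YAML with per-organism blocks and a provenance map (which values are
#' literature constants and which were fitted).
#'
#' @param calib a \code{\link{calibrated_params}}.
#' @param path file path.
#' @export
write_calibrated_params <- function(calib, path) {
  obj <- list(ne = calib$ne, nw = calib$nw)
  obj <- obj[!vapply(obj, is.null, logical(1))]
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_calibrated_params
#' @export
read_calibrated_params <- function(path) {
  obj <- yaml::read_yaml(path)
  fix_prov <- function(p) {
    if (!is.null(p$provenance)) p$provenance <- unlist(p$provenance)
    for (f in c("vmax_nh3", "vmax_no2"))
      if (is.list(p[[f]]) && !is.null(p[[f]]$vmax)) {
        p[[f]]$breaks <- as.numeric(unlist(p[[f]]$breaks))
        p[[f]]$vmax <- as.numeric(unlist(p[[f]]$vmax))
      }
    p
  }
  calibrated_params(
    ne = if (!is.null(obj$ne)) fix_prov(obj$ne),
    nw = if (!is.null(obj$nw)) fix_prov(obj$nw)
  )
}

RUN_CONFIG_KEYS <- c("scenario", "candidate_mode", "hao_mode", "t_end",
                     "dt_report", "seed", "constants", "out_dir", "verbose",
                     "sample_dt", "noise_sds", "n_replicates")

#' Read and validate a run configuration
#'
#' YAML file; unknown keys are rejected with a message naming them.
#' Recognized keys: \code{scenario} (fixture name), \code{candidate_mode},
#' \code{hao_mode}, \code{t_end}, \code{dt_report}, \code{seed},
#' \code{constants} (registry overrides), \code{out_dir}, \code{verbose},
#' \code{sample_dt}, \code{noise_sds}, \code{n_replicates}.
#'
#' @param path YAML file path.
#' @return validated configuration list with defaults filled in.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  unknown <- setdiff(names(cfg), RUN_CONFIG_KEYS)
  if (length(unknown))
    stop("unknown configuration key(s) in ", path, ": ",
         paste(unknown, collapse = ", "))
  cfg$scenario <- cfg$scenario %||% "ne_single"
  cfg$candidate_mode <- cfg$candidate_mode %||% "final"
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$out_dir <- cfg$out_dir %||% "."
  cfg$verbose <- isTRUE(cfg$verbose)
  cfg
}

# scenario object from a validated config
#' @keywords internal
#' @noRd
scenario_from_config <- function(cfg) {
  constants <- nox_constants(cfg$constants)
  sc <- make_fixture_scenarios(constants)[[cfg$scenario]]
  if (is.null(sc)) stop("unknown scenario: ", cfg$scenario)
  sc$candidate_mode <- cfg$candidate_mode
  if (!is.null(cfg$hao_mode)) sc$hao_mode <- cfg$hao_mode
  if (!is.null(cfg$t_end)) sc$t_end <- cfg$t_end
  if (!is.null(cfg$dt_report)) sc$dt_report <- cfg$dt_report
  sc
}

#' Run a simulation from a configuration file
#'
#' Writes the trajectory table, the NO source/sink flux table, a peak
#' summary (peak NOx, N2O, NH2OH and their times) and a structured run log
#' into the configured output directory.  Reruns with the same
#' configuration and seed are byte-identical.
#'
#' @param config path to a YAML run configuration.
#' @return invisibly, the summary list.
#' @export
cli_simulate <- function(config) {
  cfg <- read_run_config(config)
  sc <- scenario_from_config(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  traj <- simulate_scenario(sc)
  s <- trajectory_summary(traj)
  write_trajectory(traj, file.path(cfg$out_dir,
                                   paste0(sc$name, "_trajectory.csv")))
  dec <- no_source_sink_decomposition(traj)
  dec_out <- dec
  dec_out[] <- lapply(dec_out, function(x) sprintf("%.10g", x))
  con <- file(file.path(cfg$out_dir, paste0(sc$name, "_no_fluxes.csv")), "wb")
  writeLines(paste(names(dec_out), collapse = ","), con)
  writeLines(do.call(paste, c(dec_out, sep = ",")), con)
  close(con)
  summary_lines <- c(
    paste0("scenario: ", sc$name),
    paste0("candidate_mode: ", sc$candidate_mode),
    sprintf("peak_nox_ppm: %.6g", s$peak_nox_ppm),
    sprintf("t_peak_nox_h: %.6g", s$t_nox),
    sprintf("peak_n2o_ppm: %.6g", s$peak_n2o_ppm),
    sprintf("t_peak_n2o_h: %.6g", s$t_n2o),
    sprintf("peak_nh2oh_um: %.6g", s$peak_nh2oh_um),
    sprintf("t_peak_nh2oh_h: %.6g", s$t_nh2oh)
  )
  writeLines(summary_lines,
             file.path(cfg$out_dir, paste0(sc$name, "_summary.yaml")))
  if (cfg$verbose) message(paste(summary_lines, collapse = "\n"))
  invisible(s)
}

#' Calibrate against a measured series from the command line
#'
#' @param config path to a YAML run configuration.
#' @param data path to a measured-series CSV.
#' @return invisibly, the calibrated parameters (also written to
#'   \code{<scenario>_calibrated.yaml} in the output directory).
#' @export
cli_calibrate <- function(config, data) {
  cfg <- read_run_config(config)
  sc <- scenario_from_config(cfg)
  series <- read_measured_series(data)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  calib <- calibrate_scenario(sc, series)
  write_calibrated_params(calib, file.path(cfg$out_dir,
                                           paste0(sc$name, "_calibrated.yaml")))
  invisible(calib)
}

#' Generate synthetic measured series for all fixture scenarios
#'
#' @param config path to a YAML run configuration (the seed and optional
#'   noise settings apply to every scenario).
#' @return invisibly, the vector of files written (one per scenario).
#' @export
cli_synth <- function(config) {
  cfg <- read_run_config(config)
  constants <- nox_constants(cfg$constants)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (sc in make_fixture_scenarios(constants)) {
    if (!is.null(cfg$t_end)) sc$t_end <- cfg$t_end
    if (!is.null(cfg$dt_report)) sc$dt_report <- cfg$dt_report
    noise <- noise_model(sc$name, sds = cfg$noise_sds,
                         n_replicates = cfg$n_replicates %||% 4)
    ser <- generate_timeseries(sc, noise = noise, seed = cfg$seed,
                               sample_dt = cfg$sample_dt %||% 1)
    f <- file.path(cfg$out_dir, paste0(sc$name, "_series.csv"))
    write_measured_series(ser, f)
    files <- c(files, f)
  }
  invisible(files)
}
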