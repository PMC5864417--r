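# Synthetic pseudo-experimental data: hourly-sampled batch time series with
# the structure of the closed-vial experiments (liquid N species, headspace
# NOx and N2O, extracellular NH2OH), with replicate Gaussian noise at the
# magnitudes of the experimental error bars.

#' Measurement noise model
#'
#' Additive Gaussian noise per analyte, applied per replicate and clamped at
#' zero; reported series are means +/- SD of \code{n} replicates.  Default
#' SDs match the experimental error bars of the corresponding scenario
#' (errors differ strongly between experiments, e.g. headspace NOx error is
#' a few ppm where tens of ppm accumulate but ~0.1 ppm in the
#' N. winogradskyi culture where only ~1.5 ppm accumulates).
#'
#' @param scenario scenario name the defaults refer to.
#' @param sds optional named replacement SDs; names among
#'   \code{nh4_mM, no2_mM, no3_mM, nh2oh_uM, nox_ppm, n2o_ppm}.
#' @param n_replicates number of replicates (default 4).
#' @return object of class \code{nox_noise}.
#' @export
noise_model <- function(scenario = c("ne_single", "nw_single", "coculture",
                                     "abiotic_control"),
                        sds = NULL, n_replicates = 4) {
  scenario <- match.arg(scenario)
  base <- switch(scenario,
    ne_single = c(nh4_mM = 0.1, no2_mM = 0.1, no3_mM = 0,
                  nh2oh_uM = 3.1, nox_ppm = 5.7, n2o_ppm = 0.9),
    nw_single = c(nh4_mM = 0, no2_mM = 0.15, no3_mM = 0.15,
                  nh2oh_uM = 0, nox_ppm = 0.12, n2o_ppm = 0.04),
    coculture = c(nh4_mM = 0.1, no2_mM = 0.1, no3_mM = 0.1,
                  nh2oh_uM = 7.5, nox_ppm = 2.2, n2o_ppm = 4.1),
    abiotic_control = c(nh4_mM = 0.05, no2_mM = 0.1, no3_mM = 0.05,
                        nh2oh_uM = 0.5, nox_ppm = 0.1, n2o_ppm = 0.04))
  if (!is.null(sds)) {
    sds <- unlist(sds)
    unknown <- setdiff(names(sds), names(base))
    if (length(unknown)) stop("unknown analyte(s): ",
                              paste(unknown, collapse = ", "))
    base[names(sds)] <- sds
  }
  if (any(base < 0) || n_replicates < 1) stop("invalid noise model")
  structure(list(sds = base, n_replicates = n_replicates,
                 scenario = scenario), class = "nox_noise")
}

SERIES_ANALYTES <- c("nh4_mM", "no2_mM", "no3_mM", "nh2oh_uM",
                     "nox_ppm", "n2o_ppm")

# noise-free analyte table on a sampling grid, from a trajectory
#' @keywords internal
#' @noRd
sample_trajectory <- function(traj, times) {
  idx <- vapply(times, function(t) which.min(abs(traj$time - t)), integer(1))
  st <- traj$states[idx, , drop = FALSE]
  p <- traj$geometry$pressure
  data.frame(
    time_h = traj$time[idx],
    nh4_mM = st[, "nh4"] * 1e3,
    no2_mM = st[, "no2"] * 1e3,
    no3_mM = st[, "no3"] * 1e3,
    nh2oh_uM = st[, "nh2oh"] * 1e6,
    nox_ppm = atm_to_ppm(st[, "g_no"] + st[, "g_no2"], p),
    n2o_ppm = atm_to_ppm(st[, "g_n2o"], p)
  )
}

#' Generate a pseudo-experimental measured series
#'
#' Simulates the scenario, samples it on a regular grid (hourly by default)
#' and adds seeded per-replicate Gaussian noise, returning the mean +/- SD
#' over replicates in the package's measured-series layout.  Identical seed,
#' scenario and noise model give identical output.
#'
#' @param scenario a \code{\link{nox_scenario}}.
#' @param calib calibrated parameters (defaults to the scenario's).
#' @param noise a \code{\link{noise_model}}; defaults to the scenario's
#'   printed error magnitudes.
#' @param seed integer random seed.
#' @param sample_dt sampling interval (h).
#' @param traj optional pre-computed trajectory (skips re-simulation).
#' @return a \code{measured_series}: data.frame with \code{time_h}, a mean
#'   and an \code{_sd} column per analyte, and attributes
#'   \code{n_replicates} and \code{scenario}.
#' @export
generate_timeseries <- function(scenario, calib = scenario$calib,
                                noise = NULL, seed = 1, sample_dt = 1,
                                traj = NULL) {
  if (is.null(noise))
    noise <- tryCatch(noise_model(scenario$name),
                      error = function(e) noise_model("ne_single"))
  if (is.null(traj)) traj <- simulate_scenario(scenario, calib)
  times <- seq(0, scenario$t_end, by = sample_dt)
  truth <- sample_trajectory(traj, times)

  set.seed(as.integer(seed) %% .Machine$integer.max)
  n <- noise$n_replicates
  out <- data.frame(time_h = truth$time_h)
  for (an in SERIES_ANALYTES) {
    reps <- vapply(seq_len(n), function(r) {
      pmax(truth[[an]] + stats::rnorm(nrow(truth), 0, noise$sds[[an]]), 0)
    }, numeric(nrow(truth)))
    reps <- matrix(reps, nrow = nrow(truth))
    out[[an]] <- rowMeans(reps)
    out[[sub("_[^_]+$", "_sd", an)]] <- apply(reps, 1, stats::sd)
  }
  structure(out, class = c("measured_series", "data.frame"),
            n_replicates = n, scenario = scenario$name)
}
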