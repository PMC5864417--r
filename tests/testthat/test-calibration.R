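# Calibration: slope-based Vmax, segment detection, Km bisection and the
# kinetic-bound fits.

make_series <- function(time_h, conc_mM, col = "nh4_mM") {
  df <- data.frame(time_h = time_h)
  for (an in nitrox:::SERIES_ANALYTES) df[[an]] <- 0
  df[[col]] <- conc_mM
  structure(df, class = c("measured_series", "data.frame"),
            n_replicates = 1L, scenario = "constructed")
}

test_that("Vmax from a linear decline matches the hand-computed slope", {
  # 5 mM -> 0 over 4 h at X = 0.07 gDCW/L: slope 1.25 mM/h -> 17.857
  ser <- make_series(0:4, c(5, 3.75, 2.5, 1.25, 0))
  v <- vmax_from_segments(ser, "nh4", X = 0.07, segments = 0)
  expect_equal(v$vmax, 1.25 / 0.07, tolerance = 1e-9)
  # flat series -> 0 (floored)
  ser0 <- make_series(0:4, rep(3, 5))
  expect_equal(vmax_from_segments(ser0, "nh4", 0.07, 0)$vmax, 0)
  # slope is invariant under adding a constant
  ser_shift <- make_series(0:4, c(5, 3.75, 2.5, 1.25, 0) + 2)
  expect_equal(vmax_from_segments(ser_shift, "nh4", 0.07, 0)$vmax,
               v$vmax, tolerance = 1e-9)
})

test_that("per-segment slopes recover a two-rate consumption curve", {
  tt <- 0:6
  yy <- ifelse(tt <= 2, 10 - 2 * tt, 6 - 1 * (tt - 2))   # slopes -2 then -1
  ser <- make_series(tt, yy)
  v <- vmax_from_segments(ser, "nh4", X = 0.1, segments = c(0, 2))
  expect_equal(v$vmax, c(20, 10), tolerance = 1e-9)
  expect_equal(detect_segments(ser, "nh4"), c(0, 2))
  expect_error(vmax_from_segments(make_series(c(0, 1), c(5, 4)), "nh4",
                                  0.1, c(0, 0.5)), "fewer than 2")
})

test_that("larger Km leaves more residual substrate (bisection precondition)", {
  sc <- quick_ne_scenario(4)
  finals <- vapply(c(1e-5, 1e-4, 1e-3), function(km) {
    calib <- sc$calib
    calib$ne$km_nh4 <- km
    tr <- simulate_scenario(sc, calib, rtol = 1e-4, dt_report = 0.5)
    tr$states[nrow(tr$states), "nh4"]
  }, numeric(1))
  expect_true(all(diff(finals) > 0))
})

test_that("fit_km recovers the generating Km from noise-free data", {
  sc <- quick_ne_scenario(4)
  km_true <- 8e-5
  calib <- sc$calib
  calib$ne$km_nh4 <- km_true
  tr <- simulate_scenario(sc, calib, rtol = 1e-5, dt_report = 0.25)
  target <- tr$states[nrow(tr$states), "nh4"]
  km_hat <- fit_km(sc, "nh4", target_final = target, rtol = 1e-5)
  expect_equal(km_hat, km_true, tolerance = 0.10)
  # unreachable target errors with the bracketing values
  expect_error(fit_km(sc, "nh4", target_final = 4.9e-3,
                      bounds = c(1e-7, 1e-5)), "range")
})

test_that("fit_hao_cap recovers the spill capacity from noise-free data", {
  sc <- quick_ne_scenario(4)
  cap_true <- 22.6
  calib <- sc$calib
  calib$ne$hao_cap <- cap_true
  tr <- simulate_scenario(sc, calib)
  nm0 <- noise_model("ne_single", sds = c(nh4_mM = 0, no2_mM = 0, no3_mM = 0,
                                          nh2oh_uM = 0, nox_ppm = 0,
                                          n2o_ppm = 0))
  ser <- generate_timeseries(sc, calib, noise = nm0, seed = 1, traj = tr)
  cap_hat <- fit_hao_cap(sc, ser)
  expect_equal(cap_hat, cap_true, tolerance = 0.02)
})

test_that("slope-derived Vmax stays within 15% across 20 noisy seeds", {
  sc <- make_fixture_scenarios()$ne_single
  truth <- sc$calib$ne$vmax_nh3$vmax
  tr <- simulate_scenario(sc)
  X <- sc$init[["x_ne"]]
  for (seed in 1:20) {
    ser <- generate_timeseries(sc, seed = seed, traj = tr)
    v <- vmax_from_segments(ser, "nh4", X, segments = c(0, 1))
    expect_equal(v$vmax[1], truth[1], tolerance = 0.15,
                 label = paste("seed", seed, "segment 1"))
    expect_equal(v$vmax[2], truth[2], tolerance = 0.15,
                 label = paste("seed", seed, "segment 2"))
  }
})
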