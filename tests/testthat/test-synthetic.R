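# Synthetic-data generator: fixture scenarios, determinism, noise behavior.

test_that("fixture scenarios carry the experimental initial conditions", {
  sc <- make_fixture_scenarios()
  expect_equal(sc$ne_single$init[["nh4"]], 5e-3)     # 2.5 mM (NH4)2SO4
  expect_equal(sc$ne_single$inocula[["ne"]], 0.2)
  expect_equal(sc$nw_single$init[["no2"]], 5e-3)     # 5 mM NaNO2
  expect_equal(sc$nw_single$inocula[["nw"]], 0.05)
  expect_equal(sum(sc$coculture$inocula), 0.25)      # 0.2 + 0.05
  expect_equal(sc$abiotic_control$init[["x_ne"]] +
                 sc$abiotic_control$init[["x_nw"]], 0)
  g <- sc$ne_single$geometry
  expect_equal(g$v_liquid, 0.005)
  expect_equal(g$v_liquid + g$v_gas, 0.160)
  expect_equal(g$temperature, 303.15)
  expect_equal(sc$ne_single$t_end, 10)
})

test_that("generation is deterministic in the seed", {
  sc <- quick_ne_scenario(3)
  tr <- simulate_scenario(sc)
  a <- generate_timeseries(sc, seed = 42, traj = tr)
  b <- generate_timeseries(sc, seed = 42, traj = tr)
  d <- generate_timeseries(sc, seed = 43, traj = tr)
  expect_identical(a, b)
  expect_false(isTRUE(all.equal(a$nox_ppm, d$nox_ppm)))
})

test_that("zero noise reproduces the simulation at the sample times", {
  sc <- quick_ne_scenario(3)
  tr <- simulate_scenario(sc)
  nm <- noise_model("ne_single", sds = c(nh4_mM = 0, no2_mM = 0, no3_mM = 0,
                                         nh2oh_uM = 0, nox_ppm = 0,
                                         n2o_ppm = 0))
  ser <- generate_timeseries(sc, noise = nm, seed = 1, traj = tr)
  truth <- nitrox:::sample_trajectory(tr, ser$time_h)
  expect_equal(ser$nox_ppm, truth$nox_ppm)
  expect_equal(ser$nh4_mM, truth$nh4_mM)
  expect_true(all(ser$nox_sd == 0))
})

test_that("replicate spread matches the configured SD (Monte Carlo)", {
  sc <- quick_ne_scenario(3)
  tr <- simulate_scenario(sc)
  nm <- noise_model("ne_single", n_replicates = 1000)
  ser <- generate_timeseries(sc, noise = nm, seed = 7, traj = tr)
  i <- which.max(ser$nox_ppm)     # far from the clamp at zero
  expect_equal(ser$nox_sd[i], 5.7, tolerance = 0.1)
  expect_equal(ser$n2o_sd[i], 0.9, tolerance = 0.1)
})

test_that("values are clamped at zero and SDs are per-scenario", {
  expect_true(all(as.data.frame(generate_timeseries(
    make_fixture_scenarios()$abiotic_control, seed = 3)) >= 0))
  expect_lt(noise_model("nw_single")$sds[["nox_ppm"]],
            noise_model("ne_single")$sds[["nox_ppm"]])
  expect_equal(noise_model("ne_single")$n_replicates, 4)
  expect_error(noise_model("ne_single", sds = c(bogus = 1)), "unknown")
})

test_that("generated coculture series show the reported qualitative shapes", {
  sc <- make_fixture_scenarios()$coculture
  ser <- generate_timeseries(sc, seed = 11)
  # NOx transient: rises during active oxidation, peaks well after the
  # start, declines by the end of the run
  ipk <- which.max(ser$nox_ppm)
  expect_gt(ser$time_h[ipk], 1.5)
  expect_lt(ser$time_h[ipk], 5.5)
  expect_lt(ser$nox_ppm[nrow(ser)], ser$nox_ppm[ipk])
  # nitrite transient: accumulates to > 2 mM and is consumed by ~8 h
  expect_gt(max(ser$no2_mM), 2)
  expect_lt(ser$no2_mM[ser$time_h == 8], 0.5)
})
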