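# Dynamic FBA engine: Monod kinetics, objective schedules, right-hand side
# consistency, conservation, and the NO source/sink decomposition.

test_that("Monod uptake bound has the saturation properties", {
  expect_equal(monod_uptake_bound(10, 1e-5, 0), 0)
  expect_equal(monod_uptake_bound(10, 1e-5, 1e-5), 5)       # half-saturation
  expect_gt(monod_uptake_bound(10, 1e-5, 1e-2), 9.99)       # saturation
  expect_equal(monod_uptake_bound(10, 1e-5, -1e-9), 0)      # clamp
})

test_that("objective schedules resolve the documented windows", {
  sf <- objective_schedule("final")
  expect_equal(objective_for_time(sf, 0.1)[1], "nh3_uptake")  # first 15 min
  expect_equal(objective_for_time(sf, 0.3)[1], "biomass")
  s2 <- objective_schedule("model2")
  expect_equal(objective_for_time(s2, 1.0), "no2_production")
  expect_equal(objective_for_time(s2, 3.0)[1], "biomass")
  s1 <- objective_schedule("model1")
  for (t in c(0, 1, 5, 10))
    expect_equal(objective_for_time(s1, t), "biomass")
  expect_error(objective_for_time(sf, 11), "horizon")
})

test_that("with no biomass the combined RHS reduces to the abiotic RHS", {
  sc <- make_fixture_scenarios()$coculture
  sc$init[["x_ne"]] <- 0; sc$init[["x_nw"]] <- 0
  ctx <- build_engine(sc)
  y <- sc$init
  y[["no"]] <- 1e-5; y[["g_no"]] <- 2e-5
  d <- combined_rhs(1, y, ctx)[[1]]
  d_abio <- 3600 * abiotic_rhs(y[nitrox:::ABIO_STATES], ctx$kv, ctx$geom)
  expect_equal(unname(d[seq_along(d_abio)]), unname(d_abio))
  expect_equal(unname(d[c("x_ne", "x_nw")]), c(0, 0))
})

test_that("without ammonium an N. europaea culture makes no N oxides", {
  sc <- make_fixture_scenarios()$ne_single
  sc$init[["nh4"]] <- 0
  sc$t_end <- 3
  tr <- simulate_scenario(sc)
  expect_true(all(tr$states[, c("nh2oh", "no", "n2o", "g_no", "g_no2",
                                "g_n2o")] < 1e-12))
})

test_that("RHS matches finite differences of a short integration step", {
  sc <- quick_ne_scenario()
  ctx <- build_engine(sc)
  tr <- simulate_scenario(sc, rtol = 1e-7)
  i <- which.min(abs(tr$time - 0.5))
  y <- tr$states[i, ]
  d <- combined_rhs(0.5, y, ctx)[[1]]
  dt <- 1e-5
  sol <- deSolve::lsoda(y, c(0.5, 0.5 + dt),
                        function(t, y, p) combined_rhs(t, y, ctx),
                        NULL, rtol = 1e-10, atol = 1e-16)
  fd <- (sol[2, 1 + seq_along(y)] - y) / dt
  expect_equal(unname(fd), unname(d), tolerance = 1e-4)
})

test_that("total N (including biomass N) is conserved to 0.1% in all scenarios", {
  for (sc in make_fixture_scenarios()) {
    tr <- simulate_scenario(sc)
    n <- trajectory_nitrogen(tr)
    expect_lt((max(n) - min(n)) / max(n[1], 1e-12), 1e-3, label = sc$name)
  }
})

test_that("halving integrator tolerances moves the reported peaks by < 1%", {
  sc <- make_fixture_scenarios()$ne_single
  s1 <- trajectory_summary(simulate_scenario(sc, rtol = 1e-6, atol = 1e-12))
  s2 <- trajectory_summary(simulate_scenario(sc, rtol = 5e-7, atol = 5e-13))
  expect_equal(s1$peak_nox_ppm, s2$peak_nox_ppm, tolerance = 0.01)
  expect_equal(s1$peak_n2o_ppm, s2$peak_n2o_ppm, tolerance = 0.01)
  expect_equal(s1$peak_nh2oh_um, s2$peak_nh2oh_um, tolerance = 0.01)
})

test_that("NO decomposition closes against the derivative of the NO pool", {
  sc <- quick_ne_scenario(6)
  tr <- simulate_scenario(sc)
  dec <- no_source_sink_decomposition(tr)
  geom <- tr$geometry
  RT <- 0.082057 * geom$temperature
  no_umol <- (tr$states[, "no"] * geom$v_liquid +
                tr$states[, "g_no"] * geom$v_gas / RT) * 1e6
  n <- length(no_umol)
  # integral closure: the accumulated net source/sink balance reproduces
  # the total change of the NO pool
  dt <- diff(tr$time)
  integral <- sum((dec$net[-1] + dec$net[-n]) / 2 * dt)
  expect_lt(abs(integral - (no_umol[n] - no_umol[1])), 0.02 * max(no_umol))
  # pointwise closure away from structural switch times (uptake-segment
  # boundary, substrate exhaustion), where the instantaneous rates are
  # discontinuous and a centered difference straddles the jump
  fd <- (no_umol[-(1:2)] - no_umol[-((n - 1):n)]) /
    (tr$time[-(1:2)] - tr$time[-((n - 1):n)])
  net <- dec$net[-c(1, n)]
  tt <- tr$time[-c(1, n)]
  nh4 <- tr$states[, "nh4"] * 1e3
  t_done <- if (any(nh4 < 0.05)) tr$time[min(which(nh4 < 0.05))] else Inf
  interior <- !(abs(tt - 0.25) < 0.2 | abs(tt - 1) < 0.2 |
                  abs(tt - t_done) < 0.3)
  scale <- max(abs(fd))
  expect_gt(scale, 0)
  expect_lt(max(abs(net - fd)[interior]) / scale, 0.05)
})

test_that("abiotic-only runs have identically zero biotic decomposition series", {
  tr <- simulate_scenario(make_fixture_scenarios()$abiotic_control)
  dec <- no_source_sink_decomposition(tr)
  expect_true(all(dec$ne_nir == 0 & dec$ne_nor_p460 == 0 & dec$nw_nir == 0 &
                    dec$ne_hao == 0))
})

test_that("in an N. europaea culture NIR+HAO are sources and the aqueous sink consumes", {
  tr <- simulate_scenario(quick_ne_scenario(6))
  dec <- no_source_sink_decomposition(tr)
  expect_true(all(dec$ne_nir + dec$ne_hao >= 0))
  expect_true(all(dec$abiotic_aqueous <= 1e-12))
  expect_true(all(dec$ne_nor_p460 <= 1e-12))
})

test_that("seeding NO in an abiotic vial oxidizes it with N conserved", {
  sc <- nox_scenario("abiotic_no", init_headspace = list(g_no = 30))
  tr <- simulate_scenario(sc)
  last <- nrow(tr$states)
  expect_lt(tr$states[last, "g_no"], tr$states[1, "g_no"] * 0.5)
  expect_gt(tr$states[last, "g_no2"], 0)
  expect_gt(tr$states[last, "no2"], 0)
  n <- trajectory_nitrogen(tr)
  expect_lt((max(n) - min(n)) / n[1], 1e-3)
})

test_that("hydroxylamine peaks near 1 h and is gone by 4 h (final model)", {
  tr <- simulate_scenario(make_fixture_scenarios()$ne_single)
  s <- trajectory_summary(tr)
  expect_gt(s$peak_nh2oh_um, 20)
  expect_lt(abs(s$t_nh2oh - 1), 0.3)
  at4 <- tr$states[which.min(abs(tr$time - 4)), "nh2oh"] * 1e6
  expect_lt(at4, 2)
})

test_that("candidate model 1 spills hydroxylamine transiently, model 2 stays < 5 uM", {
  sc <- make_fixture_scenarios()$coculture
  sc$t_end <- 5
  sc1 <- sc; sc1$candidate_mode <- "model1"
  sc2 <- sc; sc2$candidate_mode <- "model2"
  p1 <- max(simulate_scenario(sc1)$states[, "nh2oh"]) * 1e6
  p2 <- max(simulate_scenario(sc2)$states[, "nh2oh"]) * 1e6
  expect_gt(p1, 20)
  expect_lt(p2, 5)
})

test_that("coculture dissolved O2 dips below both single cultures", {
  scs <- make_fixture_scenarios()
  mins <- vapply(scs[c("ne_single", "nw_single", "coculture")], function(sc) {
    min(simulate_scenario(sc)$states[, "o2"])
  }, numeric(1))
  expect_lt(mins[["coculture"]], mins[["ne_single"]])
  expect_lt(mins[["coculture"]], mins[["nw_single"]])
})

test_that("coculture N-oxide peak exceeds the summed single-culture peaks", {
  scs <- make_fixture_scenarios()
  peak <- function(nm) {
    s <- trajectory_summary(simulate_scenario(scs[[nm]]))
    c(s$peak_nox_ppm, s$peak_n2o_ppm)
  }
  co <- peak("coculture"); ne <- peak("ne_single"); nw <- peak("nw_single")
  expect_gt(sum(co), sum(ne) + sum(nw))
})

test_that("headspace HONO is a negligible fraction of headspace NOx", {
  tr <- simulate_scenario(quick_ne_scenario(6))
  kv <- tr$kv
  f_hono <- hono_fraction(tr$scenario$pH, kv[["pka_hono"]])
  expect_lt(f_hono, 1e-4)
  # HONO is very soluble: the headspace mixing ratio it could reach at
  # gas-liquid equilibrium, at the largest nitrite pool of the run, is far
  # below the NOx the analyzer sees
  p_hono_eq <- f_hono * max(tr$states[, "no2"]) / kv[["H_hono"]]
  peak_nox_atm <- max(tr$states[, "g_no"] + tr$states[, "g_no2"])
  expect_lt(p_hono_eq / peak_nox_atm, 1e-3)
})
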