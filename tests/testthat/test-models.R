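# Core metabolic/energy models and the FBA interface.

test_that("interior reactions of both organisms balance N and O", {
  expect_true(audit_elements(build_ne_model()))
  expect_true(audit_elements(build_ne_model("three_electron_NO")))
  expect_true(audit_elements(build_nw_model("SIMPLE")))
  expect_true(audit_elements(build_nw_model("POUGHON")))
})

test_that("ATP yield per nitrite matches the two energy variants", {
  expect_equal(atp_yield_per_no2(build_nw_model("SIMPLE")), 0.667,
               tolerance = 0.005)
  expect_equal(atp_yield_per_no2(build_nw_model("POUGHON")), 1.53,
               tolerance = 0.005)
  ratio <- atp_yield_per_no2(build_nw_model("POUGHON")) /
    atp_yield_per_no2(build_nw_model("SIMPLE"))
  expect_equal(ratio, 2.29, tolerance = 0.01)
})

test_that("HAO modes differ by exactly one recovered electron per NH2OH", {
  e4 <- build_ne_model("four_electron")$reactions$HAO$stoich[["e"]]
  e3 <- build_ne_model("three_electron_NO")$reactions$HAO$stoich[["e"]]
  expect_equal(e4 - e3, 1)
  # and the three-electron mode yields NO, not nitrite
  st3 <- build_ne_model("three_electron_NO")$reactions$HAO$stoich
  expect_true("no" %in% names(st3) && !"no2" %in% names(st3))
})

test_that("starvation with positive maintenance is infeasible", {
  ne <- build_ne_model()
  ne <- set_bounds(ne, "EX_nh3", lb = 0, ub = 0)
  fm <- fba_solve(ne, "biomass")
  expect_equal(fm$status, "infeasible")
  # with maintenance released the zero flux vector is optimal
  ne0 <- set_bounds(ne, "NGAM", lb = 0)
  for (ex in grep("^EX_", names(ne0$reactions), value = TRUE))
    ne0 <- set_bounds(ne0, ex, lb = 0, ub = 0)
  fm0 <- fba_solve(ne0, "biomass")
  expect_equal(fm0$status, "optimal")
  expect_true(all(abs(fm0$fluxes) < 1e-9))
})

test_that("fba_solve matches the enumeration oracle on a 5-reaction toy model", {
  # A -> B -> C with a branch B -> D; uptake of A bounded, objective on C
  rx <- list(
    UPT = list(stoich = c(A = 1), lb = 0, ub = 4),
    R1  = list(stoich = c(A = -1, B = 1), lb = 0, ub = 10),
    R2  = list(stoich = c(B = -1, C = 1), lb = 0, ub = 3),
    R3  = list(stoich = c(B = -1, D = 1), lb = 0, ub = 10),
    OUTC = list(stoich = c(C = -1), lb = 0, ub = 10),
    OUTD = list(stoich = c(D = -1), lb = 0, ub = 10)
  )
  toy <- nitrox:::new_core_model("toy", rx,
                                 objectives = list(c_out = c(OUTC = 1)),
                                 maintenance = list(ngam = 0, gam = 0))
  fm <- fba_solve(toy, "c_out")
  want <- enumerate_lp(c(0, 0, 0, 0, 1, 0), toy$S, rep(0, nrow(toy$S)),
                       toy$lb, toy$ub)
  expect_equal(fm$objective, want$value)   # = min(4, 3) = 3
  expect_equal(fm$objective, 3)
})

test_that("steady-state mass balance holds for optimal flux maps", {
  ne <- set_bounds(build_ne_model(), "EX_nh3", lb = -20, ub = -20)
  fm <- fba_solve(ne, "biomass")
  expect_lt(max(abs(ne$S %*% fm$fluxes)), 1e-7)
})

test_that("objective value is monotone in the uptake bound", {
  ne <- build_ne_model()
  vals <- vapply(c(16, 18, 20, 25), function(u) {
    fba_solve(ne, "biomass", uptake_bounds = c(nh3 = u),
              tie_break = FALSE)$objective
  }, numeric(1))
  expect_true(all(diff(vals) >= -1e-10))
})

test_that("with NIR and NOR shut, N. europaea makes no NO or N2O", {
  ne <- build_ne_model()
  ne <- set_bounds(ne, "NIR", ub = 0)
  ne <- set_bounds(ne, "NOR", ub = 0)
  ne <- set_bounds(ne, "P460", ub = 0)
  ne <- set_bounds(ne, "EX_nh3", lb = -20, ub = -20)
  fm <- fba_solve(ne, "biomass")
  expect_equal(unname(fm$fluxes[["EX_no"]]), 0, tolerance = 1e-9)
  expect_equal(unname(fm$fluxes[["EX_n2o"]]), 0, tolerance = 1e-9)
})

test_that("the N. winogradskyi model cannot produce N2O in either variant", {
  for (v in c("SIMPLE", "POUGHON")) {
    nw <- build_nw_model(v)
    expect_false("n2o" %in% nw$mets)
    expect_false(any(grepl("NOR", names(nw$reactions))))
  }
})

test_that("exchange fluxes scale linearly with biomass density", {
  ne <- set_bounds(build_ne_model(), "EX_nh3", lb = -20, ub = -20)
  fm <- fba_solve(ne, "biomass")
  expect_true(all(exchange_fluxes(fm, 0) == 0))
  j1 <- exchange_fluxes(fm, 0.07)
  expect_equal(exchange_fluxes(fm, 0.14), 2 * j1)
})

test_that("secreted plus assimilated N equals consumed N at steady state", {
  ne <- set_bounds(build_ne_model(), "EX_nh3", lb = -20, ub = -20)
  fm <- fba_solve(ne, "biomass")
  fl <- fm$fluxes
  n_in <- -fl[["EX_nh3"]]
  n_out <- fl[["EX_no2"]] + fl[["EX_no"]] + 2 * fl[["EX_n2o"]] +
    fl[["EX_nh2oh"]]
  n_biomass <- 10 * fl[["BIOMASS"]]
  expect_equal(unname(n_in), unname(n_out + n_biomass), tolerance = 1e-8)
})
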