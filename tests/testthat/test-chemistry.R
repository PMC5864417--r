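# Abiotic reactor chemistry: unit conversions, rate laws, speciation,
# mass transfer and the assembled abiotic right-hand side.

test_that("ppm/atm conversion matches its definition and inverts exactly", {
  expect_equal(ppm_to_atm(0, 1), 0)
  expect_equal(ppm_to_atm(1e6, 1), 1)
  expect_equal(ppm_to_atm(30.2, 1), 3.02e-5)
  x <- c(0.3, 1.5, 53.7)
  expect_equal(atm_to_ppm(ppm_to_atm(x, 0.98), 0.98), x)
  expect_error(ppm_to_atm(-1), "nonnegative")
})

test_that("two-film flux is zero at Henry equilibrium and signed correctly", {
  H <- 1.3e-3; K <- 1e-3
  expect_equal(gas_liquid_flux(H * 0.2, 0.2, H, K), 0)
  expect_lt(gas_liquid_flux(1e-4, 0, H, K), 0)       # outgassing
  expect_equal(gas_liquid_flux(0, 0.2, H, K), 2.6e-7)  # K * H * p
})

test_that("overall transfer coefficient combines film resistances in series", {
  geom <- reactor_geometry()
  K1 <- overall_transfer_coefficient(1e-5, 1e30, 1.3e-3, geom)
  # gas film negligible when k_g is huge: K = k_l * a / V
  expect_equal(K1, 1e-5 * geom$area / (geom$v_liquid * 1e-3),
               tolerance = 1e-10)
  # adding gas-side resistance can only reduce K
  K2 <- overall_transfer_coefficient(1e-5, 1e-3, 1.3e-3, geom)
  expect_lt(K2, K1)
})

test_that("aqueous NO oxidation follows its rate law orders", {
  k <- 2e6
  expect_equal(aqueous_no_oxidation_rate(0, 1e-4, k), 0)
  r <- aqueous_no_oxidation_rate(1e-6, 1e-4, k)
  expect_equal(r, 2e-10)
  expect_equal(aqueous_no_oxidation_rate(2e-6, 1e-4, k), 4 * r)   # order 2
  expect_equal(aqueous_no_oxidation_rate(1e-6, 2e-4, k), 2 * r)   # order 1
  expect_error(aqueous_no_oxidation_rate(-1e-6, 1e-4, k), "negative")
})

test_that("gas-phase NO oxidation follows its rate law orders", {
  k <- 11.5
  expect_equal(gas_no_oxidation_rate(0, 0.2, k), 0)
  r <- gas_no_oxidation_rate(3e-5, 0.2, k)
  expect_equal(r, 11.5 * (3e-5)^2 * 0.2)
  expect_equal(gas_no_oxidation_rate(6e-5, 0.2, k), 4 * r)
})

test_that("nitrous acid fraction follows Henderson-Hasselbalch", {
  expect_equal(hono_fraction(3.3, 3.3), 0.5)
  expect_equal(hono_fraction(7.4, 3.3), 1 / (1 + 10^(7.4 - 3.3)))
  expect_lt(hono_fraction(7.4, 3.3), 1e-4)    # negligible at culture pH
  expect_lt(hono_fraction(13.9, 3.3), 1e-10)  # high-pH limit
  expect_error(hono_fraction(-1), "pH")
})

test_that("abiotic RHS: zero state gives zero derivatives; NO + O2 makes nitrite", {
  st <- setNames(numeric(13), c(nitrox:::LIQUID_SPECIES, nitrox:::GAS_SPECIES))
  expect_true(all(abiotic_rhs(st) == 0))
  st2 <- st; st2[["no"]] <- 1e-5; st2[["o2"]] <- 1e-4
  d <- abiotic_rhs(st2)
  expect_gt(d[["no2"]], 0)
  expect_lt(d[["no"]], 0)
})

test_that("abiotic RHS conserves total nitrogen for random states", {
  geom <- reactor_geometry()
  kv <- nitrox:::const_values(nox_constants())
  set.seed(7)
  for (i in 1:30) {
    st <- setNames(runif(13, 0, 1e-3),
                   c(nitrox:::LIQUID_SPECIES, nitrox:::GAS_SPECIES))
    d <- abiotic_rhs(st, kv, geom)
    # the N inventory is linear in the state, so applying it to the
    # derivative gives d(total N)/dt, which must vanish to machine precision
    dN <- total_nitrogen(d, geom)
    expect_lt(abs(dN), 1e-18)
  }
})

test_that("abiotic RHS matches finite differences of the integrated map", {
  geom <- reactor_geometry()
  kv <- nitrox:::const_values(nox_constants())
  st <- setNames(numeric(13), c(nitrox:::LIQUID_SPECIES, nitrox:::GAS_SPECIES))
  st[c("no", "o2", "no2", "n2o")] <- c(2e-5, 1e-4, 1e-3, 1e-6)
  st[c("g_o2", "g_no", "g_n2o")] <- c(0.2, 3e-5, 4e-5)
  d <- abiotic_rhs(st, kv, geom)
  eps <- 1e-3                                   # seconds
  rhs_h <- function(t, y, p) list(abiotic_rhs(y, kv, geom))
  sol <- deSolve::lsoda(st, c(0, eps), rhs_h, NULL,
                        rtol = 1e-10, atol = 1e-16)
  fd <- (sol[2, -1] - st) / eps
  expect_equal(unname(fd), unname(d), tolerance = 1e-5)
})

test_that("reactor geometry validates positivity", {
  expect_error(reactor_geometry(v_liquid = -1), "positive")
  g <- reactor_geometry()
  expect_equal(g$v_liquid + g$v_gas, 0.160)
})

test_that("constants registry carries citations and rejects unknown overrides", {
  k <- nox_constants()
  expect_true(all(vapply(k, function(e) nzchar(e$citation), logical(1))))
  k2 <- nox_constants(list(kla_no = 5))
  expect_equal(k2$kla_no$value, 5)
  expect_match(k2$kla_no$citation, "override")
  expect_error(nox_constants(list(bogus = 1)), "unknown")
})
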