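# Abiotic reactor chemistry for the sealed-vial system: N-oxide reaction
# kinetics, acid-base speciation at fixed pH, and two-film gas-liquid mass
# transfer.
#
# State convention used throughout the package:
#   liquid concentrations (M):   nh4, nh2oh, no2, no3, no, n2o, o2, dic
#   headspace partial pressures (atm): g_o2, g_no, g_no2, g_n2o, g_co2
# "nh4" is total ammonium (NH4+ + NH3), "dic" total dissolved inorganic
# carbon.  Dissolved NO2 is not a state: absorbed NO2 hydrolyses to
# NO2- + NO3- much faster than it transfers, so the transfer flux is routed
# directly to the ion pools (see nox_constants).

LIQUID_SPECIES <- c("nh4", "nh2oh", "no2", "no3", "no", "n2o", "o2", "dic")
GAS_SPECIES    <- c("g_o2", "g_no", "g_no2", "g_n2o", "g_co2")

# moles of N per molecule for every N-carrying pool
N_PER_LIQ <- c(nh4 = 1, nh2oh = 1, no2 = 1, no3 = 1, no = 1, n2o = 2,
               o2 = 0, dic = 0)
N_PER_GAS <- c(g_o2 = 0, g_no = 1, g_no2 = 1, g_n2o = 2, g_co2 = 0)

#' Reactor geometry for a sealed serum vial
#'
#' @param v_liquid liquid volume (L); default 5 ml.
#' @param v_gas headspace volume (L); default 155 ml (160-ml vial).
#' @param temperature temperature (K); default 303.15 (30 degrees C).
#' @param pressure total headspace pressure (atm).
#' @param area gas-liquid interfacial area (m^2); default is the cross
#'   section of an upright 160-ml serum vial.  Only used when film
#'   coefficients rather than lumped overall coefficients are supplied.
#' @return object of class \code{nox_geometry}.
#' @export
reactor_geometry <- function(v_liquid = 0.005, v_gas = 0.155,
                             temperature = 303.15, pressure = 1,
                             area = 2.29e-3) {
  vals <- c(v_liquid = v_liquid, v_gas = v_gas, temperature = temperature,
            pressure = pressure, area = area)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all geometry fields must be strictly positive")
  structure(as.list(vals), class = "nox_geometry")
}

#' Convert a headspace mixing ratio to a partial pressure
#'
#' @param ppm mixing ratio in parts per million (mole fraction x 1e6).
#' @param p_total total pressure (atm).
#' @return partial pressure (atm).
#' @export
ppm_to_atm <- function(ppm, p_total = 1) {
  if (any(ppm < 0)) stop("ppm must be nonnegative")
  ppm * 1e-6 * p_total
}

#' @rdname ppm_to_atm
#' @param atm partial pressure (atm).
#' @export
atm_to_ppm <- function(atm, p_total = 1) {
  atm / p_total * 1e6
}

#' Two-film gas-liquid transfer flux
#'
#' Volumetric molar flux of a gas species into the liquid, proportional to
#' the departure from Henry equilibrium: \code{K * (H * p - c)}.  Positive
#' values dissolve gas, negative values outgas.  \code{K} is the overall
#' liquid-phase transfer coefficient; it may be supplied directly as a lumped
#' \code{K_L a} value or computed from film coefficients via
#' \code{\link{overall_transfer_coefficient}}.
#'
#' @param c dissolved concentration (M).
#' @param p partial pressure (atm).
#' @param H Henry's law constant (M atm^-1).
#' @param K overall volumetric transfer coefficient (s^-1).
#' @return flux into the liquid (M s^-1).
#' @export
gas_liquid_flux <- function(c, p, H, K) {
  K * (H * p - c)
}

#' Overall transfer coefficient from two-film parameters
#'
#' Combines liquid- and gas-side film coefficients with the interfacial area
#' and liquid volume into the overall volumetric coefficient used by
#' \code{\link{gas_liquid_flux}}: resistances in series,
#' \code{1/K_L = 1/k_l + 1/(k_g H R T)}, scaled by the specific area
#' \code{a / V_liquid}.
#'
#' @param k_l liquid-side film coefficient (m s^-1).
#' @param k_g gas-side film coefficient (m s^-1).
#' @param H Henry's law constant (M atm^-1).
#' @param geom \code{\link{reactor_geometry}}.
#' @return overall volumetric transfer coefficient (s^-1).
#' @export
overall_transfer_coefficient <- function(k_l, k_g, H, geom) {
  RT <- 0.082057 * geom$temperature          # L atm mol^-1
  kl_res <- 1 / k_l
  kg_res <- 1 / (k_g * H * RT)
  KL <- 1 / (kl_res + kg_res)                # m s^-1
  KL * geom$area / (geom$v_liquid * 1e-3)    # (m * m^2) / m^3 -> s^-1
}

#' Aqueous abiotic oxidation of nitric oxide
#'
#' Third-order autoxidation 4NO + O2 + 2H2O -> 4NO2- + 4H+.  The returned
#' value is the reaction *extent* rate r = k [NO]^2 [O2]; NO is consumed at
#' 4r, O2 at r and nitrite produced at 4r.  Protons are absorbed by the
#' fixed-pH assumption.
#'
#' @param c_no,c_o2 dissolved NO and O2 (M).
#' @param k third-order rate constant (M^-2 s^-1).
#' @return extent rate (M s^-1).
#' @export
aqueous_no_oxidation_rate <- function(c_no, c_o2, k) {
  if (any(c(c_no, c_o2, k) < 0)) stop("negative input")
  k * c_no^2 * c_o2
}

#' Gas-phase oxidation of nitric oxide
#'
#' 2NO + O2 -> 2NO2 in the headspace, on a partial-pressure basis.  Returns
#' the extent rate r = k pNO^2 pO2; NO is consumed at 2r, NO2 produced at 2r,
#' O2 consumed at r.
#'
#' @param p_no,p_o2 partial pressures (atm).
#' @param k rate constant (atm^-2 s^-1).
#' @return extent rate (atm s^-1).
#' @export
gas_no_oxidation_rate <- function(p_no, p_o2, k) {
  if (any(c(p_no, p_o2, k) < 0)) stop("negative input")
  k * p_no^2 * p_o2
}

#' Fraction of the nitrite pool present as nitrous acid
#'
#' Henderson-Hasselbalch fraction \code{1 / (1 + 10^(pH - pKa))}.  At the
#' fixed simulation pH of 7.4 this is below 1e-4, which is why HONO
#' volatilization is negligible in every scenario.
#'
#' @param pH medium pH (0 < pH < 14).
#' @param pka_hono pKa of nitrous acid.
#' @return fraction in [0, 1].
#' @export
hono_fraction <- function(pH, pka_hono = 3.3) {
  if (any(pH <= 0) || any(pH >= 14)) stop("pH out of range")
  1 / (1 + 10^(pH - pka_hono))
}

# per-process abiotic rates; everything per second.
# Returns extent rates and transfer fluxes used by both the RHS and the
# source/sink decomposition.
#' @keywords internal
#' @noRd
abiotic_process_rates <- function(state, kv, geom) {
  r_aq  <- kv[["k_aq_no"]]  * state[["no"]]^2  * state[["o2"]]
  r_gas <- kv[["k_gas_no"]] * state[["g_no"]]^2 * state[["g_o2"]]
  r_nh2oh <- kv[["k_nh2oh"]] * state[["nh2oh"]]
  hr <- 1 / 3600
  tf <- c(
    o2  = gas_liquid_flux(state[["o2"]],  state[["g_o2"]],  kv[["H_o2"]],
                          kv[["kla_o2"]]  * hr),
    no  = gas_liquid_flux(state[["no"]],  state[["g_no"]],  kv[["H_no"]],
                          kv[["kla_no"]]  * hr),
    n2o = gas_liquid_flux(state[["n2o"]], state[["g_n2o"]], kv[["H_n2o"]],
                          kv[["kla_n2o"]] * hr),
    co2 = gas_liquid_flux(state[["dic"]] * kv[["f_co2"]], state[["g_co2"]],
                          kv[["H_co2"]], kv[["kla_co2"]] * hr),
    # dissolved NO2 is ~0 (instant hydrolysis), so NO2 absorption is one-way
    no2 = gas_liquid_flux(0, state[["g_no2"]], kv[["H_no2"]],
                          kv[["kla_no2"]] * hr)
  )
  list(r_aq = r_aq, r_gas = r_gas, r_nh2oh = r_nh2oh, transfer = tf)
}

#' Abiotic time derivatives for the sealed-vial system
#'
#' Sums all abiotic reaction and gas-transfer terms: aqueous and gas-phase NO
#' oxidation, abiotic hydroxylamine decay, absorption of NO2 with immediate
#' hydrolysis to nitrite + nitrate, and two-film exchange of O2, NO, N2O and
#' CO2.  Total nitrogen over all pools is conserved by construction.
#'
#' @param state named numeric vector with entries
#'   \code{nh4, nh2oh, no2, no3, no, n2o, o2, dic} (M) and
#'   \code{g_o2, g_no, g_no2, g_n2o, g_co2} (atm).
#' @param constants \code{\link{nox_constants}} registry (or its value
#'   vector).
#' @param geom \code{\link{reactor_geometry}}.
#' @return named vector of time derivatives (per second), same layout as
#'   \code{state}.
#' @export
abiotic_rhs <- function(state, constants = nox_constants(),
                        geom = reactor_geometry()) {
  kv <- if (inherits(constants, "nox_constants")) const_values(constants)
        else constants
  if (any(!is.finite(state)))
    stop("non-finite state passed to abiotic_rhs at: ",
         paste(names(state)[!is.finite(state)], collapse = ", "))
  pr <- abiotic_process_rates(state, kv, geom)
  d <- state * 0

  # aqueous NO autoxidation: 4NO + O2 -> 4NO2-
  d[["no"]]  <- d[["no"]]  - 4 * pr$r_aq
  d[["o2"]]  <- d[["o2"]]  - pr$r_aq
  d[["no2"]] <- d[["no2"]] + 4 * pr$r_aq

  # abiotic NH2OH decay -> 0.5 N2O
  d[["nh2oh"]] <- d[["nh2oh"]] - pr$r_nh2oh
  d[["n2o"]]   <- d[["n2o"]]   + 0.5 * pr$r_nh2oh

  # gas-phase NO oxidation: 2NO + O2 -> 2NO2
  d[["g_no"]]  <- d[["g_no"]]  - 2 * pr$r_gas
  d[["g_o2"]]  <- d[["g_o2"]]  - pr$r_gas
  d[["g_no2"]] <- d[["g_no2"]] + 2 * pr$r_gas

  # gas-liquid transfer; gas side converted so moles are conserved
  g_per_l <- geom$v_liquid * 0.082057 * geom$temperature / geom$v_gas
  tf <- pr$transfer
  d[["o2"]]    <- d[["o2"]]  + tf[["o2"]]
  d[["no"]]    <- d[["no"]]  + tf[["no"]]
  d[["n2o"]]   <- d[["n2o"]] + tf[["n2o"]]
  d[["dic"]]   <- d[["dic"]] + tf[["co2"]]
  d[["no2"]]   <- d[["no2"]] + 0.5 * tf[["no2"]]
  d[["no3"]]   <- d[["no3"]] + 0.5 * tf[["no2"]]
  d[["g_o2"]]  <- d[["g_o2"]]  - tf[["o2"]]  * g_per_l
  d[["g_no"]]  <- d[["g_no"]]  - tf[["no"]]  * g_per_l
  d[["g_n2o"]] <- d[["g_n2o"]] - tf[["n2o"]] * g_per_l
  d[["g_co2"]] <- d[["g_co2"]] - tf[["co2"]] * g_per_l
  d[["g_no2"]] <- d[["g_no2"]] - tf[["no2"]] * g_per_l
  d
}

#' Total nitrogen inventory of a reactor state
#'
#' Moles of N summed over all liquid and headspace pools (biomass-bound N is
#' accounted separately by the simulation engine).
#'
#' @inheritParams abiotic_rhs
#' @return moles of nitrogen.
#' @export
total_nitrogen <- function(state, geom = reactor_geometry()) {
  nl <- sum(state[names(N_PER_LIQ)] * N_PER_LIQ) * geom$v_liquid
  RT <- 0.082057 * geom$temperature
  ng <- sum(state[names(N_PER_GAS)] * N_PER_GAS) * geom$v_gas / RT
  nl + ng
}
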