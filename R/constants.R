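# Physical-constant registry: literature defaults for abiotic kinetics,
# Henry's law solubilities and gas-liquid transfer, each carrying a citation
# string so the provenance of every number is auditable and overridable.

#' Physical and kinetic constants registry
#'
#' Returns the registry of abiotic rate constants, Henry's law constants,
#' lumped gas-liquid transfer coefficients and unit-conversion constants used
#' by the reactor chemistry and simulation modules.  Every entry records its
#' value, units and a literature citation (or the word "assumption"), and any
#' entry can be overridden, so a scenario is always fully reproducible from
#' its configuration.
#'
#' Values refer to 30 degrees C (303.15 K), the incubation temperature of the
#' closed-vial experiments the package emulates.  Temperature dependence of
#' the constants is not modeled.
#'
#' @param overrides named list; entries replace the default value of the
#'   constant of the same name (the citation is rewritten to mark the
#'   override).  Unknown names are an error.
#' @return an object of class \code{nox_constants}: a named list of entries,
#'   each a list with \code{value}, \code{units} and \code{citation}.
#' @examples
#' k <- nox_constants()
#' k$k_aq_no$value
#' k2 <- nox_constants(list(kla_no = 5))
#' @export
nox_constants <- function(overrides = NULL) {
  ent <- function(value, units, citation)
    list(value = value, units = units, citation = citation)

  reg <- list(
    ## --- abiotic kinetics -------------------------------------------------
    # aqueous 4NO + O2 + 2H2O -> 4NO2- + 4H+; extent rate r = k [NO]^2 [O2],
    # NO consumed at 4r.
    k_aq_no = ent(2.1e6, "M^-2 s^-1",
                  "Lewis & Deen 1994 Chem Res Toxicol 7:568 (third-order aqueous NO autoxidation)"),
    # gas phase 2NO + O2 -> 2NO2; extent rate r = k pNO^2 pO2 on a
    # partial-pressure basis, NO consumed at 2r.
    k_gas_no = ent(11.5, "atm^-2 s^-1",
                   "Tsukahara et al. 1999 Nitric Oxide 3:191; 7.1e3 M^-2 s^-1 converted with (RT)^2 at 303 K"),
    # nitrous acid dissociation
    pka_hono = ent(3.3, "dimensionless",
                   "Park & Lee 1988 J Phys Chem 92:6294 (HNO2 pKa ~3.3)"),
    # abiotic pseudo-first-order hydroxylamine decay (to 0.5 N2O); kept near
    # zero: abiotic NH2OH breakdown is not a significant N-oxide source in
    # this medium.
    k_nh2oh = ent(1e-8, "s^-1", "assumption (negligible abiotic NH2OH loss)"),
    # absorbed NO2 disproportionates, 2NO2 + H2O -> NO2- + NO3-.  The aqueous
    # reaction (~1e8 M^-1 s^-1) is orders of magnitude faster than interfacial
    # transfer, so dissolved NO2 is treated as instantaneously hydrolysed and
    # the transfer flux is split 1:1 between nitrite and nitrate.
    k_no2_hydrolysis = ent(1e8, "M^-1 s^-1",
                           "Schwartz & White 1981 Adv Environ Sci Eng 4:1; treated as instantaneous"),

    ## --- Henry's law constants at 303 K (M atm^-1) ------------------------
    H_o2  = ent(1.16e-3, "M atm^-1", "Sander 2015 Atmos Chem Phys 15:4399"),
    H_no  = ent(1.7e-3,  "M atm^-1", "Sander 2015 Atmos Chem Phys 15:4399"),
    H_no2 = ent(7.0e-3,  "M atm^-1", "Sander 2015 Atmos Chem Phys 15:4399"),
    H_n2o = ent(2.1e-2,  "M atm^-1", "Sander 2015 Atmos Chem Phys 15:4399"),
    H_co2 = ent(3.0e-2,  "M atm^-1", "Sander 2015 Atmos Chem Phys 15:4399"),
    # nitrous acid is very soluble; its headspace mixing ratio is
    # equilibrium-limited to a negligible fraction of NOx (diagnostic only)
    H_hono = ent(49, "M atm^-1", "Park & Lee 1988 J Phys Chem 92:6294"),

    ## --- lumped overall gas-liquid transfer coefficients (K_L a, h^-1) ----
    # Effective per-species coefficients for 5 ml of medium shaken at 200 rpm
    # in a crimp-sealed 160-ml serum vial.  The O2 value is set so that the
    # maximum O2 delivery rate (kla_o2 * c_sat ~ 3.6 mmol L^-1 h^-1) sustains
    # the observed NH3 + NO2- oxidation rates of the coculture while letting
    # dissolved O2 dip to micro-oxic levels during active oxidation; the
    # NO/NO2/N2O values are empirical effective coefficients for the trace
    # gases in this vial format (see the methods vignette for their
    # justification and caveats).
    kla_o2  = ent(15, "h^-1", "assumption (shaken closed serum vial)"),
    kla_no  = ent(3,  "h^-1", "assumption (effective trace-gas coefficient)"),
    kla_no2 = ent(3,  "h^-1", "assumption (effective trace-gas coefficient)"),
    kla_n2o = ent(2,  "h^-1", "assumption (effective trace-gas coefficient)"),
    kla_co2 = ent(10, "h^-1", "assumption (shaken closed serum vial)"),

    ## --- speciation / misc -------------------------------------------------
    # fraction of dissolved inorganic carbon present as CO2(aq) at pH 7.4
    # (pK1 = 6.35): 1/(1 + 10^(pH - pK1))
    f_co2 = ent(0.082, "dimensionless",
                "Stumm & Morgan 1996, carbonate speciation at pH 7.4"),
    gas_constant = ent(0.082057, "L atm mol^-1 K^-1", "CODATA"),
    # biomass conversion and composition
    od_to_gdcw = ent(0.35, "gDCW L^-1 per OD600 unit",
                     "assumption (typical for dilute nitrifier suspensions)"),
    biomass_n = ent(10, "mmol N gDCW^-1",
                    "assumption (~14% N by dry weight, E. coli-like biomass)"),
    biomass_c = ent(40, "mmol C gDCW^-1", "assumption (~48% C by dry weight)")
  )

  if (!is.null(overrides)) {
    stopifnot(is.list(overrides))
    unknown <- setdiff(names(overrides), names(reg))
    if (length(unknown))
      stop("unknown constant(s): ", paste(unknown, collapse = ", "))
    for (nm in names(overrides)) {
      reg[[nm]]$value <- overrides[[nm]]
      reg[[nm]]$citation <- "user override"
    }
  }
  structure(reg, class = "nox_constants")
}

#' @export
print.nox_constants <- function(x, ...) {
  cat("Constants registry (", length(x), " entries)\n", sep = "")
  for (nm in names(x))
    cat(sprintf("  %-18s %-12g %-18s %s\n", nm, x[[nm]]$value,
                x[[nm]]$units, x[[nm]]$citation))
  invisible(x)
}

# plain named vector of values, for fast access in inner loops
#' @keywords internal
#' @noRd
const_values <- function(k) {
  vapply(k, function(e) e$value, numeric(1))
}
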