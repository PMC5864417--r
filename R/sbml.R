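# SBML Level 3 Version 1 + Flux Balance Constraints (fbc v2) import/export
# for the core models.  This is the substitution hook for full genome-scale
# reconstructions: any FBC-annotated SBML model with the same exchange ids
# can be read in place of the built-in cores.  Stoichiometries and bounds
# are written with 17 significant digits, so a write/read round trip
# reproduces them bit-exactly.

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
FBC_NS  <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

#' Write a core model as SBML Level 3 + FBC
#'
#' @param model a \code{nox_model}.
#' @param path output file.
#' @param objective objective id (from \code{model$objectives}) to mark as
#'   the active FBC objective; default "biomass" when present.
#' @export
write_sbml <- function(model, path, objective = NULL) {
  if (is.null(objective))
    objective <- if ("biomass" %in% names(model$objectives)) "biomass"
                 else names(model$objectives)[1]
  num <- function(x) sprintf("%.17g", x)

  doc <- xml2::xml_new_root("sbml", xmlns = SBML_NS, "xmlns:fbc" = FBC_NS,
                            level = "3", version = "1",
                            "fbc:required" = "false")
  mdl <- xml2::xml_add_child(doc, "model",
                             id = paste0(model$organism, "_core"),
                             "fbc:strict" = "true")
  cmp <- xml2::xml_add_child(mdl, "listOfCompartments")
  xml2::xml_add_child(cmp, "compartment", id = "c", constant = "true")
  sp <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (m in model$mets)
    xml2::xml_add_child(sp, "species", id = paste0("m_", m),
                        compartment = "c", hasOnlySubstanceUnits = "false",
                        boundaryCondition = "false", constant = "false")
  par <- xml2::xml_add_child(mdl, "listOfParameters")
  for (id in names(model$reactions)) {
    xml2::xml_add_child(par, "parameter", id = paste0("lb_", id),
                        value = num(model$lb[[id]]), constant = "true")
    xml2::xml_add_child(par, "parameter", id = paste0("ub_", id),
                        value = num(model$ub[[id]]), constant = "true")
  }
  rxs <- xml2::xml_add_child(mdl, "listOfReactions")
  for (id in names(model$reactions)) {
    st <- model$reactions[[id]]$stoich
    rx <- xml2::xml_add_child(rxs, "reaction", id = id,
                              reversible = if (model$lb[[id]] < 0) "true" else "false",
                              fast = "false",
                              "fbc:lowerFluxBound" = paste0("lb_", id),
                              "fbc:upperFluxBound" = paste0("ub_", id))
    neg <- st[st < 0]; pos <- st[st > 0]
    if (length(neg)) {
      lr <- xml2::xml_add_child(rx, "listOfReactants")
      for (m in names(neg))
        xml2::xml_add_child(lr, "speciesReference", species = paste0("m_", m),
                            stoichiometry = num(-neg[[m]]), constant = "true")
    }
    if (length(pos)) {
      lp <- xml2::xml_add_child(rx, "listOfProducts")
      for (m in names(pos))
        xml2::xml_add_child(lp, "speciesReference", species = paste0("m_", m),
                            stoichiometry = num(pos[[m]]), constant = "true")
    }
  }
  lo <- xml2::xml_add_child(mdl, "fbc:listOfObjectives",
                            "fbc:activeObjective" = "obj1")
  ob <- xml2::xml_add_child(lo, "fbc:objective", "fbc:id" = "obj1",
                            "fbc:type" = "maximize")
  lf <- xml2::xml_add_child(ob, "fbc:listOfFluxObjectives")
  oc <- model$objectives[[objective]]
  for (rid in names(oc))
    xml2::xml_add_child(lf, "fbc:fluxObjective", "fbc:reaction" = rid,
                        "fbc:coefficient" = num(oc[[rid]]))
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read an SBML Level 3 + FBC model
#'
#' Parses species, reactions, stoichiometries, FBC flux bounds and the
#' active FBC objective into a \code{nox_model}.  Species ids may carry an
#' \code{m_} prefix (as written by \code{\link{write_sbml}}), which is
#' stripped.
#'
#' @param path SBML file.
#' @return a \code{nox_model} (maintenance parameters are not encoded in
#'   SBML and are left NA).
#' @export
read_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  mdl <- xml2::xml_find_first(doc, ".//model")
  organism <- sub("_core$", "", xml2::xml_attr(mdl, "id"))

  pars <- xml2::xml_find_all(doc, ".//listOfParameters/parameter")
  pval <- stats::setNames(as.numeric(xml2::xml_attr(pars, "value")),
                          xml2::xml_attr(pars, "id"))
  strip_m <- function(x) sub("^m_", "", x)

  reactions <- list()
  for (rx in xml2::xml_find_all(doc, ".//listOfReactions/reaction")) {
    id <- xml2::xml_attr(rx, "id")
    st <- numeric(0)
    for (sr in xml2::xml_find_all(rx, "./listOfReactants/speciesReference")) {
      m <- strip_m(xml2::xml_attr(sr, "species"))
      st[m] <- (if (m %in% names(st)) st[[m]] else 0) -
        as.numeric(xml2::xml_attr(sr, "stoichiometry"))
    }
    for (sr in xml2::xml_find_all(rx, "./listOfProducts/speciesReference")) {
      m <- strip_m(xml2::xml_attr(sr, "species"))
      st[m] <- (if (m %in% names(st)) st[[m]] else 0) +
        as.numeric(xml2::xml_attr(sr, "stoichiometry"))
    }
    lbid <- xml2::xml_attr(rx, "lowerFluxBound")
    ubid <- xml2::xml_attr(rx, "upperFluxBound")
    lb <- if (!is.na(lbid) && lbid %in% names(pval)) pval[[lbid]] else -BIG_BOUND
    ub <- if (!is.na(ubid) && ubid %in% names(pval)) pval[[ubid]] else BIG_BOUND
    reactions[[id]] <- list(stoich = st, lb = lb, ub = ub)
  }

  objectives <- list()
  fo <- xml2::xml_find_all(doc, ".//listOfObjectives/objective[1]/listOfFluxObjectives/fluxObjective")
  if (length(fo)) {
    oc <- stats::setNames(as.numeric(xml2::xml_attr(fo, "coefficient")),
                          xml2::xml_attr(fo, "reaction"))
    objectives$biomass <- oc
  }
  new_core_model(organism, reactions, objectives,
                 maintenance = list(ngam = NA_real_, gam = NA_real_))
}
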