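# Reduced stoichiometric/energy models of Nitrosomonas europaea (Ne) and
# Nitrobacter winogradskyi (Nw), and the linear-programming interface that
# yields growth and exchange fluxes at every dynamic-FBA step.
#
# The models are ~20-reaction energy cores: they preserve the electron and
# ATP accounting of the full genome-scale reconstructions (nitrogen redox
# reactions, a lumped terminal-oxidase / proton-translocation / ATP-synthase
# chain, maintenance demands and a lumped biomass equation) without their
# anabolic detail.  Fluxes are mmol gDCW^-1 h^-1; biomass flux is the
# specific growth rate (h^-1).
#
# Currency metabolites: "e" (electron), "hp" (translocated proton, i.e. the
# proton-motive charge available to ATP synthase) and "atp".  These are
# excluded from the elemental audit; water is tracked so that N and O
# balance exactly in every interior reaction.

BIG_BOUND <- 1e4

# N and O content of tracked metabolites (currency metabolites excluded)
MET_ELEMENTS <- list(
  nh3     = c(N = 1, O = 0), nh2oh = c(N = 1, O = 1),
  nh2oh_x = c(N = 1, O = 1), no2   = c(N = 1, O = 2),
  no2_p   = c(N = 1, O = 2), no2_c = c(N = 1, O = 2),
  no3     = c(N = 1, O = 3), no    = c(N = 1, O = 1),
  n2o     = c(N = 2, O = 1), o2    = c(N = 0, O = 2),
  co2     = c(N = 0, O = 2), h2o   = c(N = 0, O = 1)
)
CURRENCY_METS <- c("e", "hp", "atp")

#' @keywords internal
#' @noRd
new_core_model <- function(organism, reactions, objectives, maintenance,
                           extra = list()) {
  mets <- unique(unlist(lapply(reactions, function(r) names(r$stoich))))
  S <- matrix(0, length(mets), length(reactions),
              dimnames = list(mets, names(reactions)))
  for (j in seq_along(reactions))
    S[names(reactions[[j]]$stoich), j] <- reactions[[j]]$stoich
  m <- c(list(
    organism = organism,
    reactions = reactions,
    mets = mets,
    S = S,
    lb = vapply(reactions, `[[`, numeric(1), "lb"),
    ub = vapply(reactions, `[[`, numeric(1), "ub"),
    objectives = objectives,
    maintenance = maintenance
  ), extra)
  class(m) <- "nox_model"
  m
}

#' @export
print.nox_model <- function(x, ...) {
  cat(sprintf("<nox_model> %s: %d reactions, %d metabolites\n",
              x$organism, length(x$reactions), length(x$mets)))
  cat("  NGAM:", x$maintenance$ngam, "mmol ATP gDCW^-1 h^-1;  GAM:",
      x$maintenance$gam, "mmol ATP gDCW^-1\n")
  if (!is.null(x$energy_variant)) cat("  energy variant:", x$energy_variant, "\n")
  invisible(x)
}

#' Build the reduced N. europaea energy model
#'
#' Ammonia oxidation core: AMO (NH3 + O2 + 2e -> NH2OH + H2O), HAO
#' (NH2OH + H2O -> NO2- + 4e by default, or NH2OH -> NO + 3e in the
#' alternative three-electron mode), the nitrifier-denitrification pair NIR
#' (NO2- + e -> NO) and NOR (2NO + 2e -> N2O), cytochrome P460 oxidizing
#' *extracellular* hydroxylamine to N2O, a lumped terminal-oxidase /
#' ATP-synthase chain, maintenance reactions and a biomass equation, plus
#' exchanges for NH3/NH4+, O2, NO2-, NO, N2O, CO2, water and a reversible
#' hydroxylamine exchange.
#'
#' Hydroxylamine handling reflects how the organism is modeled dynamically:
#' AMO output enters an intracellular pool consumed by HAO; throughput beyond
#' the HAO capacity bound spills to the extracellular pool, whose only
#' catabolic sink is P460.
#'
#' @param hao_mode "four_electron" (NH2OH to nitrite, 4 electrons) or
#'   "three_electron_NO" (NH2OH to NO, 3 electrons).
#' @param include_p460 include the cytochrome P460 reaction.
#' @param ngam non-growth-associated maintenance (mmol ATP gDCW^-1 h^-1).
#' @param gam growth-associated maintenance embedded in the biomass reaction
#'   (mmol ATP gDCW^-1).
#' @param atp_per_pair lumped ATP yield per electron pair respired at the
#'   terminal oxidase (see the methods vignette for how this effective
#'   stoichiometry is constrained).
#' @param h_per_atp protons translocated per ATP synthesized.
#' @param biomass_n,biomass_c biomass N and C content (mmol gDCW^-1).
#' @return a \code{nox_model}.
#' @export
build_ne_model <- function(hao_mode = c("four_electron", "three_electron_NO"),
                           include_p460 = TRUE,
                           ngam = 52.82, gam = 1060,
                           atp_per_pair = 3.5, h_per_atp = 3,
                           biomass_n = 10, biomass_c = 40) {
  hao_mode <- match.arg(hao_mode)
  # hp released per 4 e- at the oxidase: 2 pairs * atp_per_pair * h_per_atp
  h_ox <- 2 * atp_per_pair * h_per_atp

  rx <- function(stoich, lb = 0, ub = BIG_BOUND) list(stoich = stoich, lb = lb, ub = ub)
  reactions <- list(
    AMO  = rx(c(nh3 = -1, o2 = -1, e = -2, nh2oh = 1, h2o = 1)),
    HAO  = if (hao_mode == "four_electron")
             rx(c(nh2oh = -1, h2o = -1, no2 = 1, e = 4))
           else
             rx(c(nh2oh = -1, no = 1, e = 3)),
    SPILL = rx(c(nh2oh = -1, nh2oh_x = 1)),
    # re-uptake of extracellular hydroxylamine into catabolism (HAO);
    # bounded kinetically by the engine
    TNH2OH = rx(c(nh2oh_x = -1, nh2oh = 1)),
    P460 = rx(c(nh2oh_x = -2, n2o = 1, h2o = 1, e = 4),
              ub = if (include_p460) BIG_BOUND else 0),
    NIR  = rx(c(no2 = -1, e = -1, no = 1, h2o = 1)),
    NOR  = rx(c(no = -2, e = -2, n2o = 1, h2o = 1)),
    CYTOX = rx(c(o2 = -1, e = -4, h2o = 2, hp = h_ox)),
    ATPS = rx(c(hp = -h_per_atp, atp = 1)),
    NGAM = rx(c(atp = -1), lb = ngam),
    BIOMASS = rx(c(atp = -gam, nh3 = -biomass_n, co2 = -biomass_c)),
    EX_nh3   = rx(c(nh3 = -1),   lb = -BIG_BOUND),
    EX_o2    = rx(c(o2 = -1),    lb = -BIG_BOUND, ub = 0),
    EX_no2   = rx(c(no2 = -1),   lb = -BIG_BOUND),
    EX_no    = rx(c(no = -1),    lb = -BIG_BOUND),
    EX_n2o   = rx(c(n2o = -1)),
    # reversible, but uptake closed by default: extracellular hydroxylamine
    # re-enters catabolism only through P460, whose rate the simulation
    # engine bounds kinetically (it widens this lower bound accordingly)
    EX_nh2oh = rx(c(nh2oh_x = -1), lb = 0),
    EX_co2   = rx(c(co2 = -1),   lb = -BIG_BOUND),
    EX_h2o   = rx(c(h2o = -1),   lb = -BIG_BOUND)
  )
  objectives <- list(
    biomass        = c(BIOMASS = 1),
    nh3_uptake     = c(EX_nh3 = -1),
    no2_production = c(EX_no2 = 1),
    atp            = c(NGAM = 1),
    denitrification = c(NIR = 1, NOR = 1, P460 = 1)
  )
  new_core_model("Ne", reactions, objectives,
                 maintenance = list(ngam = ngam, gam = gam),
                 extra = list(hao_mode = hao_mode,
                              include_p460 = include_p460,
                              biomass_id = "BIOMASS", ngam_id = "NGAM"))
}

#' Build the reduced N. winogradskyi energy model
#'
#' Nitrite oxidation core: NXR (NO2- + H2O -> NO3- + 2e), a periplasmic NIR
#' (NO2- + e -> NO, the organism's only route to NO), the terminal-oxidase /
#' ATP-synthase chain at the stoichiometry that yields 0.667 mmol ATP per
#' mmol NO2- oxidized, maintenance and biomass.  The POUGHON variant adds a
#' lumped nitrite self-cycling loop (periplasmic reduction to NO, diffusion
#' to the cytoplasm and re-oxidation to nitrite) whose net effect is extra
#' proton translocation per nitrite processed, raising the maximum yield to
#' 1.53 mmol ATP per mmol NO2-.  Neither variant contains NOR or any other
#' N2O-producing reaction: the organism's genome encodes no known NOR.
#'
#' @param variant "SIMPLE" (periplasmic NIR only) or "POUGHON".
#' @param ngam non-growth maintenance; defaults to 8 (SIMPLE) or 18.52
#'   (POUGHON) mmol ATP gDCW^-1 h^-1.
#' @inheritParams build_ne_model
#' @return a \code{nox_model}.
#' @export
build_nw_model <- function(variant = c("SIMPLE", "POUGHON"),
                           ngam = NULL, gam = 1060,
                           biomass_n = 10, biomass_c = 40) {
  variant <- match.arg(variant)
  if (is.null(ngam)) ngam <- if (variant == "SIMPLE") 8 else 18.52
  # oxidase: 4 H+ per 2 e-; synthase: 6 H+ per ATP  ->  2e from one NO2-
  # give 4/6 = 0.667 ATP.  The Poughon loop nets 5.18 extra H+ per NO2-,
  # (4 + 5.18)/6 = 1.53 ATP.
  cycle_hp <- 5.18

  rx <- function(stoich, lb = 0, ub = BIG_BOUND) list(stoich = stoich, lb = lb, ub = ub)
  reactions <- list(
    TNO2  = rx(c(no2_p = -1, no2_c = 1)),
    CYCLE = rx(c(no2_p = -1, no2_c = 1, hp = cycle_hp),
               ub = if (variant == "POUGHON") BIG_BOUND else 0),
    NXR   = rx(c(no2_c = -1, h2o = -1, no3 = 1, e = 2)),
    NIR   = rx(c(no2_p = -1, e = -1, no = 1, h2o = 1)),
    CYTOX = rx(c(o2 = -1, e = -4, h2o = 2, hp = 8)),
    ATPS  = rx(c(hp = -6, atp = 1)),
    NGAM  = rx(c(atp = -1), lb = ngam),
    BIOMASS = rx(c(atp = -gam, no2_c = -biomass_n, co2 = -biomass_c)),
    EX_no2 = rx(c(no2_p = -1), lb = -BIG_BOUND),
    EX_no3 = rx(c(no3 = -1)),
    EX_no  = rx(c(no = -1)),
    EX_o2  = rx(c(o2 = -1), lb = -BIG_BOUND, ub = 0),
    EX_co2 = rx(c(co2 = -1), lb = -BIG_BOUND),
    EX_h2o = rx(c(h2o = -1), lb = -BIG_BOUND)
  )
  objectives <- list(
    biomass        = c(BIOMASS = 1),
    no2_uptake     = c(EX_no2 = -1),
    atp            = c(NGAM = 1),
    denitrification = c(NIR = 1)
  )
  new_core_model("Nw", reactions, objectives,
                 maintenance = list(ngam = ngam, gam = gam),
                 extra = list(energy_variant = variant,
                              biomass_id = "BIOMASS", ngam_id = "NGAM"))
}

#' Audit elemental balance of a core model
#'
#' Checks that every interior (non-exchange, non-biomass) reaction balances
#' nitrogen and oxygen exactly, using the metabolite composition table.
#' Currency metabolites (electrons, translocated protons, ATP) are excluded.
#'
#' @param model a \code{nox_model}.
#' @return invisibly TRUE; errors with the offending reactions otherwise.
#' @export
audit_elements <- function(model) {
  skip <- c(model$biomass_id, grep("^EX_", names(model$reactions), value = TRUE))
  bad <- character(0)
  for (id in setdiff(names(model$reactions), skip)) {
    st <- model$reactions[[id]]$stoich
    st <- st[!(names(st) %in% CURRENCY_METS)]
    if (!length(st)) next
    tot <- c(N = 0, O = 0)
    for (met in names(st)) {
      el <- MET_ELEMENTS[[met]]
      if (is.null(el)) stop("unknown metabolite in audit: ", met)
      tot <- tot + st[[met]] * el
    }
    if (any(abs(tot) > 1e-9)) bad <- c(bad, id)
  }
  if (length(bad))
    stop("elementally unbalanced reaction(s): ", paste(bad, collapse = ", "))
  invisible(TRUE)
}

#' Set flux bounds on a model
#'
#' @param model a \code{nox_model}.
#' @param id reaction id.
#' @param lb,ub new bounds (either may be omitted).
#' @return the modified model.
#' @export
set_bounds <- function(model, id, lb = NULL, ub = NULL) {
  if (!id %in% names(model$reactions)) stop("no reaction ", id)
  if (!is.null(lb)) { model$lb[[id]] <- lb; model$reactions[[id]]$lb <- lb }
  if (!is.null(ub)) { model$ub[[id]] <- ub; model$reactions[[id]]$ub <- ub }
  model
}

# translate an objective spec (id, ordered ids, or named numeric) to a list
# of coefficient vectors over reactions, one per lexicographic stage
#' @keywords internal
#' @noRd
objective_vectors <- function(model, objective) {
  n <- length(model$reactions)
  ids <- names(model$reactions)
  as_vec <- function(o) {
    v <- numeric(n); names(v) <- ids
    if (is.character(o) && length(o) == 1 && o %in% names(model$objectives))
      o <- model$objectives[[o]]
    else if (is.character(o) && length(o) == 1 && o %in% ids) {
      tmp <- 1; names(tmp) <- o; o <- tmp
    }
    if (is.null(names(o))) stop("unintelligible objective")
    unknown <- setdiff(names(o), ids)
    if (length(unknown)) stop("objective names not in model: ",
                              paste(unknown, collapse = ", "))
    v[names(o)] <- as.numeric(o)
    v
  }
  if (is.character(objective)) lapply(objective, as_vec)
  else if (is.numeric(objective)) list(as_vec(objective))
  else if (is.list(objective)) lapply(objective, as_vec)
  else stop("unintelligible objective")
}

#' Flux balance analysis on a core model
#'
#' Solves \code{max c'v} subject to \code{S v = 0} and the model's flux
#' bounds.  A character vector of several objective ids triggers
#' lexicographic optimization: each objective is maximized in turn with all
#' previous optima fixed.  Ties in the final stage are broken by minimizing
#' the total absolute flux (so the returned flux vector is unique and
#' deterministic); set \code{tie_break = FALSE} to skip that stage.
#'
#' @param model a \code{nox_model}.
#' @param objective an objective id from \code{model$objectives} (e.g.
#'   "biomass", "atp"), a reaction id, an ordered character vector for
#'   lexicographic optimization, or a named numeric vector of coefficients.
#' @param uptake_bounds named vector: maximum uptake rate per exchanged
#'   species (mmol gDCW^-1 h^-1); entry "nh3" bounds \code{EX_nh3} etc.
#'   Sets the exchange lower bound to minus the value.
#' @param tie_break break objective ties by minimizing total absolute flux.
#' @param warm optional warm-start information from a previous solve of the
#'   same model (internal use by the simulation engine).
#' @return a FluxMap: list with \code{status} ("optimal"/"infeasible"),
#'   \code{fluxes} (named vector), \code{objective} (value of the first
#'   objective stage) and \code{warm}.
#' @export
fba_solve <- function(model, objective = "biomass", uptake_bounds = NULL,
                      tie_break = TRUE, warm = NULL) {
  ids <- names(model$reactions)
  lb <- model$lb; ub <- model$ub
  if (!is.null(uptake_bounds)) {
    for (sp in names(uptake_bounds)) {
      ex <- paste0("EX_", sp)
      if (!ex %in% ids) stop("no exchange reaction for species ", sp)
      lb[[ex]] <- -abs(uptake_bounds[[sp]])
    }
  }
  objs <- objective_vectors(model, objective)
  A <- model$S
  b <- numeric(nrow(A))
  first_val <- NA_real_
  sol <- NULL
  for (k in seq_along(objs)) {
    sol <- lp_solve(objs[[k]], A, b, lb, ub, maximize = TRUE,
                    warm = if (k == 1) warm else NULL)
    if (sol$status != "optimal") {
      if (sol$status == "unbounded")
        stop("unbounded objective in fba_solve (stage ", k, ")")
      return(list(status = "infeasible",
                  fluxes = setNames(rep(NA_real_, length(ids)), ids),
                  objective = NA_real_, warm = NULL))
    }
    if (k == 1) first_val <- sol$value
    if (k < length(objs) || tie_break) {     # pin this stage's optimum
      A <- rbind(A, objs[[k]])
      b <- c(b, sol$value)
    }
  }
  if (tie_break) {
    n <- length(ids)
    rev_idx <- which(lb < 0)
    # aux variables w_j >= |v_j| for reversible reactions; irreversible
    # fluxes are their own magnitude
    n_aux <- length(rev_idx)
    if (n_aux) {
      A2 <- cbind(rbind(A, matrix(0, 2 * n_aux, n)),
                  matrix(0, nrow(A) + 2 * n_aux, 3 * n_aux))
      b2 <- c(b, rep(0, 2 * n_aux))
      for (i in seq_len(n_aux)) {
        j <- rev_idx[i]
        rw <- nrow(A) + 2 * (i - 1) + 1
        # w - v - s1 = 0 ; w + v - s2 = 0
        A2[rw,     c(j, n + i, n + n_aux + 2 * (i - 1) + 1)] <- c(-1, 1, -1)
        A2[rw + 1, c(j, n + i, n + n_aux + 2 * (i - 1) + 2)] <- c(1, 1, -1)
      }
      obj2 <- c(rep(0, n), rep(-1, n_aux), rep(0, 2 * n_aux))
      obj2[seq_len(n)][lb >= 0] <- -1
      lb2 <- c(lb, rep(0, 3 * n_aux))
      ub2 <- c(ub, rep(BIG_BOUND, n_aux), rep(2 * BIG_BOUND, 2 * n_aux))
      sol2 <- lp_solve(obj2, A2, b2, lb2, ub2, maximize = TRUE)
      if (sol2$status == "optimal")
        sol$x <- sol2$x[seq_len(n)]
    } else {
      sol2 <- lp_solve(-rep(1, n), A, b, lb, ub, maximize = TRUE)
      if (sol2$status == "optimal") sol$x <- sol2$x
    }
  }
  fl <- setNames(sol$x[seq_along(ids)], ids)
  list(status = "optimal", fluxes = fl, objective = first_val,
       warm = sol$warm)
}

#' Maximum ATP yield per mmol nitrite oxidized
#'
#' Releases the maintenance (NGAM) lower bound, fixes nitrite uptake at
#' 1 mmol gDCW^-1 h^-1 and maximizes ATP hydrolysis by linear programming.
#' For the N. winogradskyi energy model this returns 0.667 (SIMPLE variant)
#' or 1.53 (POUGHON variant) mmol ATP per mmol NO2-.
#'
#' @param model a \code{nox_model} with an \code{EX_no2} exchange.
#' @return mmol ATP per mmol NO2-.
#' @export
atp_yield_per_no2 <- function(model) {
  if (!"EX_no2" %in% names(model$reactions))
    stop("model has no nitrite exchange")
  model <- set_bounds(model, model$ngam_id, lb = 0)
  model <- set_bounds(model, "EX_no2", lb = -1, ub = -1)
  fm <- fba_solve(model, "atp", tie_break = FALSE)
  if (fm$status != "optimal") stop("ATP yield LP infeasible")
  fm$objective
}

#' Volumetric exchange fluxes
#'
#' Converts specific exchange fluxes (mmol gDCW^-1 h^-1) to volumetric rates
#' (mmol L^-1 h^-1) at a given biomass density.  Positive = secretion into
#' the medium.
#'
#' @param fm a FluxMap from \code{\link{fba_solve}}.
#' @param X biomass density (gDCW L^-1).
#' @return named vector over exchange reactions.
#' @export
exchange_fluxes <- function(fm, X) {
  ex <- grep("^EX_", names(fm$fluxes), value = TRUE)
  fm$fluxes[ex] * X
}
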