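#' @import methods
NULL

#' Stoichiometric metabolic model
#'
#' An S4 container for a constraint-based metabolic model: a metabolite table,
#' a reaction table (bounds, GPR rules, subsystems) and the stoichiometric
#' matrix, plus the designated biomass and ATP-maintenance reactions.
#'
#' Conventions used throughout the package:
#' \itemize{
#'   \item two compartments only, cytosol \code{"c"} and extracellular
#'     \code{"e"}; periplasmic proton translocation is represented as
#'     cytosol-to-extracellular proton movement;
#'   \item exchange reactions touch exactly one (extracellular) metabolite;
#'     negative exchange flux is uptake into the network, positive is
#'     secretion;
#'   \item fluxes are mmol/gdw/h, the biomass reaction carries 1/h.
#' }
#'
#' @slot modelId single character identifier.
#' @slot species free-text species label.
#' @slot metabolites data.frame with columns \code{id}, \code{name},
#'   \code{compartment} ("c" or "e"), \code{formula} (elemental composition,
#'   may be \code{NA}), \code{charge} (integer, may be \code{NA}).
#' @slot reactions data.frame with columns \code{id}, \code{name},
#'   \code{lower}, \code{upper} (flux bounds), \code{gpr} (boolean gene rule,
#'   "" for non-gene-associated), \code{subsystem} (one of the nine functional
#'   classifications).
#' @slot S numeric matrix, metabolites x reactions; negative coefficients are
#'   consumed, positive produced.
#' @slot biomassReaction id of the biomass demand reaction.
#' @slot atpmReaction id of the ATP maintenance reaction.
#' @slot biomassGAM growth-associated maintenance ATP (mmol ATP/gdw) embedded
#'   in the biomass reaction; needed to remove the GAM term in max-ATP mode.
#'
#' @export
setClass("MetabolicModel",
  representation(
    modelId = "character",
    species = "character",
    metabolites = "data.frame",
    reactions = "data.frame",
    S = "matrix",
    biomassReaction = "character",
    atpmReaction = "character",
    biomassGAM = "numeric"
  )
)

#' The nine functional reaction classifications
#'
#' Fixed subsystem vocabulary used by the model container and the cross-model
#' comparison report.
#' @export
SUBSYSTEMS <- c(
  "Amino Acid Metabolism", "Carbohydrate Metabolism", "Central Metabolism",
  "Cofactor Metabolism", "Energy Metabolism", "Lipid Metabolism",
  "Nucleotide Metabolism", "Transport", "Other"
)

setValidity("MetabolicModel", function(object) {
  msg <- character()
  met <- object@metabolites
  rxn <- object@reactions
  need_m <- c("id", "name", "compartment", "formula", "charge")
  need_r <- c("id", "name", "lower", "upper", "gpr", "subsystem")
  if (!all(need_m %in% names(met))) {
    msg <- c(msg, "metabolite table lacks required columns")
  }
  if (!all(need_r %in% names(rxn))) {
    msg <- c(msg, "reaction table lacks required columns")
  }
  if (length(msg)) return(msg)
  if (anyDuplicated(met$id)) msg <- c(msg, "duplicate metabolite ids")
  if (anyDuplicated(rxn$id)) msg <- c(msg, "duplicate reaction ids")
  if (!identical(dim(object@S), c(nrow(met), nrow(rxn)))) {
    msg <- c(msg, "stoichiometric matrix dimensions do not match tables")
  }
  if (length(msg)) msg else TRUE
})

#' Flux solution of a linear flux-balance problem
#'
#' @slot status one of "optimal", "infeasible", "unbounded".
#' @slot objective objective value (NA unless optimal).
#' @slot fluxes named numeric flux vector (mmol/gdw/h; biomass in 1/h);
#'   length zero unless optimal.
#' @slot objectiveReaction id of the objective reaction.
#' @slot sense "max" or "min".
#' @export
setClass("FluxSolution",
  representation(
    status = "character",
    objective = "numeric",
    fluxes = "numeric",
    objectiveReaction = "character",
    sense = "character"
  ),
  prototype(status = "infeasible", objective = NA_real_, fluxes = numeric(0),
            objectiveReaction = NA_character_, sense = "max")
)

#' Energy parameters of a Pelobacter core model
#'
#' The calibrated energy contract: growth-associated maintenance (GAM, mmol
#' ATP/gdw), non-growth-associated maintenance (nGAM, mmol ATP/gdw/h), the
#' H+/2e- translocation stoichiometry of the two sulfur reductases (hydrogen-
#' dependent SRE and NADPH-dependent SRE2), and the ATP synthase H+/ATP ratio.
#'
#' @slot gam growth-associated maintenance, mmol ATP/gdw (default 97.5).
#' @slot ngam non-growth-associated maintenance, mmol ATP/gdw/h.
#' @slot sreHPer2e protons translocated per 2 electrons by SRE (1 or 2).
#' @slot sre2HPer2e protons translocated per 2 electrons by SRE2 (1 or 2).
#' @slot atpSynthaseHPerAtp protons consumed per ATP by the ATP synthase.
#' @export
setClass("EnergyParams",
  representation(
    gam = "numeric", ngam = "numeric",
    sreHPer2e = "numeric", sre2HPer2e = "numeric",
    atpSynthaseHPerAtp = "numeric"
  )
)

setValidity("EnergyParams", function(object) {
  msg <- character()
  if (object@gam < 0) msg <- c(msg, "gam must be >= 0")
  if (object@ngam < 0) msg <- c(msg, "ngam must be >= 0")
  if (!object@sreHPer2e %in% c(1, 2)) {
    msg <- c(msg, "sreHPer2e must be 1 or 2")
  }
  if (!object@sre2HPer2e %in% c(1, 2)) {
    msg <- c(msg, "sre2HPer2e must be 1 or 2")
  }
  if (object@atpSynthaseHPerAtp <= 0) {
    msg <- c(msg, "atpSynthaseHPerAtp must be positive")
  }
  if (length(msg)) msg else TRUE
})

#' Lumped biomass composition
#'
#' The full biomass composition of the source reconstructions is not
#' distributable; the core models use a lumped biomass demand built from
#' acetyl-CoA (carbon/electron channel), NADPH (anabolic reducing power),
#' ammonium (nitrogen) and GAM ATP (taken from [energyParams()]).
#' Coefficients are mmol per gdw of biomass formed.
#'
#' @slot accoa acetyl-CoA coefficient (mmol/gdw).
#' @slot nadph NADPH coefficient (mmol/gdw).
#' @slot nh4 ammonium coefficient (mmol/gdw).
#' @export
setClass("BiomassSpec",
  representation(accoa = "numeric", nadph = "numeric", nh4 = "numeric")
)

setValidity("BiomassSpec", function(object) {
  if (object@accoa < 0 || object@nadph < 0 || object@nh4 < 0) {
    "biomass coefficients must be >= 0"
  } else TRUE
})

#' Simulation condition (medium + constraints + objective)
#'
#' One simulation's constraint set: the freely exchanged medium components,
#' per-exchange maximum uptake rates, fixed-flux assignments, exchanges to
#' close entirely, and the objective.
#'
#' @slot freeExchanges metabolite ids (extracellular) whose exchange is
#'   unbounded in both directions.
#' @slot uptakeLimits named numeric, exchange reaction id -> maximum uptake
#'   rate (mmol/gdw/h); the exchange lower bound becomes -limit.
#' @slot fixedFluxes named numeric, reaction id -> fixed value.
#' @slot closedReactions reaction ids whose bounds are set to zero.
#' @slot objective reaction id of the objective.
#' @slot sense "max" or "min".
#' @export
setClass("Condition",
  representation(
    freeExchanges = "character",
    uptakeLimits = "numeric",
    fixedFluxes = "numeric",
    closedReactions = "character",
    objective = "character",
    sense = "character"
  )
)

#' Chemostat maintenance regression fit
#'
#' Result of regressing the maximal ATP production rate against dilution
#' rate over a set of chemostat observations: the slope is the
#' growth-associated maintenance (GAM) and the intercept the non-growth-
#' associated maintenance (nGAM).
#'
#' @slot gam regression slope (mmol ATP/gdw).
#' @slot ngam regression intercept (mmol ATP/gdw/h).
#' @slot rSquared coefficient of determination of the fit.
#' @slot points data.frame with one row per observation: \code{mu},
#'   \code{qatp}.
#' @export
setClass("MaintenanceFit",
  representation(gam = "numeric", ngam = "numeric", rSquared = "numeric",
                 points = "data.frame")
)

setValidity("MaintenanceFit", function(object) {
  if (!is.na(object@rSquared) &&
      (object@rSquared < -1e-9 || object@rSquared > 1 + 1e-9)) {
    "rSquared must lie in [0, 1]"
  } else TRUE
})

#' Validation scenario
#'
#' A named growth condition from the published validation set: species,
#' substrates, electron acceptor, whether H2/formate secretion is open
#' (syntrophic mode), the growth constraint and the objective mode.
#'
#' @slot label scenario name.
#' @slot species "pcar" or "ppro".
#' @slot substrates named numeric: extracellular metabolite id -> maximum
#'   uptake rate.
#' @slot acceptor "none", "fe3" or "s0".
#' @slot h2Open logical, allow H2 (and formate) secretion.
#' @slot mu fixed growth rate (1/h) or NA to maximise biomass.
#' @slot objectiveMode "min-uptake", "max-biomass" or "max-atp".
#' @slot closeReactions extra reaction ids closed in this scenario.
#' @export
setClass("Scenario",
  representation(
    label = "character", species = "character", substrates = "numeric",
    acceptor = "character", h2Open = "logical", mu = "numeric",
    objectiveMode = "character", closeReactions = "character"
  )
)
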