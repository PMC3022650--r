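# Flux balance analysis: condition handling and the published objective
# modes (maximise growth, minimise substrate uptake at fixed growth,
# maximise the ATP-maintenance flux under measured fluxes), plus the
# biomass-producibility (gap) analysis.

#' Default freely-exchanged medium components
#'
#' Extracellular metabolites allowed to enter and leave the network without
#' limit in every anaerobic minimal-medium simulation.
#' @export
FREE_EXCHANGE_METS <- c("co2_e", "h_e", "h2o_e", "k_e", "mg2_e", "nh4_e",
                        "pi_e", "so4_e")

#' Build a simulation condition
#'
#' A condition fixes the medium (which exchanges are free, which substrates
#' may be taken up and at what maximum rate), fixed-flux assignments, closed
#' reactions and the objective. Exchanges not listed anywhere default to
#' secretion-only (lower bound 0).
#'
#' @param objective reaction id of the objective.
#' @param sense "max" or "min".
#' @param uptakeLimits named numeric: exchange reaction id (or extracellular
#'   metabolite id, resolved via \code{EX_<met>}) -> maximum uptake rate.
#' @param fixedFluxes named numeric: reaction id -> fixed flux value.
#' @param closeReactions reaction ids to close (bounds zero).
#' @param freeExchanges extracellular metabolite ids freely exchanged.
#' @return a \linkS4class{Condition}.
#' @export
makeCondition <- function(objective, sense = c("max", "min"),
                          uptakeLimits = numeric(0),
                          fixedFluxes = numeric(0),
                          closeReactions = character(0),
                          freeExchanges = FREE_EXCHANGE_METS) {
  sense <- match.arg(sense)
  new("Condition", freeExchanges = freeExchanges,
      uptakeLimits = uptakeLimits, fixedFluxes = fixedFluxes,
      closedReactions = closeReactions, objective = objective, sense = sense)
}

exchangeIdFor <- function(model, met) {
  rid <- paste0("EX_", met)
  if (rid %in% model@reactions$id) return(rid)
  if (met %in% model@reactions$id) return(met)
  stop("no exchange reaction for '", met, "'")
}

# Apply a condition to model bounds; returns list(lb, ub, objIndex)
conditionBounds <- function(model, cond) {
  rxn <- model@reactions
  lb <- rxn$lower
  ub <- rxn$upper
  names(lb) <- names(ub) <- rxn$id
  exch <- exchangeCandidates(model)$ids
  # exchanges: secretion-only by default
  lb[exch] <- pmax(lb[exch], 0)
  # free medium components
  for (metId in cond@freeExchanges) {
    rid <- paste0("EX_", metId)
    if (rid %in% exch) { lb[rid] <- -Inf; ub[rid] <- Inf }
  }
  # substrate uptake limits
  if (length(cond@uptakeLimits)) {
    for (k in seq_along(cond@uptakeLimits)) {
      rid <- exchangeIdFor(model, names(cond@uptakeLimits)[k])
      lb[rid] <- -abs(cond@uptakeLimits[k])
    }
  }
  # closures
  if (length(cond@closedReactions)) {
    miss <- setdiff(cond@closedReactions, rxn$id)
    cl <- intersect(cond@closedReactions, rxn$id)
    lb[cl] <- 0
    ub[cl] <- 0
  }
  # fixed fluxes last: they override
  if (length(cond@fixedFluxes)) {
    bad <- setdiff(names(cond@fixedFluxes), rxn$id)
    if (length(bad)) stop("fixed flux for unknown reaction(s): ",
                          paste(bad, collapse = ", "))
    for (k in seq_along(cond@fixedFluxes)) {
      rid <- names(cond@fixedFluxes)[k]
      val <- cond@fixedFluxes[[k]]
      if (val < rxn$lower[match(rid, rxn$id)] - 1e-9 ||
          val > rxn$upper[match(rid, rxn$id)] + 1e-9) {
        stop("fixed flux for ", rid, " (", val,
             ") lies outside the reaction's bounds")
      }
      lb[rid] <- val
      ub[rid] <- val
    }
  }
  if (!(cond@objective %in% rxn$id)) {
    stop("objective reaction not in model: ", cond@objective)
  }
  list(lb = unname(lb), ub = unname(ub),
       objIndex = match(cond@objective, rxn$id))
}

#' Solve a flux-balance problem
#'
#' Maximises or minimises the flux through the condition's objective
#' reaction subject to steady-state mass balance (\eqn{S v = 0}), the
#' reaction bounds, the medium and any fixed fluxes.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param condition a \linkS4class{Condition}.
#' @return a \linkS4class{FluxSolution}; solver outcome is reported in its
#'   status ("optimal", "infeasible", "unbounded").
#' @export
solveFBA <- function(model, condition) {
  cb <- conditionBounds(model, condition)
  n <- nrow(model@reactions)
  obj <- numeric(n)
  obj[cb$objIndex] <- 1
  res <- simplexSolve(obj, model@S, lb = cb$lb, ub = cb$ub,
                      maximize = condition@sense == "max")
  if (res$status != "optimal") {
    return(new("FluxSolution", status = res$status, objective = NA_real_,
               fluxes = numeric(0), objectiveReaction = condition@objective,
               sense = condition@sense))
  }
  fx <- res$x
  names(fx) <- model@reactions$id
  new("FluxSolution", status = "optimal", objective = res$objective,
      fluxes = fx, objectiveReaction = condition@objective,
      sense = condition@sense)
}

#' Optimal growth at fixed substrate uptake
#'
#' Fixes the substrate exchange flux at \code{-uptake} (uptake into the
#' network) and maximises the biomass flux.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param substrate extracellular metabolite id (or exchange reaction id).
#' @param uptake positive uptake rate (mmol/gdw/h).
#' @param condition optional base \linkS4class{Condition}; its objective and
#'   sense are replaced.
#' @return a \linkS4class{FluxSolution} (status "infeasible" when the
#'   maintenance requirement cannot be met).
#' @export
optimalGrowth <- function(model, substrate, uptake,
                          condition = makeCondition(biomassReaction(model))) {
  stopifnot(uptake > 0)
  rid <- exchangeIdFor(model, substrate)
  fx <- condition@fixedFluxes
  fx[rid] <- -uptake
  condition@fixedFluxes <- fx
  condition@objective <- biomassReaction(model)
  condition@sense <- "max"
  solveFBA(model, condition)
}

#' Minimal substrate uptake at fixed growth
#'
#' Fixes the biomass flux at \code{mu} and minimises the substrate uptake
#' magnitude; since uptake is a negative exchange flux, this is implemented
#' as maximising the signed exchange flux toward zero.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param substrate extracellular metabolite id (or exchange reaction id).
#' @param mu growth rate to fix (1/h), >= 0.
#' @param maxUptake cap on the substrate uptake rate (default 1000).
#' @param condition optional base \linkS4class{Condition}.
#' @return a \linkS4class{FluxSolution}; the substrate exchange flux in the
#'   solution is negative, its magnitude the minimal uptake.
#' @export
minSubstrateAtGrowth <- function(model, substrate, mu, maxUptake = 1000,
                                 condition = makeCondition(biomassReaction(model))) {
  stopifnot(mu >= 0)
  rid <- exchangeIdFor(model, substrate)
  ul <- condition@uptakeLimits
  ul[rid] <- maxUptake
  condition@uptakeLimits <- ul
  fx <- condition@fixedFluxes
  fx[biomassReaction(model)] <- mu
  condition@fixedFluxes <- fx
  condition@objective <- rid
  condition@sense <- "max"   # maximise the (negative) flux toward zero
  solveFBA(model, condition)
}

# strip the GAM term from the biomass reaction (max-ATP fitting mode):
# the growth-associated ATP hydrolysis (gam x {atp + h2o -> adp + pi + h})
# is removed so the regression slope captures total growth-associated ATP.
zeroGAM <- function(model) {
  if (model@biomassGAM == 0) return(model)
  j <- match(model@biomassReaction, model@reactions$id)
  g <- model@biomassGAM
  for (met in c("atp", "h2o")) {
    if (met %in% rownames(model@S)) {
      model@S[met, j] <- model@S[met, j] + g
    }
  }
  for (met in c("adp", "pi", "h")) {
    if (met %in% rownames(model@S)) {
      model@S[met, j] <- model@S[met, j] - g
    }
  }
  model@S[abs(model@S[, j]) < 1e-12, j] <- 0
  model@biomassGAM <- 0
  model
}

#' Maximal ATP-maintenance flux under fixed measured fluxes
#'
#' The chemostat fitting mode: measured exchange fluxes (and the dilution
#' rate as the biomass flux) are fixed, the growth-associated ATP term is
#' removed from the biomass reaction, and the flux through the
#' ATP-maintenance reaction is maximised. The optimum is the ATP production
#' rate qATP that the measured fluxes can support.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param fixed named numeric: reaction id -> fixed flux (measured values;
#'   exchange fluxes negative for uptake).
#' @param mu biomass flux to fix (dilution rate, 1/h); NULL leaves biomass
#'   free.
#' @param condition optional base \linkS4class{Condition}.
#' @param keepGAM set TRUE to keep the GAM term in the biomass reaction (used
#'   by the yield-based nGAM estimator, where GAM is part of the model being
#'   interrogated).
#' @return a \linkS4class{FluxSolution} for the ATPM objective.
#' @export
maxATP <- function(model, fixed = numeric(0), mu = NULL,
                   condition = makeCondition(atpmReaction(model)),
                   keepGAM = FALSE) {
  if (!keepGAM) model <- zeroGAM(model)
  # the maintenance flux is the objective: release its nGAM lower bound
  model <- setBounds(model, atpmReaction(model), lower = 0)
  fx <- condition@fixedFluxes
  if (length(fixed)) fx[names(fixed)] <- fixed
  if (!is.null(mu)) fx[biomassReaction(model)] <- mu
  condition@fixedFluxes <- fx
  condition@objective <- atpmReaction(model)
  condition@sense <- "max"
  solveFBA(model, condition)
}

#' Biomass precursor producibility (gap analysis)
#'
#' For each metabolite consumed by the biomass reaction, adds a temporary
#' demand reaction and tests whether its flux can exceed a small positive
#' threshold on the given medium. Demands respect conserved moieties: a
#' precursor whose carrier is returned by the biomass reaction (acetyl-CoA /
#' CoA, NADPH / NADP, ATP / ADP + Pi) is consumed against that carrier, so
#' the probe does not drain a conserved pool.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param condition a \linkS4class{Condition} describing the medium (its
#'   objective is ignored).
#' @param threshold minimal demand flux regarded as producible.
#' @param partners named list mapping precursor id -> character vector of
#'   carrier products returned per unit of precursor consumed.
#' @return data.frame with columns \code{precursor}, \code{producible},
#'   \code{maxFlux}.
#' @export
biomassProducibility <- function(model, condition,
                                 threshold = 1e-4,
                                 partners = list(accoa = c(coa = 1),
                                                 succoa = c(coa = 1),
                                                 nadph = c(nadp = 1),
                                                 nadh = c(nad = 1),
                                                 atp = c(adp = 1, pi = 1))) {
  j <- match(model@biomassReaction, model@reactions$id)
  st <- model@S[, j]
  precursors <- names(st)[st < 0]
  out <- lapply(precursors, function(p) {
    dem <- c(stats::setNames(-1, p))
    pt <- partners[[p]]
    pt <- pt[names(pt) %in% model@metabolites$id]
    if (length(pt)) dem <- c(dem, pt)
    m2 <- addReaction(model, "DM_probe", dem, lower = 0, upper = Inf)
    # growth itself is not required while probing a single precursor
    m2 <- setBounds(m2, m2@biomassReaction, lower = 0, upper = 0)
    m2 <- setBounds(m2, m2@atpmReaction, lower = 0)
    cond2 <- condition
    cond2@objective <- "DM_probe"
    cond2@sense <- "max"
    cond2@uptakeLimits <- pmin(cond2@uptakeLimits, 1000)
    sol <- solveFBA(m2, cond2)
    mx <- if (solverStatus(sol) == "optimal") objectiveValue(sol)
          else if (solverStatus(sol) == "unbounded") Inf else 0
    data.frame(precursor = p, producible = mx > threshold, maxFlux = mx,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
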