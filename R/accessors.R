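#' Accessors for package classes
#'
#' Accessor functions for the S4 containers: reaction and metabolite tables,
#' the stoichiometric matrix, designated reactions, exchange reaction ids,
#' gene ids parsed from the GPR rules, and flux-solution components.
#'
#' @param object a \linkS4class{MetabolicModel} or \linkS4class{FluxSolution}.
#' @return See individual methods; tables are returned as data.frames.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("reactions", "MetabolicModel", function(object) object@reactions)

#' @rdname accessors
#' @export
setMethod("metabolites", "MetabolicModel", function(object) object@metabolites)

#' @rdname accessors
#' @export
setMethod("stoichiometryMatrix", "MetabolicModel", function(object) object@S)

#' @rdname accessors
#' @export
setMethod("biomassReaction", "MetabolicModel",
          function(object) object@biomassReaction)

#' @rdname accessors
#' @export
setMethod("atpmReaction", "MetabolicModel", function(object) object@atpmReaction)

#' @rdname accessors
#' @export
setMethod("exchangeReactions", "MetabolicModel", function(object) {
  idx <- which(colSums(object@S != 0) == 1)
  ext <- object@metabolites$id[object@metabolites$compartment == "e"]
  keep <- vapply(idx, function(j) {
    object@metabolites$id[which(object@S[, j] != 0)] %in% ext
  }, logical(1))
  object@reactions$id[idx[keep]]
})

#' @rdname accessors
#' @export
setMethod("geneIds", "MetabolicModel", function(object) {
  toks <- unlist(lapply(object@reactions$gpr, gprGenes))
  sort(unique(toks))
})

#' @rdname accessors
#' @export
setMethod("fluxes", "FluxSolution", function(object) object@fluxes)

#' @rdname accessors
#' @export
setMethod("solverStatus", "FluxSolution", function(object) object@status)

#' @rdname accessors
#' @export
setMethod("objectiveValue", "FluxSolution", function(object) object@objective)

setMethod("show", "MetabolicModel", function(object) {
  nex <- length(exchangeReactions(object))
  cat("MetabolicModel", object@modelId, "(", object@species, ")\n")
  cat(" ", nrow(object@metabolites), "metabolites (",
      sum(object@metabolites$compartment == "e"), "extracellular ),",
      nrow(object@reactions), "reactions (", nex, "exchanges )\n")
  cat("  biomass:", object@biomassReaction,
      " ATPM:", object@atpmReaction,
      " GAM:", object@biomassGAM, "mmol ATP/gdw\n")
})

setMethod("show", "FluxSolution", function(object) {
  cat("FluxSolution:", object@status, "\n")
  cat("  objective (", object@sense, " ", object@objectiveReaction, "): ",
      format(object@objective, digits = 6), "\n", sep = "")
})

setMethod("show", "EnergyParams", function(object) {
  cat("EnergyParams\n")
  cat("  GAM: ", object@gam, " mmol ATP/gdw;  nGAM: ", object@ngam,
      " mmol ATP/gdw/h\n", sep = "")
  cat("  SRE H+/2e-: ", object@sreHPer2e,
      ";  SRE2 H+/2e-: ", object@sre2HPer2e,
      ";  ATP synthase H+/ATP: ", object@atpSynthaseHPerAtp, "\n", sep = "")
})

setMethod("show", "MaintenanceFit", function(object) {
  cat("MaintenanceFit: qATP =", format(object@gam, digits = 6), "* mu +",
      format(object@ngam, digits = 6), "\n")
  cat("  R-squared:", format(object@rSquared, digits = 6),
      " (", nrow(object@points), "observations )\n")
})

setMethod("show", "BiomassSpec", function(object) {
  cat("BiomassSpec (mmol/gdw): acetyl-CoA", object@accoa,
      "| NADPH", object@nadph, "| NH4", object@nh4, "\n")
})

setMethod("show", "Scenario", function(object) {
  cat("Scenario", object@label, "[", object@species, "]\n")
  cat("  substrates:",
      paste(names(object@substrates), object@substrates, sep = "<=",
            collapse = ", "),
      " acceptor:", object@acceptor,
      " H2 open:", object@h2Open, "\n")
  cat("  mu:", ifelse(is.na(object@mu), "maximise", object@mu),
      " mode:", object@objectiveMode, "\n")
})
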