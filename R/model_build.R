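# Internal model assembly helpers shared by the I/O layer and the
# species-specific builders.

#' Assemble a MetabolicModel from component tables
#'
#' Low-level constructor: builds the stoichiometric matrix from a list of
#' named stoichiometry vectors and runs structural validation.
#'
#' @param modelId,species identifiers.
#' @param metabolites data.frame with columns id, name, compartment, formula,
#'   charge (formula/charge may be NA).
#' @param reactions data.frame with columns id, name, lower, upper, gpr,
#'   subsystem.
#' @param stoichiometry list (one element per reaction, same order) of named
#'   numeric vectors: metabolite id -> signed coefficient (negative consumed).
#' @param biomassReaction,atpmReaction designated reaction ids.
#' @param biomassGAM GAM ATP embedded in the biomass reaction (mmol ATP/gdw).
#' @param check if TRUE (default) stop on validation violations.
#' @return a \linkS4class{MetabolicModel}.
#' @export
makeModel <- function(modelId, species, metabolites, reactions, stoichiometry,
                      biomassReaction, atpmReaction, biomassGAM = 0,
                      check = TRUE) {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  if (is.null(metabolites$formula)) metabolites$formula <- NA_character_
  if (is.null(metabolites$charge)) metabolites$charge <- NA_real_
  if (is.null(reactions$gpr)) reactions$gpr <- ""
  reactions$gpr[is.na(reactions$gpr)] <- ""
  if (is.null(reactions$subsystem)) reactions$subsystem <- "Other"
  stopifnot(length(stoichiometry) == nrow(reactions))
  if (anyDuplicated(metabolites$id)) {
    stop("duplicate metabolite id(s): ",
         paste(unique(metabolites$id[duplicated(metabolites$id)]),
               collapse = ", "))
  }
  if (anyDuplicated(reactions$id)) {
    stop("duplicate reaction id(s): ",
         paste(unique(reactions$id[duplicated(reactions$id)]),
               collapse = ", "))
  }
  bad <- setdiff(metabolites$compartment, c("c", "e"))
  if (length(bad)) stop("unknown compartment(s): ", paste(bad, collapse = ", "))
  S <- matrix(0, nrow(metabolites), nrow(reactions),
              dimnames = list(metabolites$id, reactions$id))
  for (j in seq_along(stoichiometry)) {
    st <- stoichiometry[[j]]
    miss <- setdiff(names(st), metabolites$id)
    if (length(miss)) {
      stop("reaction ", reactions$id[j], " references missing metabolite(s): ",
           paste(miss, collapse = ", "))
    }
    S[names(st), j] <- st
  }
  m <- new("MetabolicModel", modelId = modelId, species = species,
           metabolites = metabolites, reactions = reactions, S = S,
           biomassReaction = biomassReaction, atpmReaction = atpmReaction,
           biomassGAM = as.numeric(biomassGAM))
  if (check) {
    v <- validateModel(m)
    if (length(v)) {
      stop("model fails validation:\n  ", paste(v, collapse = "\n  "))
    }
  }
  m
}

#' Stoichiometry of one reaction
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param rid reaction id.
#' @return named numeric vector (negative = consumed).
#' @export
reactionStoichiometry <- function(model, rid) {
  j <- match(rid, model@reactions$id)
  if (is.na(j)) stop("unknown reaction id: ", rid)
  col <- model@S[, j]
  col[col != 0]
}

#' Set reaction bounds
#'
#' Returns a modified copy of the model with new bounds on the given
#' reactions; setting both bounds to zero deletes (closes) a reaction, the
#' usual in silico knockout.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param rid reaction id(s).
#' @param lower,upper new bounds (recycled); NULL leaves a side unchanged.
#' @return the modified model.
#' @export
setBounds <- function(model, rid, lower = NULL, upper = NULL) {
  i <- match(rid, model@reactions$id)
  if (anyNA(i)) stop("unknown reaction id(s): ",
                     paste(rid[is.na(i)], collapse = ", "))
  if (!is.null(lower)) model@reactions$lower[i] <- lower
  if (!is.null(upper)) model@reactions$upper[i] <- upper
  model
}

#' Add a reaction to a model
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param id new reaction id.
#' @param stoich named stoichiometry vector.
#' @param lower,upper bounds.
#' @param name,gpr,subsystem reaction annotation.
#' @return the extended model.
#' @export
addReaction <- function(model, id, stoich, lower = 0, upper = Inf,
                        name = id, gpr = "", subsystem = "Other") {
  if (id %in% model@reactions$id) stop("reaction id exists: ", id)
  miss <- setdiff(names(stoich), model@metabolites$id)
  if (length(miss)) stop("unknown metabolite(s): ", paste(miss, collapse = ", "))
  model@reactions <- rbind(model@reactions,
    data.frame(id = id, name = name, lower = lower, upper = upper,
               gpr = gpr, subsystem = subsystem, stringsAsFactors = FALSE))
  col <- numeric(nrow(model@metabolites))
  names(col) <- model@metabolites$id
  col[names(stoich)] <- stoich
  model@S <- cbind(model@S, col)
  colnames(model@S) <- model@reactions$id
  model
}

#' Parse an elemental formula
#'
#' Parses composition strings such as \code{"C23H34N7O17P3S"} into a named
#' count vector.
#'
#' @param formula character formula (single string).
#' @return named numeric vector of element counts; zero-length for NA/"".
#' @export
parseFormula <- function(formula) {
  if (is.na(formula) || !nzchar(formula)) return(numeric(0))
  m <- gregexpr("[A-Z][a-z]?[0-9]*", formula)[[1]]
  toks <- regmatches(formula, list(m))[[1]]
  if (!length(toks) || sum(attr(m, "match.length")) != nchar(formula)) {
    stop("cannot parse formula: ", formula)
  }
  el <- sub("[0-9]*$", "", toks)
  cnt <- as.numeric(sub("^[A-Za-z]+", "", toks))
  cnt[is.na(cnt)] <- 1
  out <- tapply(cnt, el, sum)
  structure(as.numeric(out), names = names(out))
}

#' Validate a metabolic model
#'
#' Checks every structural invariant of the model container and, for every
#' reaction whose participating metabolites all carry formulas, elemental
#' balance. Exchange reactions, the biomass demand and the ATP-maintenance
#' reaction are exempt from the balance check (they are pseudo-reactions or
#' boundary reactions by construction; ATPM itself is balanced but kept in
#' the exempt set with the other designated pseudo-reactions).
#'
#' Violations are returned as data, not raised as conditions: an empty
#' character vector means the model is valid.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param checkCharge also check charge balance (off by default; the source
#'   reconstructions publish no charges).
#' @return character vector of violation messages (empty = valid).
#' @export
validateModel <- function(model, checkCharge = FALSE) {
  v <- character()
  met <- model@metabolites
  rxn <- model@reactions
  if (anyDuplicated(met$id)) {
    v <- c(v, paste("duplicate metabolite id:",
                    paste(unique(met$id[duplicated(met$id)]), collapse = ", ")))
  }
  if (anyDuplicated(rxn$id)) {
    v <- c(v, paste("duplicate reaction id:",
                    paste(unique(rxn$id[duplicated(rxn$id)]), collapse = ", ")))
  }
  bad <- setdiff(met$compartment, c("c", "e"))
  if (length(bad)) {
    v <- c(v, paste("unknown compartment:", paste(bad, collapse = ", ")))
  }
  bad <- setdiff(rxn$subsystem, SUBSYSTEMS)
  if (length(bad)) {
    v <- c(v, paste("unknown subsystem:", paste(bad, collapse = ", ")))
  }
  if (any(rxn$lower > rxn$upper)) {
    v <- c(v, paste("lower bound exceeds upper bound:",
                    paste(rxn$id[rxn$lower > rxn$upper], collapse = ", ")))
  }
  if (!(model@biomassReaction %in% rxn$id)) {
    v <- c(v, paste("missing biomass reaction:", model@biomassReaction))
  }
  if (!(model@atpmReaction %in% rxn$id)) {
    v <- c(v, paste("missing ATPM reaction:", model@atpmReaction))
  }
  zero <- which(colSums(model@S != 0) == 0)
  if (length(zero)) {
    v <- c(v, paste("all-zero stoichiometry column:",
                    paste(rxn$id[zero], collapse = ", ")))
  }
  # exchanges: single metabolite, extracellular
  exch <- exchangeCandidates(model)
  for (j in exch$index[!exch$ok]) {
    v <- c(v, paste0("exchange-like reaction ", rxn$id[j],
                     " does not touch exactly one extracellular metabolite"))
  }
  # elemental balance
  exempt <- unique(c(exch$ids, model@biomassReaction, model@atpmReaction))
  comp <- lapply(met$formula, function(f) {
    tryCatch(parseFormula(f), error = function(e) NULL)
  })
  names(comp) <- met$id
  for (j in seq_len(nrow(rxn))) {
    if (rxn$id[j] %in% exempt) next
    st <- model@S[, j]
    part <- which(st != 0)
    if (!length(part)) next
    forms <- comp[part]
    if (any(vapply(forms, is.null, logical(1))) ||
        any(!vapply(forms, length, integer(1)))) {
      next  # some participant lacks a formula: balance not checkable
    }
    els <- unique(unlist(lapply(forms, names)))
    bal <- numeric(length(els))
    names(bal) <- els
    for (k in seq_along(part)) {
      f <- forms[[k]]
      bal[names(f)] <- bal[names(f)] + st[part[k]] * f
    }
    off <- names(bal)[abs(bal) > 1e-6]
    if (length(off)) {
      v <- c(v, paste0("reaction ", rxn$id[j], " elementally unbalanced in ",
                       paste(off, collapse = ", ")))
    }
    if (checkCharge) {
      ch <- met$charge[part]
      if (!anyNA(ch)) {
        cb <- sum(st[part] * ch)
        if (abs(cb) > 1e-6) {
          v <- c(v, paste0("reaction ", rxn$id[j], " charge unbalanced (",
                           format(cb), ")"))
        }
      }
    }
  }
  v
}

# exchange detection used by validateModel and exchangeReactions: reactions
# touching exactly one metabolite; ok = that metabolite is extracellular
exchangeCandidates <- function(model) {
  idx <- which(colSums(model@S != 0) == 1)
  ok <- vapply(idx, function(j) {
    i <- which(model@S[, j] != 0)
    model@metabolites$compartment[i] == "e"
  }, logical(1))
  list(index = idx, ok = ok, ids = model@reactions$id[idx[ok]])
}
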