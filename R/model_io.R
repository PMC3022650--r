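# Model serialisation.
#
# Native dialect: a single JSON document with model-level fields plus
# "metabolites" and "reactions" arrays; each reaction carries its
# stoichiometry as a {metabolite-id: signed coefficient} object. Infinite
# bounds are serialised as the strings "Inf"/"-Inf". Alternatively a pair of
# TSV tables (metabolites.tsv / reactions.tsv) with the same fields, the
# stoichiometry flattened to "met_id:coeff" pairs joined by ";" and the
# model-level fields in "#key=value" header lines of reactions.tsv.
# writeModel() output is canonical: writing a just-read canonical file
# reproduces it byte-identically.

#' Read a metabolic model
#'
#' Reads a model from the package's native JSON dialect (a \code{.json} file)
#' or from a TSV table pair (pass the directory containing
#' \code{metabolites.tsv} and \code{reactions.tsv}, or the
#' \code{reactions.tsv} path itself).
#'
#' @param path file or directory path.
#' @return a validated \linkS4class{MetabolicModel}.
#' @seealso [writeModel()], [validateModel()]
#' @export
readModel <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (dir.exists(path) || grepl("\\.tsv$", path)) {
    return(readModelTSV(path))
  }
  doc <- tryCatch(
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE, simplifyVector = FALSE),
    error = function(e) stop("parse error in ", path, ": ", conditionMessage(e))
  )
  for (f in c("id", "species", "biomass_reaction", "atpm_reaction",
              "metabolites", "reactions")) {
    if (is.null(doc[[f]])) stop("model file ", path, " lacks field '", f, "'")
  }
  getf <- function(rec, field, default = NA) {
    x <- rec[[field]]
    if (is.null(x)) default else x
  }
  met <- do.call(rbind, lapply(seq_along(doc$metabolites), function(i) {
    r <- doc$metabolites[[i]]
    if (is.null(r$id)) stop("metabolite record ", i, " in ", path, " lacks id")
    data.frame(id = r$id, name = as.character(getf(r, "name", r$id)),
               compartment = as.character(getf(r, "compartment", "c")),
               formula = as.character(getf(r, "formula", NA_character_)),
               charge = suppressWarnings(as.numeric(getf(r, "charge"))),
               stringsAsFactors = FALSE)
  }))
  rxn <- do.call(rbind, lapply(seq_along(doc$reactions), function(i) {
    r <- doc$reactions[[i]]
    if (is.null(r$id)) stop("reaction record ", i, " in ", path, " lacks id")
    data.frame(id = r$id, name = as.character(getf(r, "name", r$id)),
               lower = suppressWarnings(as.numeric(getf(r, "lower", -Inf))),
               upper = suppressWarnings(as.numeric(getf(r, "upper", Inf))),
               gpr = as.character(getf(r, "gpr", "")),
               subsystem = as.character(getf(r, "subsystem", "Other")),
               stringsAsFactors = FALSE)
  }))
  stoich <- lapply(doc$reactions, function(r) {
    st <- r$stoichiometry
    if (is.null(st) || !length(st)) {
      stop("reaction ", r$id, " in ", path, " has empty stoichiometry")
    }
    vapply(st, as.numeric, numeric(1))
  })
  makeModel(modelId = doc$id, species = doc$species,
            metabolites = met, reactions = rxn, stoichiometry = stoich,
            biomassReaction = doc$biomass_reaction,
            atpmReaction = doc$atpm_reaction,
            biomassGAM = as.numeric(getf(doc, "biomass_gam", 0)))
}

fmtNum <- function(x) {
  ifelse(is.finite(x), vapply(x, function(v) {
    if (v == round(v) && abs(v) < 1e15) sprintf("%d", as.integer(round(v)))
    else sprintf("%.12g", v)
  }, character(1)), ifelse(x > 0, "Inf", "-Inf"))
}

#' Write a metabolic model
#'
#' Writes the canonical serialisation of a model; \code{format} is inferred
#' from the path (".json" or a directory / ".tsv" path) unless given.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param path output file (JSON) or directory (TSV pair).
#' @param format "json" or "tsv".
#' @return invisibly, the path written.
#' @export
writeModel <- function(model, path,
                       format = if (dir.exists(path) || grepl("\\.tsv$", path))
                         "tsv" else "json") {
  format <- match.arg(format, c("json", "tsv"))
  if (format == "tsv") return(writeModelTSV(model, path))
  met <- model@metabolites
  rxn <- model@reactions
  lines <- c("{",
    paste0('  "id": ', jsonlite::toJSON(model@modelId, auto_unbox = TRUE), ","),
    paste0('  "species": ', jsonlite::toJSON(model@species, auto_unbox = TRUE), ","),
    paste0('  "biomass_reaction": "', model@biomassReaction, '",'),
    paste0('  "atpm_reaction": "', model@atpmReaction, '",'),
    paste0('  "biomass_gam": ', fmtNum(model@biomassGAM), ","),
    '  "metabolites": [')
  mlines <- vapply(seq_len(nrow(met)), function(i) {
    ch <- if (is.na(met$charge[i])) "null" else fmtNum(met$charge[i])
    fo <- if (is.na(met$formula[i])) "null"
          else paste0('"', met$formula[i], '"')
    paste0('    {"id": "', met$id[i], '", "name": ',
           jsonlite::toJSON(met$name[i], auto_unbox = TRUE),
           ', "compartment": "', met$compartment[i],
           '", "formula": ', fo, ', "charge": ', ch, "}")
  }, character(1))
  lines <- c(lines, paste0(mlines, c(rep(",", length(mlines) - 1), "")),
             "  ],", '  "reactions": [')
  rlines <- vapply(seq_len(nrow(rxn)), function(j) {
    st <- model@S[, j]
    st <- st[st != 0]
    stj <- paste0('"', names(st), '": ', fmtNum(unname(st)), collapse = ", ")
    lo <- if (is.finite(rxn$lower[j])) fmtNum(rxn$lower[j])
          else paste0('"', fmtNum(rxn$lower[j]), '"')
    up <- if (is.finite(rxn$upper[j])) fmtNum(rxn$upper[j])
          else paste0('"', fmtNum(rxn$upper[j]), '"')
    paste0('    {"id": "', rxn$id[j], '", "name": ',
           jsonlite::toJSON(rxn$name[j], auto_unbox = TRUE),
           ', "lower": ', lo, ', "upper": ', up,
           ', "gpr": ', jsonlite::toJSON(rxn$gpr[j], auto_unbox = TRUE),
           ', "subsystem": "', rxn$subsystem[j],
           '", "stoichiometry": {', stj, "}}")
  }, character(1))
  lines <- c(lines, paste0(rlines, c(rep(",", length(rlines) - 1), "")),
             "  ]", "}")
  writeLines(lines, path)
  invisible(path)
}

readModelTSV <- function(path) {
  if (dir.exists(path)) {
    rpath <- file.path(path, "reactions.tsv")
    mpath <- file.path(path, "metabolites.tsv")
  } else {
    rpath <- path
    mpath <- file.path(dirname(path), "metabolites.tsv")
  }
  for (p in c(rpath, mpath)) if (!file.exists(p)) stop("no such file: ", p)
  hdr <- grep("^#", readLines(rpath, warn = FALSE), value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- strsplit(sub("^#", "", h), "=", fixed = TRUE)[[1]]
    if (length(kv) == 2) meta[[trimws(kv[1])]] <- trimws(kv[2])
  }
  for (f in c("model_id", "species", "biomass_reaction", "atpm_reaction")) {
    if (is.null(meta[[f]])) stop(rpath, " lacks header line #", f, "=")
  }
  met <- utils::read.delim(mpath, stringsAsFactors = FALSE, comment.char = "#",
                           na.strings = c("NA", ""))
  met$formula <- as.character(met$formula)
  met$charge <- suppressWarnings(as.numeric(met$charge))
  rxn <- utils::read.delim(rpath, stringsAsFactors = FALSE, comment.char = "#",
                           na.strings = "NA")
  rxn$gpr[is.na(rxn$gpr)] <- ""
  stoich <- lapply(seq_len(nrow(rxn)), function(j) {
    pairs <- strsplit(rxn$stoichiometry[j], ";", fixed = TRUE)[[1]]
    kv <- strsplit(pairs, ":", fixed = TRUE)
    bad <- vapply(kv, length, integer(1)) != 2
    if (any(bad)) {
      stop("record ", j, " (", rxn$id[j], ") in ", rpath,
           ": malformed stoichiometry pair")
    }
    stats::setNames(vapply(kv, function(p) as.numeric(p[2]), numeric(1)),
                    vapply(kv, `[`, character(1), 1))
  })
  rxn$lower <- as.numeric(rxn$lower)
  rxn$upper <- as.numeric(rxn$upper)
  makeModel(modelId = meta$model_id, species = meta$species,
            metabolites = met[, c("id", "name", "compartment", "formula",
                                  "charge")],
            reactions = rxn[, c("id", "name", "lower", "upper", "gpr",
                                "subsystem")],
            stoichiometry = stoich,
            biomassReaction = meta$biomass_reaction,
            atpmReaction = meta$atpm_reaction,
            biomassGAM = as.numeric(ifelse(is.null(meta$biomass_gam), 0,
                                           meta$biomass_gam)))
}

writeModelTSV <- function(model, path) {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  met <- model@metabolites
  rxn <- model@reactions
  mt <- data.frame(id = met$id, name = met$name,
                   compartment = met$compartment,
                   formula = ifelse(is.na(met$formula), "NA", met$formula),
                   charge = ifelse(is.na(met$charge), "NA",
                                   fmtNum(met$charge)),
                   stringsAsFactors = FALSE)
  utils::write.table(mt, file.path(path, "metabolites.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  st <- vapply(seq_len(nrow(rxn)), function(j) {
    col <- model@S[, j]
    col <- col[col != 0]
    paste0(names(col), ":", fmtNum(unname(col)), collapse = ";")
  }, character(1))
  rt <- data.frame(id = rxn$id, name = rxn$name, lower = fmtNum(rxn$lower),
                   upper = fmtNum(rxn$upper), gpr = rxn$gpr,
                   subsystem = rxn$subsystem, stoichiometry = st,
                   stringsAsFactors = FALSE)
  con <- file(file.path(path, "reactions.tsv"), "w")
  on.exit(close(con))
  writeLines(c(paste0("#model_id=", model@modelId),
               paste0("#species=", model@species),
               paste0("#biomass_reaction=", model@biomassReaction),
               paste0("#atpm_reaction=", model@atpmReaction),
               paste0("#biomass_gam=", fmtNum(model@biomassGAM))), con)
  utils::write.table(rt, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a model to SBML Level 3 (one-way)
#'
#' Writes a minimal SBML Level 3 Version 1 document with the fbc extension:
#' compartments, species, reactions with stoichiometry, flux bounds as fbc
#' bound parameters and the biomass reaction as the active objective. Export
#' only; SBML import of third-party models is out of scope.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param path output .xml file.
#' @return invisibly, the path written.
#' @export
exportSBML <- function(model, path) {
  doc <- xml2::xml_new_root(
    "sbml",
    xmlns = "http://www.sbml.org/sbml/level3/version1/core",
    "xmlns:fbc" = "http://www.sbml.org/sbml/level3/version1/fbc/version2",
    level = "3", version = "1", "fbc:required" = "false")
  mdl <- xml2::xml_add_child(doc, "model", id = model@modelId,
                             name = model@species, "fbc:strict" = "false")
  comps <- xml2::xml_add_child(mdl, "listOfCompartments")
  for (cp in c(c = "cytosol", e = "extracellular")) {
    xml2::xml_add_child(comps, "compartment",
                        id = names(which(c(c = "cytosol",
                                           e = "extracellular") == cp)),
                        name = cp, constant = "true")
  }
  sp <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (i in seq_len(nrow(model@metabolites))) {
    r <- model@metabolites[i, ]
    nd <- xml2::xml_add_child(sp, "species", id = paste0("M_", r$id),
                              name = r$name, compartment = r$compartment,
                              hasOnlySubstanceUnits = "false",
                              boundaryCondition = "false", constant = "false")
    if (!is.na(r$formula)) {
      xml2::xml_set_attr(nd, "fbc:chemicalFormula", r$formula)
    }
    if (!is.na(r$charge)) {
      xml2::xml_set_attr(nd, "fbc:charge", as.character(as.integer(r$charge)))
    }
  }
  pars <- xml2::xml_add_child(mdl, "listOfParameters")
  bndid <- function(v, j, side) {
    id <- sprintf("B_%s_%s", side, model@reactions$id[j])
    val <- if (is.finite(v)) fmtNum(v) else ifelse(v > 0, "INF", "-INF")
    xml2::xml_add_child(pars, "parameter", id = id, value = val,
                        constant = "true")
    id
  }
  rl <- xml2::xml_add_child(mdl, "listOfReactions")
  for (j in seq_len(nrow(model@reactions))) {
    r <- model@reactions[j, ]
    lo <- bndid(r$lower, j, "lb")
    up <- bndid(r$upper, j, "ub")
    nd <- xml2::xml_add_child(rl, "reaction", id = paste0("R_", r$id),
                              name = r$name, fast = "false",
                              reversible = ifelse(r$lower < 0, "true", "false"),
                              "fbc:lowerFluxBound" = lo,
                              "fbc:upperFluxBound" = up)
    st <- model@S[, j]
    sub <- st[st < 0]
    prod <- st[st > 0]
    if (length(sub)) {
      ls <- xml2::xml_add_child(nd, "listOfReactants")
      for (k in seq_along(sub)) {
        xml2::xml_add_child(ls, "speciesReference",
                            species = paste0("M_", names(sub)[k]),
                            stoichiometry = fmtNum(-unname(sub[k])),
                            constant = "true")
      }
    }
    if (length(prod)) {
      lp <- xml2::xml_add_child(nd, "listOfProducts")
      for (k in seq_along(prod)) {
        xml2::xml_add_child(lp, "speciesReference",
                            species = paste0("M_", names(prod)[k]),
                            stoichiometry = fmtNum(unname(prod[k])),
                            constant = "true")
      }
    }
  }
  objs <- xml2::xml_add_child(mdl, "fbc:listOfObjectives",
                              "fbc:activeObjective" = "obj")
  ob <- xml2::xml_add_child(objs, "fbc:objective", "fbc:id" = "obj",
                            "fbc:type" = "maximize")
  fl <- xml2::xml_add_child(ob, "fbc:listOfFluxObjectives")
  xml2::xml_add_child(fl, "fbc:fluxObjective",
                      "fbc:reaction" = paste0("R_", model@biomassReaction),
                      "fbc:coefficient" = "1")
  xml2::write_xml(doc, path)
  invisible(path)
}
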