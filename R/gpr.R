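# Gene-protein-reaction (GPR) rules: OR of AND-groups, written with "&" for
# complexes (e.g. "Pcar_2542 & Pcar_2543") and "or" for isozymes, with
# parentheses allowed. An empty rule means non-gene-associated.

gprTokenize <- function(gpr) {
  if (is.na(gpr) || !nzchar(trimws(gpr))) return(character(0))
  s <- gsub("([()&])", " \\1 ", gpr)
  toks <- strsplit(trimws(s), "[[:space:]]+")[[1]]
  toks[nzchar(toks)]
}

#' Genes referenced by a GPR rule
#'
#' @param gpr GPR rule string.
#' @return character vector of gene ids (empty for non-gene reactions).
#' @export
gprGenes <- function(gpr) {
  toks <- gprTokenize(gpr)
  toks <- toks[!(tolower(toks) %in% c("or", "and")) & !(toks %in% c("&", "(", ")"))]
  unique(toks)
}

#' Evaluate a GPR rule against a set of expressed genes
#'
#' A reaction is active iff at least one AND-group of its rule has all genes
#' in the expressed set; reactions with an empty rule (non-gene-associated)
#' are always active.
#'
#' @param gpr GPR rule string ("" = non-gene-associated).
#' @param expressed character vector of expressed gene ids.
#' @return logical active flag.
#' @export
evaluateGPR <- function(gpr, expressed) {
  toks <- gprTokenize(gpr)
  if (!length(toks)) return(TRUE)
  out <- character(length(toks))
  for (i in seq_along(toks)) {
    t <- toks[i]
    if (t == "&" || tolower(t) == "and") out[i] <- "&"
    else if (tolower(t) == "or") out[i] <- "|"
    else if (t %in% c("(", ")")) out[i] <- t
    else if (grepl("^[A-Za-z][A-Za-z0-9_.]*$", t)) {
      out[i] <- if (t %in% expressed) "TRUE" else "FALSE"
    } else stop("malformed GPR token: '", t, "' in rule: ", gpr)
  }
  expr <- paste(out, collapse = " ")
  val <- tryCatch(eval(parse(text = expr), envir = baseenv()),
                  error = function(e) stop("malformed GPR rule: ", gpr))
  if (!is.logical(val) || length(val) != 1L || is.na(val)) {
    stop("malformed GPR rule: ", gpr)
  }
  val
}

#' Close reactions whose genes are not expressed
#'
#' Applies an expression profile to a model: genes with expression level at
#' or above the threshold count as expressed, each reaction's GPR rule is
#' evaluated against that set, and reactions evaluating inactive are closed
#' (both bounds set to zero). Non-gene-associated reactions, the biomass and
#' ATP-maintenance reactions, and exchange reactions are never closed.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param profile named numeric vector: gene id -> nonnegative expression
#'   level. Ids absent from the model's GPR rules are ignored with a warning.
#' @param threshold nonnegative closure threshold; genes with level >=
#'   threshold are treated as expressed.
#' @return a modified copy of the model.
#' @export
applyExpressionClosure <- function(model, profile, threshold) {
  stopifnot(is.numeric(profile), threshold >= 0)
  if (length(profile) && is.null(names(profile))) {
    stop("profile must be a named numeric vector")
  }
  if (any(profile < 0)) stop("expression levels must be nonnegative")
  known <- geneIds(model)
  unknown <- setdiff(names(profile), known)
  if (length(unknown)) {
    warning("ignoring unknown gene id(s): ", paste(unknown, collapse = ", "))
  }
  if (!length(profile)) return(model)
  expressed <- names(profile)[profile >= threshold]
  # genes absent from the profile are treated as expressed (no evidence
  # against them)
  expressed <- union(expressed, setdiff(known, names(profile)))
  protected <- c(model@biomassReaction, model@atpmReaction,
                 exchangeReactions(model))
  for (j in seq_len(nrow(model@reactions))) {
    rid <- model@reactions$id[j]
    gpr <- model@reactions$gpr[j]
    if (!nzchar(gpr) || rid %in% protected) next
    if (!evaluateGPR(gpr, expressed)) {
      model@reactions$lower[j] <- 0
      model@reactions$upper[j] <- 0
    }
  }
  model
}
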