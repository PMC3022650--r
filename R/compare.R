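# Cross-model reaction-set comparison by functional category.

# canonical stoichiometry signature: metabolite ids sorted, coefficients
# scaled so the smallest magnitude is 1, sign fixed so the lexicographically
# first metabolite has a negative coefficient (direction-insensitive)
reactionSignature <- function(st) {
  st <- st[st != 0]
  st <- st[order(names(st))]
  st <- st / min(abs(st))
  if (st[1] > 0) st <- -st
  paste(names(st), format(round(st, 6), trim = TRUE, scientific = FALSE),
        sep = ":", collapse = "|")
}

#' Compare reaction sets across models by functional category
#'
#' Matches reactions across two or more models — by canonicalised
#' stoichiometry (default; metabolite ids sorted, coefficients normalised to
#' the smallest magnitude, direction-insensitive) or by reaction id — and
#' tabulates per category and per model the total and unique reaction
#' counts (unique = present in exactly one of the models) plus the count of
#' reactions common to all models.
#'
#' @param models list of \linkS4class{MetabolicModel} objects (>= 2).
#' @param matchOn "stoichiometry" (default) or "id".
#' @return list with \code{table} (per category x model: total, unique,
#'   pctUnique; category "Total reactions" summarises), \code{common}
#'   (named numeric, common count per category plus "Total reactions"),
#'   and \code{matchOn}.
#' @export
compareModels <- function(models, matchOn = c("stoichiometry", "id")) {
  matchOn <- match.arg(matchOn)
  stopifnot(length(models) >= 2)
  keysOf <- function(m) {
    if (matchOn == "id") {
      k <- m@reactions$id
    } else {
      k <- vapply(seq_len(nrow(m@reactions)), function(j) {
        reactionSignature(m@S[, j])
      }, character(1))
    }
    data.frame(key = k, subsystem = m@reactions$subsystem,
               stringsAsFactors = FALSE)
  }
  keys <- lapply(models, keysOf)
  # deduplicate within each model (isozyme duplicates count once)
  keys <- lapply(keys, function(k) k[!duplicated(k$key), , drop = FALSE])
  labels <- vapply(models, function(m) m@modelId, character(1))
  if (anyDuplicated(labels)) labels <- make.unique(labels)
  presence <- table(unlist(lapply(keys, function(k) unique(k$key))))
  cats <- c(SUBSYSTEMS, "Total reactions")
  rows <- list()
  common <- stats::setNames(numeric(length(cats)), cats)
  # subsystem of a key: taken from the first model containing it
  subsysOf <- new.env(parent = emptyenv())
  for (k in keys) {
    for (i in seq_len(nrow(k))) {
      if (is.null(subsysOf[[k$key[i]]])) subsysOf[[k$key[i]]] <- k$subsystem[i]
    }
  }
  allKeys <- names(presence)
  allSub <- vapply(allKeys, function(x) subsysOf[[x]], character(1))
  for (cat in cats) {
    inCat <- if (cat == "Total reactions") rep(TRUE, length(allKeys))
             else allSub == cat
    common[cat] <- sum(presence[inCat] == length(models))
    for (mi in seq_along(models)) {
      k <- keys[[mi]]
      mine <- if (cat == "Total reactions") k$key
              else k$key[k$subsystem == cat]
      uniq <- sum(presence[mine] == 1L)
      rows[[length(rows) + 1L]] <- data.frame(
        category = cat, model = labels[mi], total = length(mine),
        unique = uniq,
        pctUnique = if (length(mine)) uniq / length(mine) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  list(table = do.call(rbind, rows), common = common, matchOn = matchOn)
}
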