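#' @rdname accessors
#' @export
setGeneric("reactions", function(object) standardGeneric("reactions"))

#' @rdname accessors
#' @export
setGeneric("metabolites", function(object) standardGeneric("metabolites"))

#' @rdname accessors
#' @export
setGeneric("stoichiometryMatrix",
           function(object) standardGeneric("stoichiometryMatrix"))

#' @rdname accessors
#' @export
setGeneric("biomassReaction",
           function(object) standardGeneric("biomassReaction"))

#' @rdname accessors
#' @export
setGeneric("atpmReaction", function(object) standardGeneric("atpmReaction"))

#' @rdname accessors
#' @export
setGeneric("exchangeReactions",
           function(object) standardGeneric("exchangeReactions"))

#' @rdname accessors
#' @export
setGeneric("geneIds", function(object) standardGeneric("geneIds"))

#' @rdname accessors
#' @export
setGeneric("fluxes", function(object) standardGeneric("fluxes"))

#' @rdname accessors
#' @export
setGeneric("solverStatus", function(object) standardGeneric("solverStatus"))

#' @rdname accessors
#' @export
setGeneric("objectiveValue",
           function(object) standardGeneric("objectiveValue"))
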