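#' @name FluxBalanceR-generics
#' @title Accessor generics for FluxBalanceR classes
#' @description Accessors are the supported way to inspect model objects;
#'   slot access is not part of the API.
#' @param object an object.
#' @keywords internal
NULL

#' @rdname FluxBalanceR-generics
#' @export
setGeneric("metabolites", function(object) standardGeneric("metabolites"))

#' @rdname FluxBalanceR-generics
#' @export
setGeneric("reactions", function(object) standardGeneric("reactions"))

#' @rdname FluxBalanceR-generics
#' @export
setGeneric("genes", function(object) standardGeneric("genes"))

#' @rdname FluxBalanceR-generics
#' @export
setGeneric("stoichiometry", function(object) standardGeneric("stoichiometry"))

#' @rdname FluxBalanceR-generics
#' @export
setGeneric("biomassReaction", function(object) standardGeneric("biomassReaction"))

#' @rdname FluxBalanceR-generics
#' @export
setGeneric("compartments", function(object) standardGeneric("compartments"))

#' @rdname FluxBalanceR-generics
#' @export
setGeneric("exchangeReactions", function(object) standardGeneric("exchangeReactions"))

#' @rdname FluxBalanceR-generics
#' @export
setGeneric("reactionGPR", function(object, reaction) standardGeneric("reactionGPR"))

#' @rdname FluxBalanceR-generics
#' @export
setGeneric("objectiveValue", function(object) standardGeneric("objectiveValue"))

#' @rdname FluxBalanceR-generics
#' @export
setGeneric("fluxes", function(object) standardGeneric("fluxes"))

#' @rdname FluxBalanceR-generics
#' @export
setGeneric("solutionStatus", function(object) standardGeneric("solutionStatus"))
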