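#' MetabolicModel: a compartmentalized stoichiometric model
#'
#' The central S4 container of the package. Holds metabolites, reactions with
#' flux bounds and Boolean gene-protein-reaction (GPR) associations, the
#' stoichiometric matrix, the gene list, the biomass reaction id and the
#' compartment set. Reversibility is encoded purely by the bounds
#' (reversible: -1000/1000, irreversible: 0/1000 by default); there is no
#' separate flag. Exchange reactions are boundary pseudo-reactions touching
#' exactly one extracellular metabolite; uptake through an exchange is a
#' negative flux.
#'
#' Compartment labels are free tokens, but the label \code{"e"} is reserved
#' for the extracellular space (used to validate exchange reactions), and
#' metabolite ids carry their compartment as a bracket suffix, e.g.
#' \code{glc[e]}.
#'
#' @slot metabolites data.frame with columns \code{id}, \code{name},
#'   \code{compartment}, \code{formula}.
#' @slot reactions data.frame with columns \code{id}, \code{name},
#'   \code{lower_bound}, \code{upper_bound}, \code{subsystem}, \code{gpr}
#'   (string form), \code{is_exchange}, \code{is_transport}. Bounds are in
#'   mmol/gDCW/h (the biomass reaction flux is in 1/h).
#' @slot S dense stoichiometric matrix, metabolites x reactions, with
#'   dimnames; negative coefficients are consumed metabolites.
#' @slot gprTrees list of parsed GPR trees (or NULL), parallel to reactions.
#' @slot genes character vector of all gene identifiers.
#' @slot biomassReactionId id of the biomass reaction.
#' @slot compartments declared compartment labels.
#'
#' @name MetabolicModel-class
#' @aliases MetabolicModel-class
#' @exportClass MetabolicModel
setClass("MetabolicModel",
  representation(
    metabolites = "data.frame",
    reactions = "data.frame",
    S = "matrix",
    gprTrees = "list",
    genes = "character",
    biomassReactionId = "character",
    compartments = "character"
  )
)

setValidity("MetabolicModel", function(object) {
  msg <- character(0)
  met <- object@metabolites
  rxn <- object@reactions
  if (anyDuplicated(met$id)) {
    msg <- c(msg, paste("duplicate metabolite id:",
                        paste(unique(met$id[duplicated(met$id)]), collapse = ", ")))
  }
  if (anyDuplicated(rxn$id)) {
    msg <- c(msg, paste("duplicate reaction id:",
                        paste(unique(rxn$id[duplicated(rxn$id)]), collapse = ", ")))
  }
  if (!all(met$compartment %in% object@compartments)) {
    msg <- c(msg, "metabolite compartment outside the declared compartment set")
  }
  if (nrow(object@S) != nrow(met) || ncol(object@S) != nrow(rxn)) {
    msg <- c(msg, "stoichiometric matrix dimensions must be (|metabolites|, |reactions|)")
  } else {
    if (!identical(rownames(object@S), met$id) || !identical(colnames(object@S), rxn$id)) {
      msg <- c(msg, "stoichiometric matrix dimnames must match metabolite/reaction ids")
    }
    empty <- colSums(abs(object@S)) == 0
    if (any(empty)) {
      msg <- c(msg, paste("reaction with empty stoichiometry:",
                          paste(rxn$id[empty], collapse = ", ")))
    }
    nm <- colSums(object@S != 0)
    bad <- rxn$is_exchange & nm != 1L
    if (any(bad)) {
      msg <- c(msg, paste("exchange reaction touching != 1 metabolite:",
                          paste(rxn$id[bad], collapse = ", ")))
    }
    if (nrow(met) > 0) {
      exch1 <- which(rxn$is_exchange & nm == 1L)
      for (j in exch1) {
        i <- which(object@S[, j] != 0)
        if (met$compartment[i] != "e") {
          msg <- c(msg, paste("exchange reaction", rxn$id[j],
                              "touches a non-extracellular metabolite"))
        }
      }
    }
  }
  if (any(rxn$lower_bound > rxn$upper_bound + 1e-12)) {
    msg <- c(msg, "lower_bound > upper_bound for some reaction")
  }
  if (length(object@gprTrees) != nrow(rxn)) {
    msg <- c(msg, "gprTrees must be parallel to reactions")
  } else {
    leaf <- unique(unlist(lapply(object@gprTrees, gprGenes)))
    orphan <- setdiff(leaf, object@genes)
    if (length(orphan)) {
      msg <- c(msg, paste("GPR references genes absent from the gene list:",
                          paste(orphan, collapse = ", ")))
    }
  }
  if (length(object@biomassReactionId) == 1L && nzchar(object@biomassReactionId) &&
      !(object@biomassReactionId %in% rxn$id)) {
    msg <- c(msg, paste("biomass reaction id does not resolve:", object@biomassReactionId))
  }
  if (length(msg)) msg else TRUE
})

#' MediumSpec: a named growth condition as exchange-bound overrides
#'
#' @slot name condition label (e.g. \code{"xylose-aerobic"}).
#' @slot bounds matrix with columns \code{lower}, \code{upper} and exchange
#'   reaction ids as rownames; all rates in mmol/gDCW/h.
#' @exportClass MediumSpec
setClass("MediumSpec",
  representation(name = "character", bounds = "matrix")
)

setValidity("MediumSpec", function(object) {
  b <- object@bounds
  if (ncol(b) != 2L || !identical(colnames(b), c("lower", "upper"))) {
    return("bounds must have columns 'lower' and 'upper'")
  }
  if (is.null(rownames(b)) && nrow(b) > 0) return("bounds must have reaction ids as rownames")
  if (any(b[, "lower"] > b[, "upper"] + 1e-12)) return("lower > upper in a bound override")
  TRUE
})

#' FluxSolution: result of one flux balance analysis solve
#'
#' @slot objectiveReactionId objective reaction.
#' @slot objectiveValue optimal objective value (NA unless status "optimal").
#' @slot fluxes named numeric flux vector (length 0 unless optimal).
#' @slot status one of \code{"optimal"}, \code{"infeasible"}, \code{"unbounded"}.
#' @exportClass FluxSolution
setClass("FluxSolution",
  representation(
    objectiveReactionId = "character",
    objectiveValue = "numeric",
    fluxes = "numeric",
    status = "character"
  )
)

#' RobustnessCurve: objective response to a swept fixed uptake
#'
#' @slot controlledReactionId the exchange reaction being fixed.
#' @slot grid uptake rates (mmol/gDCW/h, positive = consumption), strictly monotone.
#' @slot responses maximized objective at each grid point; NA where infeasible.
#' @exportClass RobustnessCurve
setClass("RobustnessCurve",
  representation(
    controlledReactionId = "character",
    grid = "numeric",
    responses = "numeric"
  )
)

setValidity("RobustnessCurve", function(object) {
  if (length(object@grid) != length(object@responses)) {
    return("grid and responses must have the same length")
  }
  d <- diff(object@grid)
  if (length(d) && !(all(d > 0) || all(d < 0))) return("grid must be strictly monotone")
  TRUE
})

#' GapReport: dead-end metabolites and blocked reactions
#'
#' @slot noProduction metabolites that cannot carry net production.
#' @slot noConsumption metabolites that cannot carry net consumption.
#' @slot blockedReactions reactions whose flux range is identically zero.
#' @exportClass GapReport
setClass("GapReport",
  representation(
    noProduction = "character",
    noConsumption = "character",
    blockedReactions = "character"
  )
)
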