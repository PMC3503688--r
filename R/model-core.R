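## Construction, accessors and summary statistics for MetabolicModel.

DEFAULT_UB <- 1000
DEFAULT_LB_REV <- -1000

#' Construct a MetabolicModel
#'
#' Builds and validates the S4 model container from plain tables. Exchange
#' and transport flags are inferred from the stoichiometry when not given:
#' a reaction touching exactly one metabolite in the extracellular
#' compartment (\code{"e"}) is an exchange; a reaction touching two or more
#' compartments is a transport. The gene list is inferred from the GPRs when
#' not supplied.
#'
#' @param metabolites data.frame with at least an \code{id} column; optional
#'   \code{name}, \code{compartment}, \code{formula}. If \code{compartment}
#'   is missing it is taken from the id's bracket suffix (\code{met[c]}).
#' @param reactions data.frame with at least an \code{id} column; optional
#'   \code{name}, \code{lower_bound}, \code{upper_bound} (defaults -1000/1000
#'   for reversible rows, 0/1000 if a logical \code{reversible} column says
#'   otherwise), \code{subsystem}, \code{gpr}, \code{is_exchange},
#'   \code{is_transport}.
#' @param stoichiometry named list, one entry per reaction id, each a named
#'   numeric vector of metabolite coefficients (negative = consumed).
#' @param biomass id of the biomass reaction ("" if none).
#' @param genes gene identifiers; default: union of GPR leaves.
#' @param compartments compartment labels; default: those used by metabolites.
#' @return a validated \linkS4class{MetabolicModel}.
#' @examples
#' m <- MetabolicModel(
#'   metabolites = data.frame(id = c("a[e]", "a[c]")),
#'   reactions = data.frame(id = c("EX_a", "At"),
#'                          lower_bound = c(-10, 0), upper_bound = c(1000, 1000)),
#'   stoichiometry = list(EX_a = c(`a[e]` = -1), At = c(`a[e]` = -1, `a[c]` = 1)),
#'   biomass = ""
#' )
#' reactions(m)$is_exchange
#' @export
MetabolicModel <- function(metabolites, reactions, stoichiometry,
                           biomass = "", genes = NULL, compartments = NULL) {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  if (is.null(metabolites$compartment)) {
    metabolites$compartment <- compartmentOf(metabolites$id)
  }
  if (is.null(metabolites$name)) metabolites$name <- metabolites$id
  if (is.null(metabolites$formula)) metabolites$formula <- NA_character_
  metabolites <- metabolites[, c("id", "name", "compartment", "formula")]

  if (is.null(reactions$name)) reactions$name <- reactions$id
  if (is.null(reactions$subsystem)) reactions$subsystem <- NA_character_
  if (is.null(reactions$gpr)) reactions$gpr <- ""
  reactions$gpr[is.na(reactions$gpr)] <- ""
  if (is.null(reactions$lower_bound)) {
    rev <- if (!is.null(reactions$reversible)) reactions$reversible else TRUE
    reactions$lower_bound <- ifelse(rev, DEFAULT_LB_REV, 0)
  }
  if (is.null(reactions$upper_bound)) reactions$upper_bound <- DEFAULT_UB

  missingRxn <- setdiff(reactions$id, names(stoichiometry))
  if (length(missingRxn)) {
    stop("no stoichiometry given for reaction(s): ", paste(missingRxn, collapse = ", "))
  }
  S <- matrix(0, nrow(metabolites), nrow(reactions),
              dimnames = list(metabolites$id, reactions$id))
  for (rid in reactions$id) {
    st <- stoichiometry[[rid]]
    unknown <- setdiff(names(st), metabolites$id)
    if (length(unknown)) {
      stop("reaction ", rid, " references unknown metabolite(s): ",
           paste(unknown, collapse = ", "))
    }
    S[names(st), rid] <- as.numeric(st)
  }

  trees <- lapply(reactions$gpr, gprParse)
  reactions$gpr <- vapply(trees, gprDeparse, character(1))
  if (is.null(genes)) genes <- sort(unique(unlist(lapply(trees, gprGenes))))
  if (is.null(compartments)) compartments <- sort(unique(metabolites$compartment))

  nmet <- colSums(S != 0)
  if (is.null(reactions$is_exchange)) {
    extramet <- metabolites$compartment == "e"
    reactions$is_exchange <- vapply(seq_len(ncol(S)), function(j) {
      nmet[j] == 1L && extramet[which(S[, j] != 0)]
    }, logical(1))
  }
  if (is.null(reactions$is_transport)) {
    reactions$is_transport <- vapply(seq_len(ncol(S)), function(j) {
      idx <- which(S[, j] != 0)
      length(unique(metabolites$compartment[idx])) >= 2L
    }, logical(1))
  }
  reactions <- reactions[, c("id", "name", "lower_bound", "upper_bound",
                             "subsystem", "gpr", "is_exchange", "is_transport")]
  rownames(metabolites) <- NULL
  rownames(reactions) <- NULL

  methods::new("MetabolicModel",
               metabolites = metabolites, reactions = reactions, S = S,
               gprTrees = trees, genes = genes,
               biomassReactionId = biomass, compartments = compartments)
}

#' Compartment token from a bracket-suffixed metabolite id
#' @param id metabolite id(s) like \code{"glc[e]"}.
#' @return compartment token(s); \code{"c"} when no suffix is present.
#' @keywords internal
compartmentOf <- function(id) {
  out <- sub("^.*\\[([^][]+)\\]$", "\\1", id)
  out[out == id] <- "c"
  out
}

#' @rdname FluxBalanceR-generics
#' @export
setMethod("metabolites", "MetabolicModel", function(object) object@metabolites)

#' @rdname FluxBalanceR-generics
#' @export
setMethod("reactions", "MetabolicModel", function(object) object@reactions)

#' @rdname FluxBalanceR-generics
#' @export
setMethod("genes", "MetabolicModel", function(object) object@genes)

#' @rdname FluxBalanceR-generics
#' @export
setMethod("stoichiometry", "MetabolicModel", function(object) object@S)

#' @rdname FluxBalanceR-generics
#' @export
setMethod("biomassReaction", "MetabolicModel", function(object) object@biomassReactionId)

#' @rdname FluxBalanceR-generics
#' @export
setMethod("compartments", "MetabolicModel", function(object) object@compartments)

#' @rdname FluxBalanceR-generics
#' @export
setMethod("exchangeReactions", "MetabolicModel", function(object) {
  object@reactions$id[object@reactions$is_exchange]
})

#' @rdname FluxBalanceR-generics
#' @param reaction a reaction id.
#' @export
setMethod("reactionGPR", "MetabolicModel", function(object, reaction) {
  j <- match(reaction, object@reactions$id)
  if (is.na(j)) stop("unknown reaction: ", reaction)
  object@gprTrees[[j]]
})

#' @rdname FluxBalanceR-generics
#' @export
setMethod("objectiveValue", "FluxSolution", function(object) object@objectiveValue)

#' @rdname FluxBalanceR-generics
#' @export
setMethod("fluxes", "FluxSolution", function(object) object@fluxes)

#' @rdname FluxBalanceR-generics
#' @export
setMethod("solutionStatus", "FluxSolution", function(object) object@status)

setMethod("show", "MetabolicModel", function(object) {
  cat("MetabolicModel:", nrow(object@metabolites), "metabolites,",
      nrow(object@reactions), "reactions,", length(object@genes), "genes\n")
  cat("  compartments:", paste(object@compartments, collapse = ", "), "\n")
  cat("  exchange reactions:", sum(object@reactions$is_exchange), "\n")
  if (nzchar(object@biomassReactionId)) {
    cat("  biomass reaction:", object@biomassReactionId, "\n")
  }
})

setMethod("show", "FluxSolution", function(object) {
  cat("FluxSolution:", object@status, "\n")
  if (object@status == "optimal") {
    cat("  objective (", object@objectiveReactionId, "): ",
        format(object@objectiveValue, digits = 6), "\n", sep = "")
  }
})

setMethod("show", "MediumSpec", function(object) {
  cat("MediumSpec:", object@name, "(", nrow(object@bounds), "bound overrides )\n")
})

setMethod("show", "RobustnessCurve", function(object) {
  ok <- !is.na(object@responses)
  cat("RobustnessCurve over", object@controlledReactionId, ":",
      length(object@grid), "points,", sum(!ok), "infeasible\n")
  if (any(ok)) {
    i <- which.max(object@responses)
    cat("  maximum response", format(object@responses[i], digits = 6),
        "at uptake", object@grid[i], "\n")
  }
})

setMethod("show", "GapReport", function(object) {
  cat("GapReport:", length(object@noProduction), "no-production,",
      length(object@noConsumption), "no-consumption metabolites;",
      length(object@blockedReactions), "blocked reactions\n")
})

#' Update reaction bounds
#'
#' Returns a copy of the model with the named reactions' bounds replaced.
#' @param model a \linkS4class{MetabolicModel}.
#' @param ids reaction ids.
#' @param lower,upper new bounds, recycled to \code{length(ids)}; \code{NA}
#'   keeps the current value.
#' @return the modified model.
#' @export
setReactionBounds <- function(model, ids, lower = NA, upper = NA) {
  j <- match(ids, model@reactions$id)
  if (anyNA(j)) stop("unknown reaction(s): ", paste(ids[is.na(j)], collapse = ", "))
  lower <- rep_len(lower, length(ids))
  upper <- rep_len(upper, length(ids))
  keepL <- is.na(lower)
  keepU <- is.na(upper)
  model@reactions$lower_bound[j][!keepL] <- lower[!keepL]
  model@reactions$upper_bound[j][!keepU] <- upper[!keepU]
  methods::validObject(model)
  model
}

#' Summary statistics of a metabolic model
#'
#' Reports raw counts: genes, metabolites, reactions, gene-associated and
#' non-gene-associated reactions, how many of the non-gene-associated ones
#' are transport reactions, and reactions per subsystem. Counts are reported
#' as-is; apparent inconsistencies in published figures are left to the user.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @return a list with elements \code{genes}, \code{metabolites},
#'   \code{reactions}, \code{gene_associated}, \code{non_gene_associated},
#'   \code{non_gene_associated_transport}, and a data.frame
#'   \code{per_subsystem}.
#' @examples
#' m <- toyStipitisModel()
#' modelStatistics(m)$reactions
#' @export
modelStatistics <- function(model) {
  stopifnot(methods::is(model, "MetabolicModel"))
  hasGene <- vapply(model@gprTrees, function(t) !is.null(t), logical(1))
  rxn <- model@reactions
  sub <- table(rxn$subsystem, useNA = "ifany")
  list(
    genes = length(model@genes),
    metabolites = nrow(model@metabolites),
    reactions = nrow(rxn),
    gene_associated = sum(hasGene),
    non_gene_associated = sum(!hasGene),
    non_gene_associated_transport = sum(!hasGene & rxn$is_transport),
    per_subsystem = data.frame(subsystem = names(sub), reactions = as.integer(sub),
                               row.names = NULL)
  )
}
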