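## Dead-end metabolite detection and minimal gap filling.
##
## Production/consumption tests run, by default, with every exchange lower
## bound opened to -1000 so that gaps reflect network topology rather than
## medium starvation; pass a medium to test under a specific condition
## instead. A metabolite is a no-production (no-consumption) dead end when a
## temporary drain (supply) reaction attached to it cannot carry flux above
## 1e-9. Blocked reactions have an identically zero flux range.

#' Find dead-end metabolites and blocked reactions
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param medium optional \linkS4class{MediumSpec}; when NULL all exchange
#'   lower bounds are opened to -1000 (topology-level test).
#' @param tol flux threshold below which a test counts as zero (default 1e-9).
#' @return a \linkS4class{GapReport}.
#' @examples
#' net <- generateNetwork(syntheticSpec(n_deadends = 2, seed = 5))
#' findGaps(net$model)
#' @export
findGaps <- function(model, medium = NULL, tol = 1e-9) {
  if (is.null(medium)) {
    exch <- exchangeReactions(model)
    model <- setReactionBounds(model, exch, -1000, NA)
  } else {
    model <- applyMedium(model, medium)
  }
  S <- model@S
  m <- nrow(S); n <- ncol(S)
  lb <- model@reactions$lower_bound
  ub <- model@reactions$upper_bound
  testMet <- function(i, produce) {
    ## temporary drain (produce test) or supply (consume test) column
    col <- numeric(m); col[i] <- if (produce) -1 else 1
    A <- cbind(S, col)
    obj <- c(numeric(n), 1)
    r <- simplexBounded(obj, A, rep(0, m), c(lb, 0), c(ub, 1000), maximize = TRUE)
    r$status == "optimal" && r$objective > tol
  }
  canProduce <- vapply(seq_len(m), testMet, logical(1), produce = TRUE)
  canConsume <- vapply(seq_len(m), testMet, logical(1), produce = FALSE)
  fva <- fluxVariability(model)
  blocked <- fva$id[!is.na(fva$min) & !is.na(fva$max) &
                    abs(fva$min) <= tol & abs(fva$max) <= tol]
  methods::new("GapReport",
               noProduction = sort(model@metabolites$id[!canProduce]),
               noConsumption = sort(model@metabolites$id[!canConsume]),
               blockedReactions = sort(blocked))
}

#' Minimal gap filling from a universal reaction pool
#'
#' For each target metabolite, finds a minimum-cardinality subset of pool
#' reactions whose addition makes the target producible at
#' \code{min_production}, by a MILP with one binary inclusion variable per
#' pool reaction (pool bounds are switched off unless included). Among
#' minimum-cardinality solutions the tie is broken deterministically towards
#' lexicographically early pool reaction ids via vanishing rank weights.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param universal_pool a \linkS4class{MetabolicModel} holding candidate
#'   reactions (readable with the same dialects); its reaction ids must not
#'   clash with the model's, and its metabolites are merged by id.
#' @param targets metabolite ids to make producible.
#' @param min_production flux the temporary target drain must carry (default 1).
#' @param max_additions cap on additions per target (default 3).
#' @param open_exchanges open all model exchange lower bounds to -1000 before
#'   testing (default TRUE, matching \code{\link{findGaps}}).
#' @return named list per target: character vector of added pool reaction ids,
#'   or NA if the target cannot be repaired within \code{max_additions}.
#' @export
fillGaps <- function(model, universal_pool, targets, min_production = 1,
                     max_additions = 3, open_exchanges = TRUE) {
  stopifnot(methods::is(universal_pool, "MetabolicModel"))
  if (open_exchanges) {
    model <- setReactionBounds(model, exchangeReactions(model), -1000, NA)
  }
  clash <- intersect(universal_pool@reactions$id, model@reactions$id)
  if (length(clash)) stop("pool reaction ids clash with the model: ",
                          paste(clash, collapse = ", "))
  poolIds <- sort(universal_pool@reactions$id)
  mets <- union(model@metabolites$id, universal_pool@metabolites$id)
  unknownT <- setdiff(targets, mets)
  if (length(unknownT)) stop("unknown target metabolite(s): ",
                             paste(unknownT, collapse = ", "))

  m <- length(mets); n <- ncol(model@S); np <- length(poolIds)
  Sfull <- matrix(0, m, n + np, dimnames = list(mets, c(colnames(model@S), poolIds)))
  Sfull[rownames(model@S), colnames(model@S)] <- model@S
  Sfull[rownames(universal_pool@S), poolIds] <- universal_pool@S[, poolIds]
  lbP <- universal_pool@reactions$lower_bound[match(poolIds, universal_pool@reactions$id)]
  ubP <- universal_pool@reactions$upper_bound[match(poolIds, universal_pool@reactions$id)]
  lbM <- model@reactions$lower_bound
  ubM <- model@reactions$upper_bound

  out <- stats::setNames(vector("list", length(targets)), targets)
  for (tg in targets) {
    ti <- match(tg, mets)
    drain <- numeric(m); drain[ti] <- -1
    ## columns: model fluxes | pool fluxes | drain | binaries b
    A <- cbind(Sfull, drain, matrix(0, m, np))
    rhs <- rep(0, m); sense <- rep("=", m)
    ## switch rows: v_p - ub_p b_p <= 0 ; -v_p + lb_p b_p <= 0
    for (k in seq_len(np)) {
      r1 <- numeric(n + np + 1 + np); r1[n + k] <- 1; r1[n + np + 1 + k] <- -ubP[k]
      r2 <- numeric(n + np + 1 + np); r2[n + k] <- -1; r2[n + np + 1 + k] <- lbP[k]
      A <- rbind(A, r1, r2); rhs <- c(rhs, 0, 0); sense <- c(sense, "<=", "<=")
    }
    ## addition budget
    rb <- numeric(n + np + 1 + np); rb[n + np + 1 + seq_len(np)] <- 1
    A <- rbind(A, rb); rhs <- c(rhs, max_additions); sense <- c(sense, "<=")
    lo <- c(lbM, pmin(lbP, 0), min_production, rep(0, np))
    hiv <- c(ubM, pmax(ubP, 0), 1000, rep(1, np))
    obj <- c(rep(0, n + np + 1), 1 + seq_len(np) * 1e-7)
    sol <- solveMILP(obj, A, rhs, sense, lo, hiv,
                     binaryIndex = n + np + 1 + seq_len(np), maximize = FALSE)
    if (sol$status != "optimal" || is.null(sol$x)) {
      out[[tg]] <- NA_character_
    } else {
      out[[tg]] <- poolIds[sol$x[n + np + 1 + seq_len(np)] > 0.5]
    }
  }
  out
}

#' Merge pool reactions into a model
#'
#' Adds the named pool reactions (e.g. a \code{\link{fillGaps}} result) to
#' the model, merging metabolite namespaces by id.
#' @param model a \linkS4class{MetabolicModel}.
#' @param universal_pool pool model.
#' @param reaction_ids pool reactions to add.
#' @return the extended \linkS4class{MetabolicModel}.
#' @export
addPoolReactions <- function(model, universal_pool, reaction_ids) {
  jp <- match(reaction_ids, universal_pool@reactions$id)
  if (anyNA(jp)) stop("unknown pool reaction(s): ",
                      paste(reaction_ids[is.na(jp)], collapse = ", "))
  mets <- union(model@metabolites$id, rownames(universal_pool@S)[
    rowSums(abs(universal_pool@S[, jp, drop = FALSE])) > 0])
  newMets <- setdiff(mets, model@metabolites$id)
  metTab <- rbind(model@metabolites,
                  universal_pool@metabolites[match(newMets, universal_pool@metabolites$id), ])
  rxnTab <- rbind(model@reactions, universal_pool@reactions[jp, ])
  stoich <- c(
    lapply(seq_len(ncol(model@S)), function(j) { s <- model@S[, j]; s[s != 0] }),
    lapply(jp, function(j) { s <- universal_pool@S[, j]; s[s != 0] })
  )
  names(stoich) <- rxnTab$id
  MetabolicModel(metTab, rxnTab, stoich, biomass = model@biomassReactionId,
                 genes = union(model@genes, unlist(lapply(universal_pool@gprTrees[jp], gprGenes))),
                 compartments = union(model@compartments, universal_pool@compartments))
}
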