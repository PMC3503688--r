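## Flux balance analysis.
##
## FBA solves max (or min) c'v subject to S v = 0 and lb <= v <= ub, where v
## is the flux vector (mmol/gDCW/h; the biomass flux is the growth rate in
## 1/h). Only the optimal objective value is unique; reported flux vectors
## are one optimum among possibly many, so condition reports use a
## parsimonious representative (minimal total absolute flux at the fixed
## optimal objective).

#' Solve a flux balance analysis problem
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param medium optional \linkS4class{MediumSpec} applied before solving.
#' @param objective objective reaction id; defaults to the biomass reaction.
#' @param direction \code{"max"} or \code{"min"}.
#' @param fixedFluxes optional named numeric vector; each named reaction's
#'   flux is fixed to the given value (values must lie within the reaction's
#'   bounds after medium application).
#' @param pfba if TRUE and the solve is optimal, a second linear program
#'   minimizes total absolute flux at the fixed optimal objective and its
#'   flux vector is reported instead (the objective value is unchanged).
#' @return a \linkS4class{FluxSolution}; infeasible/unbounded statuses are
#'   returned, not raised.
#' @examples
#' m <- toyStipitisModel()
#' sol <- solveFBA(m, buildMedium(m, "xylose"))
#' objectiveValue(sol)
#' @export
solveFBA <- function(model, medium = NULL, objective = biomassReaction(model),
                     direction = c("max", "min"), fixedFluxes = NULL,
                     pfba = FALSE) {
  direction <- match.arg(direction)
  model <- applyMedium(model, medium)
  rxn <- model@reactions
  jobj <- match(objective, rxn$id)
  if (is.na(jobj)) stop("unknown objective reaction: ", objective)
  lb <- rxn$lower_bound
  ub <- rxn$upper_bound
  if (!is.null(fixedFluxes)) {
    jf <- match(names(fixedFluxes), rxn$id)
    if (anyNA(jf)) stop("unknown reaction in fixedFluxes: ",
                        paste(names(fixedFluxes)[is.na(jf)], collapse = ", "))
    out <- fixedFluxes < lb[jf] - 1e-9 | fixedFluxes > ub[jf] + 1e-9
    if (any(out)) stop("fixed flux outside reaction bounds for: ",
                       paste(names(fixedFluxes)[out], collapse = ", "))
    lb[jf] <- ub[jf] <- fixedFluxes
  }
  n <- ncol(model@S)
  obj <- numeric(n); obj[jobj] <- 1
  res <- simplexBounded(obj, model@S, rep(0, nrow(model@S)), lb, ub,
                        maximize = (direction == "max"))
  if (res$status != "optimal") {
    return(methods::new("FluxSolution", objectiveReactionId = objective,
                        objectiveValue = NA_real_, fluxes = numeric(0),
                        status = res$status))
  }
  v <- stats::setNames(res$x, rxn$id)
  if (pfba) {
    v2 <- parsimoniousFluxes(model@S, lb, ub, jobj, res$objective)
    if (!is.null(v2)) v <- stats::setNames(v2, rxn$id)
  }
  methods::new("FluxSolution", objectiveReactionId = objective,
               objectiveValue = res$objective, fluxes = v, status = "optimal")
}

## minimize sum |v| subject to S v = 0, bounds, v_obj = z*
## via t_j >= |v_j|:  v - t <= 0 and -v - t <= 0, minimize sum t
parsimoniousFluxes <- function(S, lb, ub, jobj, zstar) {
  m <- nrow(S); n <- ncol(S)
  lb[jobj] <- ub[jobj] <- zstar
  tmax <- pmax(abs(lb), abs(ub))
  A <- rbind(
    cbind(S, matrix(0, m, n)),
    cbind(diag(n), -diag(n)),
    cbind(-diag(n), -diag(n))
  )
  rhs <- c(rep(0, m), rep(0, 2 * n))
  sense <- c(rep("=", m), rep("<=", 2 * n))
  obj <- c(rep(0, n), rep(1, n))
  res <- solveLP(obj, A, rhs, sense, c(lb, rep(0, n)), c(ub, tmax),
                 maximize = FALSE)
  if (res$status != "optimal") return(NULL)
  res$x[seq_len(n)]
}

#' Flux variability over a set of reactions
#'
#' Minimum and maximum attainable flux of each reaction, optionally with the
#' objective fixed at a fraction of its optimum.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param medium optional \linkS4class{MediumSpec}.
#' @param reactionIds reactions to scan (default: all).
#' @return data.frame with columns \code{id}, \code{min}, \code{max} (NA where
#'   infeasible).
#' @export
fluxVariability <- function(model, medium = NULL, reactionIds = NULL) {
  model <- applyMedium(model, medium)
  rxn <- model@reactions
  if (is.null(reactionIds)) reactionIds <- rxn$id
  j <- match(reactionIds, rxn$id)
  if (anyNA(j)) stop("unknown reaction(s): ", paste(reactionIds[is.na(j)], collapse = ", "))
  n <- ncol(model@S)
  zero <- rep(0, nrow(model@S))
  one <- function(k, maximize) {
    obj <- numeric(n); obj[k] <- 1
    r <- simplexBounded(obj, model@S, zero, rxn$lower_bound, rxn$upper_bound,
                        maximize = maximize)
    if (r$status == "optimal") r$objective else NA_real_
  }
  data.frame(id = reactionIds,
             min = vapply(j, one, numeric(1), maximize = FALSE),
             max = vapply(j, one, numeric(1), maximize = TRUE),
             row.names = NULL)
}

#' Robustness scan of a controlled uptake
#'
#' Fixes the controlled exchange flux to \code{-rate} (consumption) at each
#' grid point, optionally fixes growth with an equality constraint, and
#' maximizes the objective. Infeasible points are reported as NA.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param medium a \linkS4class{MediumSpec} (e.g. xylose minimal medium).
#' @param controlledExchangeId exchange reaction being swept (id or token).
#' @param grid monotone vector of uptake rates, mmol/gDCW/h (positive =
#'   consumption).
#' @param objective objective reaction id (e.g. the ethanol exchange).
#' @param fixedGrowth optional growth rate (1/h) imposed as an equality on
#'   the biomass reaction at every grid point.
#' @return a \linkS4class{RobustnessCurve}.
#' @examples
#' m <- toyStipitisModel()
#' rc <- robustnessScan(m, buildMedium(m, "xylose"), "o2",
#'                      grid = seq(0, 10, by = 0.5),
#'                      objective = findExchange(m, "etoh"),
#'                      fixedGrowth = 0.01)
#' @export
robustnessScan <- function(model, medium, controlledExchangeId, grid,
                           objective, fixedGrowth = NULL) {
  stopifnot(length(grid) >= 1L)
  d <- diff(grid)
  if (length(d) && !(all(d > 0) || all(d < 0))) stop("grid must be strictly monotone")
  ctrl <- findExchange(model, controlledExchangeId)
  model <- applyMedium(model, medium)
  responses <- vapply(grid, function(rate) {
    fixed <- stats::setNames(-rate, ctrl)
    if (!is.null(fixedGrowth)) {
      fixed <- c(fixed, stats::setNames(fixedGrowth, biomassReaction(model)))
    }
    m2 <- setReactionBounds(model, names(fixed), fixed, fixed)
    sol <- solveFBA(m2, NULL, objective, "max")
    if (solutionStatus(sol) == "optimal") objectiveValue(sol) else NA_real_
  }, numeric(1))
  methods::new("RobustnessCurve", controlledReactionId = ctrl,
               grid = as.numeric(grid), responses = responses)
}

#' Per-condition flux report for selected reactions
#'
#' For each condition the growth rate is maximized, then fluxes are taken
#' from a parsimonious representative (total absolute flux minimized at the
#' fixed growth optimum); only objective values are unique, flux vectors are
#' representatives.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param conditions character vector of preset names (\code{"GA"},
#'   \code{"GSA"}, \code{"XA"}, \code{"XSA"}) or a list of
#'   \linkS4class{MediumSpec} objects.
#' @param reactionIds reactions to report.
#' @return data.frame, one row per reaction, one column per condition, plus a
#'   \code{growth} attribute row ("growth") giving the maximized growth rate.
#' @export
conditionFluxReport <- function(model, conditions = c("GA", "GSA", "XA", "XSA"),
                                reactionIds) {
  j <- match(reactionIds, model@reactions$id)
  if (anyNA(j)) stop("unknown reaction(s): ", paste(reactionIds[is.na(j)], collapse = ", "))
  media <- if (is.character(conditions)) {
    stats::setNames(lapply(conditions, mediumPreset, model = model),
                    make.unique(conditions))
  } else {
    stats::setNames(conditions,
                    make.unique(vapply(conditions, function(m) m@name, character(1))))
  }
  out <- data.frame(id = c(reactionIds, "growth"), stringsAsFactors = FALSE)
  for (nm in names(media)) {
    sol <- solveFBA(model, media[[nm]], pfba = TRUE)
    if (solutionStatus(sol) != "optimal") {
      out[[nm]] <- NA_real_
    } else {
      out[[nm]] <- c(unname(fluxes(sol)[reactionIds]), objectiveValue(sol))
    }
  }
  out
}
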