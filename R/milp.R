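## Branch-and-bound for small mixed binary linear programs.
##
## Depth-first search over binary variables, bounding each node with the
## bounded-variable simplex on the LP relaxation. Designed for the problem
## sizes this package produces (tens of binaries): OptKnock reformulations
## and minimal gap-filling.

#' @keywords internal
#' @noRd
solveMILP <- function(obj, A, rhs, sense, lb, ub, binaryIndex,
                      maximize = TRUE, tol = 1e-6, nodeLimit = 50000L) {
  best <- list(objective = if (maximize) -Inf else Inf, x = NULL)
  nodes <- 0L
  status <- "optimal"

  rec <- function(lb, ub) {
    nodes <<- nodes + 1L
    if (nodes > nodeLimit) { status <<- "node-limit"; return(invisible(NULL)) }
    rel <- solveLP(obj, A, rhs, sense, lb, ub, maximize = maximize)
    if (rel$status != "optimal") return(invisible(NULL))
    if (maximize && rel$objective <= best$objective + 1e-9) return(invisible(NULL))
    if (!maximize && rel$objective >= best$objective - 1e-9) return(invisible(NULL))
    xb <- rel$x[binaryIndex]
    frac <- abs(xb - round(xb))
    if (all(frac <= tol)) {
      best <<- list(objective = rel$objective, x = rel$x)
      return(invisible(NULL))
    }
    k <- binaryIndex[which.max(frac)]
    v <- rel$x[k]
    ## explore the nearer side first
    first0 <- v < 0.5
    for (side in if (first0) c(0, 1) else c(1, 0)) {
      lb2 <- lb; ub2 <- ub
      if (side == 0) ub2[k] <- 0 else lb2[k] <- 1
      rec(lb2, ub2)
    }
    invisible(NULL)
  }
  rec(lb, ub)
  if (is.null(best$x)) {
    return(list(status = if (status == "node-limit") status else "infeasible",
                objective = NA_real_, x = NULL))
  }
  list(status = status, objective = best$objective, x = best$x)
}
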