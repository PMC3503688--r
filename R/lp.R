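## Bounded-variable primal simplex.
##
## The whole package runs on this solver: FBA, flux variability, robustness
## scans and the LP relaxations inside the branch-and-bound MILP.  Problems
## are small and dense (tens to a few hundred rows), so the basis inverse is
## recomputed by LAPACK at every iteration; that costs O(m^3) per pivot but
## is numerically self-correcting, which matters more here than speed.

#' @keywords internal
#' @noRd
simplexBounded <- function(obj, A, b, lb, ub,
                           maximize = TRUE,
                           tol = 1e-9,
                           maxit = 50000L) {
  A <- as.matrix(A)
  m <- nrow(A)
  n <- ncol(A)
  stopifnot(length(obj) == n, length(lb) == n, length(ub) == n,
            length(b) == m, all(lb <= ub + tol))

  cc <- if (maximize) as.numeric(obj) else -as.numeric(obj)

  if (m == 0L) {
    x <- ifelse(cc > tol, ub, ifelse(cc < -tol, lb, ifelse(is.finite(lb), pmin(pmax(0, lb), ub), pmin(0, ub))))
    if (any(!is.finite(x) & abs(cc) > tol)) {
      return(list(status = "unbounded", objective = NA_real_, x = rep(NA_real_, n)))
    }
    x[!is.finite(x)] <- 0
    z <- sum(cc * x)
    return(list(status = "optimal", objective = if (maximize) z else -z, x = x))
  }

  ## columns: n structural + m artificial
  lo <- c(lb, rep(0, m))
  hi <- c(ub, rep(Inf, m))

  ## nonbasic start: finite bound nearest zero; free variables parked at 0
  stat <- character(n + m)
  xnb <- numeric(n + m)
  for (j in seq_len(n)) {
    if (is.finite(lo[j]) && (!is.finite(hi[j]) || abs(lo[j]) <= abs(hi[j]))) {
      stat[j] <- "lb"; xnb[j] <- lo[j]
    } else if (is.finite(hi[j])) {
      stat[j] <- "ub"; xnb[j] <- hi[j]
    } else {
      stat[j] <- "free"; xnb[j] <- 0
    }
  }

  r <- as.numeric(b - A %*% xnb[seq_len(n)])
  s <- ifelse(r >= 0, 1, -1)
  M <- cbind(A, diag(s, nrow = m))
  basis <- n + seq_len(m)
  stat[basis] <- "basic"

  runSimplex <- function(cvec, phase1, stat, xnb, basis, lo, hi) {
    it <- 0L
    degen <- 0L
    bland <- FALSE
    status <- "maxit"
    repeat {
      it <- it + 1L
      if (it > maxit) break
      B <- M[, basis, drop = FALSE]
      Binv <- tryCatch(solve(B), error = function(e) NULL)
      if (is.null(Binv)) {
        return(list(status = "numerical", stat = stat, xnb = xnb, basis = basis))
      }
      xall <- xnb
      xall[basis] <- 0
      xB <- as.numeric(Binv %*% (b - M %*% xall))
      y <- as.numeric(crossprod(Binv, cvec[basis]))
      d <- cvec - as.numeric(crossprod(M, y))
      nonbasic <- which(stat != "basic")
      elig <- nonbasic[(stat[nonbasic] == "lb" & d[nonbasic] > tol) |
                       (stat[nonbasic] == "ub" & d[nonbasic] < -tol) |
                       (stat[nonbasic] == "free" & abs(d[nonbasic]) > tol)]
      if (length(elig) == 0L) {
        status <- "optimal"
        xall[basis] <- xB
        return(list(status = status, stat = stat, xnb = xnb, basis = basis, x = xall))
      }
      q <- if (bland) min(elig) else elig[which.max(abs(d[elig]))]
      dir <- if (stat[q] == "ub" || (stat[q] == "free" && d[q] < 0)) -1 else 1

      w <- as.numeric(Binv %*% M[, q])
      ## ratio test over basic variables plus a bound flip of the entering one
      tlim <- rep(Inf, m)
      leaveTo <- character(m)
      dw <- dir * w
      up <- dw > tol
      dn <- dw < -tol
      if (any(up)) {
        tlim[up] <- (xB[up] - lo[basis[up]]) / dw[up]
        leaveTo[up] <- "lb"
      }
      if (any(dn)) {
        tlim[dn] <- (hi[basis[dn]] - xB[dn]) / (-dw[dn])
        leaveTo[dn] <- "ub"
      }
      tlim[tlim < 0] <- 0
      tflip <- hi[q] - lo[q]
      tmin <- min(tlim, tflip)
      if (!is.finite(tmin)) {
        return(list(status = "unbounded", stat = stat, xnb = xnb, basis = basis))
      }
      if (tmin <= tol) degen <- degen + 1L else degen <- 0L
      if (degen > 40L) bland <- TRUE

      if (tflip <= tmin + 1e-12 && is.finite(tflip) && tflip <= min(tlim)) {
        ## entering variable runs to its opposite bound; basis unchanged
        stat[q] <- if (dir > 0) "ub" else "lb"
        xnb[q] <- if (dir > 0) hi[q] else lo[q]
      } else {
        cand <- which(tlim <= tmin + 1e-12)
        rpos <- if (bland) cand[which.min(basis[cand])] else cand[which.max(abs(dw[cand]))]
        leaving <- basis[rpos]
        stat[leaving] <- leaveTo[rpos]
        xnb[leaving] <- if (leaveTo[rpos] == "lb") lo[leaving] else hi[leaving]
        newval <- switch(stat[q], lb = lo[q], ub = hi[q], free = 0) + dir * tmin
        basis[rpos] <- q
        stat[q] <- "basic"
        xnb[q] <- newval   # seed; exact value recomputed from Binv next iteration
      }
    }
    list(status = status, stat = stat, xnb = xnb, basis = basis)
  }

  ## Phase 1: drive artificials to zero
  c1 <- c(rep(0, n), rep(-1, m))
  p1 <- runSimplex(c1, TRUE, stat, xnb, basis, lo, hi)
  if (p1$status != "optimal") {
    return(list(status = if (p1$status == "unbounded") "numerical" else p1$status,
                objective = NA_real_, x = rep(NA_real_, n)))
  }
  art <- p1$x[n + seq_len(m)]
  if (sum(art) > 1e-7) {
    return(list(status = "infeasible", objective = NA_real_, x = rep(NA_real_, n)))
  }
  ## Phase 2: pin artificials at zero and optimize the true objective
  hi[n + seq_len(m)] <- 0
  xnb2 <- p1$xnb
  xnb2[n + seq_len(m)][p1$stat[n + seq_len(m)] != "basic"] <- 0
  c2 <- c(cc, rep(0, m))
  p2 <- runSimplex(c2, FALSE, p1$stat, xnb2, p1$basis, lo, hi)
  if (p2$status != "optimal") {
    return(list(status = p2$status, objective = NA_real_, x = rep(NA_real_, n)))
  }
  x <- p2$x[seq_len(n)]
  z <- sum(cc * x)
  list(status = "optimal", objective = if (maximize) z else -z, x = x)
}

#' Solve a general small dense linear program
#'
#' Maximizes or minimizes \code{obj' x} subject to row constraints
#' \code{A x (sense) rhs} and variable bounds \code{lb <= x <= ub}.
#' Inequality rows are converted to equalities with slack variables and the
#' problem is handed to the bounded-variable simplex.
#'
#' @keywords internal
#' @noRd
solveLP <- function(obj, A, rhs, sense = rep("=", length(rhs)),
                    lb, ub, maximize = TRUE, tol = 1e-9, maxit = 50000L) {
  A <- as.matrix(A)
  m <- nrow(A)
  n <- ncol(A)
  stopifnot(length(sense) == m)
  ineq <- which(sense != "=")
  if (length(ineq)) {
    Sl <- matrix(0, m, length(ineq))
    for (k in seq_along(ineq)) {
      Sl[ineq[k], k] <- if (sense[ineq[k]] == "<=") 1 else -1
    }
    A <- cbind(A, Sl)
    lb <- c(lb, rep(0, length(ineq)))
    ub <- c(ub, rep(Inf, length(ineq)))
    obj <- c(obj, rep(0, length(ineq)))
  }
  res <- simplexBounded(obj, A, rhs, lb, ub, maximize = maximize,
                        tol = tol, maxit = maxit)
  res$x <- res$x[seq_len(n)]
  res
}
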