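# Independent dense reference LP solver used as an oracle for the package's
# bounded-variable simplex.  Deliberately a different formulation and code
# path: variables are shifted/split to be nonnegative, finite upper bounds
# become explicit rows, equality rows get Big-M artificial variables, and the
# whole thing is solved by a plain full-tableau simplex with Bland's rule.
# Shares no code with the package.

referenceLP <- function(obj, A, rhs, sense = rep("=", length(rhs)),
                        lb, ub, maximize = TRUE, tol = 1e-8) {
  A <- as.matrix(A)
  n <- ncol(A)
  stopifnot(length(lb) == n, length(ub) == n)
  cmin <- if (maximize) -as.numeric(obj) else as.numeric(obj)

  # map x_j -> nonnegative columns
  cols <- list()   # each: list(orig, sign, shift)
  for (j in seq_len(n)) {
    if (is.finite(lb[j])) {
      cols[[length(cols) + 1L]] <- list(orig = j, sign = 1, shift = lb[j])
    } else if (is.finite(ub[j])) {
      cols[[length(cols) + 1L]] <- list(orig = j, sign = -1, shift = ub[j])
    } else {
      cols[[length(cols) + 1L]] <- list(orig = j, sign = 1, shift = 0)
      cols[[length(cols) + 1L]] <- list(orig = j, sign = -1, shift = 0)
    }
  }
  nz <- length(cols)
  Az <- matrix(0, nrow(A), nz)
  cz <- numeric(nz)
  shift <- numeric(n)
  for (k in seq_len(nz)) {
    cl <- cols[[k]]
    Az[, k] <- cl$sign * A[, cl$orig]
    cz[k] <- cl$sign * cmin[cl$orig]
    if (cl$shift != 0 && cl$sign == 1) shift[cl$orig] <- cl$shift
    if (cl$shift != 0 && cl$sign == -1) shift[cl$orig] <- cl$shift
  }
  rhs2 <- rhs - as.numeric(A %*% shift)
  rows <- list(A = Az, b = rhs2, sense = sense)

  # finite ranges become extra <= rows (z_j <= ub - lb, or symmetric case)
  for (k in seq_len(nz)) {
    cl <- cols[[k]]
    if (is.finite(lb[cl$orig]) && is.finite(ub[cl$orig])) {
      e <- numeric(nz); e[k] <- 1
      rows$A <- rbind(rows$A, e)
      rows$b <- c(rows$b, ub[cl$orig] - lb[cl$orig])
      rows$sense <- c(rows$sense, "<=")
    }
  }

  Afull <- rows$A; bfull <- rows$b; sfull <- rows$sense
  # normalize negative rhs
  neg <- bfull < 0
  Afull[neg, ] <- -Afull[neg, , drop = FALSE]
  bfull[neg] <- -bfull[neg]
  sfull[neg] <- ifelse(sfull[neg] == "<=", ">=", ifelse(sfull[neg] == ">=", "<=", "="))

  m <- nrow(Afull)
  bigM <- 1e7
  Tcols <- Afull
  cost <- cz
  basis <- integer(m)
  # slacks / surplus / artificials
  for (i in seq_len(m)) {
    if (sfull[i] == "<=") {
      e <- numeric(m); e[i] <- 1
      Tcols <- cbind(Tcols, e); cost <- c(cost, 0)
      basis[i] <- ncol(Tcols)
    } else if (sfull[i] == ">=") {
      e <- numeric(m); e[i] <- -1
      Tcols <- cbind(Tcols, e); cost <- c(cost, 0)
      a <- numeric(m); a[i] <- 1
      Tcols <- cbind(Tcols, a); cost <- c(cost, bigM)
      basis[i] <- ncol(Tcols)
    } else {
      a <- numeric(m); a[i] <- 1
      Tcols <- cbind(Tcols, a); cost <- c(cost, bigM)
      basis[i] <- ncol(Tcols)
    }
  }
  artset <- which(cost == bigM)

  Tab <- cbind(Tcols, bfull)
  nv <- ncol(Tcols)
  it <- 0
  repeat {
    it <- it + 1
    if (it > 100000) return(list(status = "maxit", objective = NA_real_))
    cb <- cost[basis]
    red <- cost - as.numeric(cb %*% Tab[, seq_len(nv), drop = FALSE])
    enter <- which(red < -tol)
    if (!length(enter)) break
    q <- min(enter)                       # Bland
    colq <- Tab[, q]
    pos <- which(colq > tol)
    if (!length(pos)) return(list(status = "unbounded", objective = NA_real_))
    ratio <- Tab[pos, nv + 1] / colq[pos]
    rmin <- min(ratio)
    cand <- pos[ratio <= rmin + 1e-12]
    r <- cand[which.min(basis[cand])]     # Bland tie-break
    piv <- Tab[r, q]
    Tab[r, ] <- Tab[r, ] / piv
    for (i in seq_len(m)) {
      if (i != r && abs(Tab[i, q]) > 0) Tab[i, ] <- Tab[i, ] - Tab[i, q] * Tab[r, ]
    }
    basis[r] <- q
  }
  xfull <- numeric(nv)
  xfull[basis] <- Tab[, nv + 1]
  if (any(xfull[artset] > 1e-5)) return(list(status = "infeasible", objective = NA_real_))
  zmin <- sum(cz * xfull[seq_len(nz)])
  x <- shift
  for (k in seq_len(nz)) {
    cl <- cols[[k]]
    x[cl$orig] <- x[cl$orig] + cl$sign * xfull[k]
  }
  zmin <- sum(cmin * x)
  list(status = "optimal",
       objective = if (maximize) -zmin else zmin,
       x = x)
}

# FBA via the reference solver, straight from the raw matrices.
referenceFBAObjective <- function(S, lb, ub, objIndex, maximize = TRUE) {
  obj <- numeric(ncol(S)); obj[objIndex] <- 1
  referenceLP(obj, S, rep(0, nrow(S)), rep("=", nrow(S)), lb, ub, maximize = maximize)
}
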