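## OptKnock-style bilevel strain design.
##
## Outer problem: choose at most K gene knockouts (binary y_g, 1 = gene
## present) maximizing secretion of a target product. Inner problem: the
## cell maximizes growth given the knockouts. The bilevel program is
## collapsed to a single-level MILP by LP strong duality on the inner
## problem: primal feasibility, dual feasibility and the equality of primal
## and dual objectives certify inner optimality. Bound constraints whose
## right-hand sides switch with a knockout (v_j <= ub_j z_j) produce
## bilinear dual terms z_j * alpha_j, linearized with big-M products.
## Knockouts act on genes; reactions are disabled through their GPRs, which
## are linearized per candidate set with prime-implicant ("keeping these
## genes keeps the reaction") and prime-implicate ("knocking these genes
## kills it") cuts - exact for monotone AND/OR trees.
##
## The reported production rate is the inner-growth-optimal production,
## operationalized as lexicographic FBA: maximize growth, then maximize
## (optimistic, the default, matching the MILP) or minimize (pessimistic)
## production at the fixed growth optimum.

## percent change vs a reference; exactly 0 where equal, NA only when the
## reference is zero and the value is not
relChangePct <- function(p, ref) {
  ifelse(abs(p - ref) <= 1e-12, 0,
         if (ref > 0) 100 * (p - ref) / ref else NA_real_)
}

#' Growth and production of a knockout strain (lexicographic FBA)
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param medium a \linkS4class{MediumSpec}.
#' @param target target exchange reaction id.
#' @param knockedGenes genes to delete.
#' @param pessimistic if TRUE, production is minimized at the growth optimum
#'   instead of maximized.
#' @return list with \code{growth}, \code{production}, \code{feasible}.
#' @export
productionEnvelopePoint <- function(model, medium, target,
                                    knockedGenes = character(0),
                                    pessimistic = FALSE) {
  model <- applyMedium(model, medium)
  model <- knockoutGenes(model, knockedGenes)
  g <- solveFBA(model)
  if (solutionStatus(g) != "optimal") {
    return(list(growth = 0, production = 0, feasible = FALSE))
  }
  mu <- objectiveValue(g)
  p <- solveFBA(model, objective = target,
                direction = if (pessimistic) "min" else "max",
                fixedFluxes = stats::setNames(mu, biomassReaction(model)))
  prod <- if (solutionStatus(p) == "optimal") objectiveValue(p) else 0
  list(growth = mu, production = prod, feasible = TRUE)
}

#' Exhaustive knockout enumeration (oracle for optKnock)
#'
#' Evaluates every gene subset of size at most \code{k} by lexicographic FBA.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param medium a \linkS4class{MediumSpec}.
#' @param target target exchange reaction id.
#' @param genes candidate gene set.
#' @param k maximal knockout-set size (<= 2 recommended; combinatorial).
#' @param pessimistic see \code{\link{productionEnvelopePoint}}.
#' @return data.frame ranked by production: \code{knocked_genes} (comma
#'   separated, "" = wild type), \code{n_knockouts}, \code{growth_rate},
#'   \code{production_rate}, \code{relative_change_pct}, \code{feasible}.
#' @export
enumerateKnockouts <- function(model, medium, target, genes, k = 1,
                               pessimistic = FALSE) {
  stopifnot(k >= 0)
  unknown <- setdiff(genes, model@genes)
  if (length(unknown)) stop("unknown candidate gene(s): ", paste(unknown, collapse = ", "))
  subsets <- list(character(0))
  if (k >= 1) for (kk in seq_len(min(k, length(genes)))) {
    subsets <- c(subsets, utils::combn(sort(genes), kk, simplify = FALSE))
  }
  rows <- lapply(subsets, function(ko) {
    pt <- productionEnvelopePoint(model, medium, target, ko, pessimistic)
    data.frame(knocked_genes = paste(ko, collapse = ","),
               n_knockouts = length(ko),
               growth_rate = pt$growth, production_rate = pt$production,
               feasible = pt$feasible, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  wt <- out$production_rate[out$knocked_genes == ""]
  out$relative_change_pct <- relChangePct(out$production_rate, wt)
  out <- out[order(-out$production_rate, out$n_knockouts, out$knocked_genes), ]
  rownames(out) <- NULL
  out[, c("knocked_genes", "n_knockouts", "growth_rate", "production_rate",
          "relative_change_pct", "feasible")]
}

## prime implicants (minimal present-sets keeping the reaction) and prime
## implicates (minimal knocked-sets killing it) of a monotone GPR restricted
## to the candidate genes, with all non-candidate genes present
gprPrimeSets <- function(tree, candidates) {
  cand <- intersect(gprGenes(tree), candidates)
  k <- length(cand)
  if (k == 0L) return(NULL)
  if (k > 16L) stop("GPR touches more than 16 candidate genes; restrict the candidate set")
  evalPresent <- function(present) {
    states <- stats::setNames(cand %in% present, cand)
    gprEval(tree, states)
  }
  allSubsets <- unlist(lapply(0:k, function(s) utils::combn(cand, s, simplify = FALSE)),
                       recursive = FALSE)
  truth <- vapply(allSubsets, evalPresent, logical(1))
  if (all(truth)) return(NULL)  # cannot be disabled by these candidates
  minimalOf <- function(sets) {
    keep <- rep(TRUE, length(sets))
    for (i in seq_along(sets)) for (jj in seq_along(sets)) {
      if (i != jj && keep[i] && all(sets[[jj]] %in% sets[[i]]) &&
          length(sets[[jj]]) < length(sets[[i]])) keep[i] <- FALSE
    }
    sets[keep]
  }
  implicants <- minimalOf(allSubsets[truth])                     # present-sets
  knockedSets <- lapply(allSubsets, function(s) setdiff(cand, s))
  implicates <- minimalOf(knockedSets[!truth])                   # knocked-sets
  list(genes = cand, implicants = implicants, implicates = implicates)
}

#' OptKnock: bilevel strain design as a strong-duality MILP
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param medium a \linkS4class{MediumSpec}.
#' @param target target exchange reaction id (e.g. the ethanol exchange).
#' @param max_knockouts knockout budget K (>= 0).
#' @param candidate_genes candidate gene set; must exclude genes essential on
#'   the medium (checked).
#' @param min_growth_fraction mutant growth must stay above this fraction of
#'   wild-type growth (default 0.1).
#' @param n_designs number of top designs to return; after each solve the
#'   found knockout set is excluded with a no-good cut and the MILP re-solved.
#' @param dual_bound big-M bound on the inner dual variables, set from the
#'   model's bound magnitude (1000) divided by a typical objective scale with
#'   a safety factor; inner optimality of every reported design is
#'   re-certified by a direct FBA solve (duality gap <= 1e-6), so an
#'   undersized bound is detected, not silently wrong.
#' @param pessimistic report the pessimistic (minimal) production at the
#'   growth optimum for the found designs; the search itself is optimistic.
#' @return data.frame like \code{\link{enumerateKnockouts}}, ranked by
#'   production, wild type included as reference; attribute
#'   \code{"diagnostic"} carries solver notes when no design was found.
#' @examples
#' net <- generateNetwork(syntheticSpec(n_pathways = 1, n_coupled = 1, seed = 3))
#' wt <- solveFBA(net$model)
#' optKnock(net$model, NULL, net$target_exchange, 1,
#'          net$nonessential_genes, min_growth_fraction = 0.05)
#' @export
optKnock <- function(model, medium, target, max_knockouts, candidate_genes,
                     min_growth_fraction = 0.1, n_designs = 1,
                     dual_bound = 100, pessimistic = FALSE) {
  stopifnot(max_knockouts >= 0, min_growth_fraction >= 0)
  unknown <- setdiff(candidate_genes, model@genes)
  if (length(unknown)) stop("unknown candidate gene(s): ", paste(unknown, collapse = ", "))
  model <- applyMedium(model, medium)
  rxn <- model@reactions
  jt <- match(target, rxn$id)
  if (is.na(jt)) stop("unknown target reaction: ", target)
  jb <- match(biomassReaction(model), rxn$id)

  wt <- solveFBA(model)
  if (solutionStatus(wt) != "optimal" || objectiveValue(wt) <= 0) {
    stop("wild type does not grow on this medium")
  }
  wtPt <- productionEnvelopePoint(model, NULL, target, character(0), pessimistic)
  minGrowth <- min_growth_fraction * objectiveValue(wt)

  G <- sort(unique(candidate_genes))
  ess <- vapply(G, function(g) {
    dis <- disabledReactions(model, g)
    if (!length(dis)) return(FALSE)
    s <- solveFBA(setReactionBounds(model, dis, 0, 0))
    solutionStatus(s) != "optimal" || objectiveValue(s) < 1e-6 * objectiveValue(wt)
  }, logical(1))
  if (any(ess)) {
    stop("candidate set contains essential gene(s): ", paste(G[ess], collapse = ", "))
  }

  prime <- list()
  for (j in seq_len(nrow(rxn))) {
    ps <- gprPrimeSets(model@gprTrees[[j]], G)
    if (!is.null(ps)) prime[[rxn$id[j]]] <- ps
  }
  aff <- match(names(prime), rxn$id)
  nA <- length(aff)
  n <- nrow(rxn); m <- nrow(model@S); ng <- length(G)

  ## column layout: v(n) | lambda(m) | y(ng) | z(nA) | alpha(n) | beta(n) | pa(nA) | pb(nA)
  iv <- seq_len(n)
  il <- n + seq_len(m)
  iy <- n + m + seq_len(ng)
  iz <- n + m + ng + seq_len(nA)
  ia <- n + m + ng + nA + seq_len(n)
  ib <- n + m + ng + nA + n + seq_len(n)
  ipa <- n + m + ng + nA + 2 * n + seq_len(nA)
  ipb <- n + m + ng + nA + 2 * n + nA + seq_len(nA)
  ncol <- n + m + ng + nA + 2 * n + 2 * nA

  lbv <- rxn$lower_bound; ubv <- rxn$upper_bound
  lo <- c(pmin(lbv, 0) * (seq_len(n) %in% aff) + lbv * !(seq_len(n) %in% aff),
          rep(-dual_bound, m), rep(0, ng), rep(0, nA),
          rep(0, n), rep(0, n), rep(0, nA), rep(0, nA))
  hi <- c(pmax(ubv, 0) * (seq_len(n) %in% aff) + ubv * !(seq_len(n) %in% aff),
          rep(dual_bound, m), rep(1, ng), rep(1, nA),
          rep(dual_bound, n), rep(dual_bound, n),
          rep(dual_bound, nA), rep(dual_bound, nA))

  rows <- list(); rhs <- numeric(0); sense <- character(0)
  addRow <- function(idx, coefs, s, b) {
    r <- numeric(ncol); r[idx] <- coefs
    rows[[length(rows) + 1L]] <<- r
    rhs <<- c(rhs, b); sense <<- c(sense, s)
  }
  ## (a) steady state
  for (i in seq_len(m)) addRow(iv, model@S[i, ], "=", 0)
  ## (b,c) bound rows (dual multipliers alpha, beta)
  zOf <- stats::setNames(seq_len(nA), names(prime))
  for (j in seq_len(n)) {
    if (j %in% aff) {
      zj <- iz[zOf[[rxn$id[j]]]]
      addRow(c(iv[j], zj), c(1, -ubv[j]), "<=", 0)
      addRow(c(iv[j], zj), c(-1, lbv[j]), "<=", 0)
    } else {
      addRow(iv[j], 1, "<=", ubv[j])
      addRow(iv[j], -1, "<=", -lbv[j])
    }
  }
  ## (d) dual feasibility: S'lambda + alpha - beta = c (c = e_biomass)
  for (j in seq_len(n)) {
    addRow(c(il, ia[j], ib[j]), c(model@S[, j], 1, -1), "=", as.numeric(j == jb))
  }
  ## (e) strong duality: v_b = sum(ub_j * [alpha_j | pa_j]) - sum(lb_j * [beta_j | pb_j])
  idxE <- c(iv[jb]); coefE <- c(1)
  for (j in seq_len(n)) {
    if (j %in% aff) {
      kk <- zOf[[rxn$id[j]]]
      idxE <- c(idxE, ipa[kk], ipb[kk]); coefE <- c(coefE, -ubv[j], lbv[j])
    } else {
      idxE <- c(idxE, ia[j], ib[j]); coefE <- c(coefE, -ubv[j], lbv[j])
    }
  }
  addRow(idxE, coefE, "=", 0)
  ## (f) big-M linearization pa_j = z_j alpha_j, pb_j = z_j beta_j
  for (kk in seq_len(nA)) {
    j <- aff[kk]
    addRow(c(ipa[kk], ia[j]), c(1, -1), "<=", 0)
    addRow(c(ipa[kk], iz[kk]), c(1, -dual_bound), "<=", 0)
    addRow(c(ipa[kk], ia[j], iz[kk]), c(-1, 1, dual_bound), "<=", dual_bound)
    addRow(c(ipb[kk], ib[j]), c(1, -1), "<=", 0)
    addRow(c(ipb[kk], iz[kk]), c(1, -dual_bound), "<=", 0)
    addRow(c(ipb[kk], ib[j], iz[kk]), c(-1, 1, dual_bound), "<=", dual_bound)
  }
  ## (g) GPR linearization cuts
  for (kk in seq_len(nA)) {
    ps <- prime[[kk]]
    for (C in ps$implicates) {
      addRow(c(iz[kk], iy[match(C, G)]), c(1, rep(-1, length(C))), "<=", 0)
    }
    for (I in ps$implicants) {
      addRow(c(iz[kk], iy[match(I, G)]), c(-1, rep(1, length(I))), "<=", length(I) - 1)
    }
  }
  ## (h) knockout budget, (i) minimal growth
  addRow(iy, rep(-1, ng), "<=", max_knockouts - ng)
  addRow(iv[jb], -1, "<=", -minGrowth)

  A <- do.call(rbind, rows)
  obj <- numeric(ncol); obj[iv[jt]] <- 1

  designs <- list()
  diag <- character(0)
  for (d in seq_len(max(1, n_designs))) {
    sol <- solveMILP(obj, A, rhs, sense, lo, hi, binaryIndex = iy, maximize = TRUE)
    if (sol$status != "optimal" || is.null(sol$x)) {
      diag <- c(diag, paste0("MILP ", sol$status, " at design ", d))
      break
    }
    knocked <- G[sol$x[iy] < 0.5]
    pt <- productionEnvelopePoint(model, NULL, target, knocked, pessimistic)
    gap <- abs(pt$growth - sol$x[iv[jb]])
    if (gap > 1e-6) {
      diag <- c(diag, paste0("duality-gap ", format(gap), " for {",
                             paste(knocked, collapse = ","), "}; dual_bound too small?"))
    }
    designs[[d]] <- data.frame(
      knocked_genes = paste(knocked, collapse = ","),
      n_knockouts = length(knocked),
      growth_rate = pt$growth, production_rate = pt$production,
      feasible = pt$feasible, stringsAsFactors = FALSE)
    if (d == n_designs) break
    ## no-good cut excluding exactly this knockout set
    kn <- match(knocked, G); kp <- setdiff(seq_len(ng), kn)
    r <- numeric(ncol)
    r[iy[kn]] <- -1; r[iy[kp]] <- 1
    A <- rbind(A, r)    # sum(y_kn) - sum(y_kp) >= 1 - |kp|  <=>  -sum(y_kn)+sum(y_kp) <= |kp|-1
    rhs <- c(rhs, length(kp) - 1)
    sense <- c(sense, "<=")
  }
  if (!length(designs)) {
    out <- data.frame(knocked_genes = character(0), n_knockouts = integer(0),
                      growth_rate = numeric(0), production_rate = numeric(0),
                      relative_change_pct = numeric(0), feasible = logical(0))
    attr(out, "diagnostic") <- diag
    return(out)
  }
  out <- do.call(rbind, designs)
  if (!any(out$knocked_genes == "")) {
    out <- rbind(out, data.frame(knocked_genes = "", n_knockouts = 0L,
                                 growth_rate = wtPt$growth,
                                 production_rate = wtPt$production,
                                 feasible = TRUE, stringsAsFactors = FALSE))
  }
  out$relative_change_pct <- relChangePct(out$production_rate, wtPt$production)
  out <- out[order(-out$production_rate, out$n_knockouts, out$knocked_genes), ]
  rownames(out) <- NULL
  attr(out, "diagnostic") <- diag
  out[, c("knocked_genes", "n_knockouts", "growth_rate", "production_rate",
          "relative_change_pct", "feasible")]
}

#' Amino-acid supplementation scan
#'
#' For each amino-acid exchange, adds uptake at \code{uptake} mmol/gDCW/h to
#' the base medium (optionally together with a gene knockout) and reports the
#' growth-optimal production of the target, evaluated lexicographically as in
#' \code{\link{enumerateKnockouts}}. The control row is the base medium with
#' no addition and no knockout.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param base_medium a \linkS4class{MediumSpec}.
#' @param target target exchange reaction id.
#' @param amino_acid_exchanges exchange ids (or tokens) of the amino acids;
#'   each must exist in the model.
#' @param knockout optional gene set deleted in every supplemented row.
#' @param uptake amino-acid uptake cap (default 0.1 mmol/gDCW/h).
#' @return data.frame with rows \code{control} then one per amino acid:
#'   \code{amino_acid}, \code{growth_rate}, \code{production_rate},
#'   \code{change_vs_control_pct}.
#' @export
aminoAcidScan <- function(model, base_medium, target, amino_acid_exchanges,
                          knockout = NULL, uptake = 0.1) {
  ids <- vapply(amino_acid_exchanges, function(a) findExchange(model, a), character(1))
  ctrl <- productionEnvelopePoint(model, base_medium, target)
  rows <- list(data.frame(amino_acid = "control", growth_rate = ctrl$growth,
                          production_rate = ctrl$production, stringsAsFactors = FALSE))
  for (k in seq_along(ids)) {
    b <- base_medium@bounds
    b[ids[k], "lower"] <- -uptake
    med <- methods::new("MediumSpec",
                        name = paste0(base_medium@name, "+", amino_acid_exchanges[k]),
                        bounds = b)
    pt <- productionEnvelopePoint(model, med, target,
                                  knockedGenes = if (is.null(knockout)) character(0) else knockout)
    rows[[k + 1L]] <- data.frame(amino_acid = amino_acid_exchanges[k],
                                 growth_rate = pt$growth,
                                 production_rate = pt$production,
                                 stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$change_vs_control_pct <- relChangePct(out$production_rate, ctrl$production)
  out
}
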