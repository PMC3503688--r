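## Synthetic stoichiometrically consistent networks with planted ground
## truth, used throughout the test suite. Each network is a set of linear
## uptake -> conversion -> precursor pathways feeding one biomass reaction
## (which consumes every precursor with unit coefficient), plus optional
## isoenzyme pairs, enzyme complexes, planted dead-end metabolites, and
## growth-coupled production modules. Because each pathway has unit yields
## and a single bottleneck (the substrate uptake bound), the maximal growth
## is known analytically: the minimum uptake bound across pathways.

#' Specification for a synthetic network
#'
#' @param n_pathways number of independent linear pathways (>= 1).
#' @param length_range integer range (min, max) of interior conversion steps
#'   per pathway.
#' @param n_isoenzyme_pairs interior reactions whose GPR becomes an OR pair
#'   of fresh genes (both nonessential).
#' @param n_complexes interior reactions whose GPR becomes an AND pair of
#'   fresh genes (both essential).
#' @param n_deadends planted metabolites with a producing but no consuming
#'   reaction.
#' @param n_coupled growth-coupled production modules: a substrate is split
#'   into a biomass precursor and a redox byproduct which must leave either
#'   through a gene-guarded waste route or through a product-forming route;
#'   knocking the waste gene couples product secretion to growth.
#' @param seed RNG seed; generation is reproducible from it.
#' @return a list to pass to \code{\link{generateNetwork}}.
#' @export
syntheticSpec <- function(n_pathways = 3, length_range = c(2, 4),
                          n_isoenzyme_pairs = 1, n_complexes = 1,
                          n_deadends = 1, n_coupled = 0, seed = 1) {
  stopifnot(n_pathways >= 1, all(length_range >= 1),
            n_isoenzyme_pairs >= 0, n_complexes >= 0,
            n_deadends >= 0, n_coupled >= 0)
  list(n_pathways = n_pathways, length_range = as.integer(length_range),
       n_isoenzyme_pairs = n_isoenzyme_pairs, n_complexes = n_complexes,
       n_deadends = n_deadends, n_coupled = n_coupled, seed = seed)
}

#' Generate a synthetic network with planted ground truth
#'
#' @param spec a list from \code{\link{syntheticSpec}}.
#' @return list with elements \code{model} (a \linkS4class{MetabolicModel}
#'   whose exchange bounds already define a growth-supporting medium),
#'   \code{essential_genes}, \code{nonessential_genes},
#'   \code{deadend_metabolites} (the planted no-consumption set),
#'   \code{max_growth} (analytic), and \code{target_exchange} /
#'   \code{coupled_waste_genes} when coupled modules were requested.
#' @examples
#' net <- generateNetwork(syntheticSpec(n_pathways = 2, seed = 7))
#' objectiveValue(solveFBA(net$model))  # equals net$max_growth
#' @export
generateNetwork <- function(spec) {
  set.seed(spec$seed)
  mets <- character(0)
  rxn <- list()
  addRxn <- function(id, stoich, lb = 0, ub = 1000, gpr = "", subsystem = "pathway") {
    rxn[[id]] <<- list(id = id, stoich = stoich, lb = lb, ub = ub,
                       gpr = gpr, subsystem = subsystem)
    mets <<- union(mets, names(stoich))
  }
  essential <- character(0)
  nonessential <- character(0)
  interior <- character(0)   # reaction ids eligible for iso/complex rewrites
  precursors <- character(0)

  gIdx <- 0L
  newGene <- function() { gIdx <<- gIdx + 1L; sprintf("g%03d", gIdx) }

  uptake <- sample(3:10, spec$n_pathways, replace = TRUE)
  lengthChoices <- seq(spec$length_range[1], spec$length_range[2])
  for (p in seq_len(spec$n_pathways)) {
    L <- if (length(lengthChoices) == 1L) lengthChoices else sample(lengthChoices, 1)
    sub_e <- sprintf("sub%d[e]", p)
    prev <- sprintf("sub%d[c]", p)
    addRxn(sprintf("EX_sub%d", p), stats::setNames(-1, sub_e),
           lb = -uptake[p], ub = 1000, subsystem = "exchange")
    addRxn(sprintf("T_sub%d", p), stats::setNames(c(-1, 1), c(sub_e, prev)),
           subsystem = "transport")
    for (i in seq_len(L)) {
      nxt <- if (i == L) sprintf("prec%d[c]", p) else sprintf("p%d_m%d[c]", p, i)
      g <- newGene()
      rid <- sprintf("R_p%d_s%d", p, i)
      addRxn(rid, stats::setNames(c(-1, 1), c(prev, nxt)), gpr = g)
      essential <- c(essential, g)
      interior <- c(interior, rid)
      prev <- nxt
    }
    precursors <- c(precursors, prev)
  }

  target_exchange <- character(0)
  coupled_waste_genes <- character(0)
  if (spec$n_coupled > 0) {
    for (q in seq_len(spec$n_coupled)) {
      ux <- 10
      se <- sprintf("csub%d[e]", q)
      sc <- sprintf("csub%d[c]", q)
      ax <- sprintf("cprec%d[c]", q)
      xx <- sprintf("cred%d[c]", q)
      we <- sprintf("cwaste%d[e]", q)
      pe <- sprintf("cprod%d[e]", q)
      gSplit <- newGene(); gWaste <- newGene(); gProd <- newGene()
      addRxn(sprintf("EX_csub%d", q), stats::setNames(-1, se), lb = -ux,
             subsystem = "exchange")
      addRxn(sprintf("T_csub%d", q), stats::setNames(c(-1, 1), c(se, sc)),
             subsystem = "transport")
      addRxn(sprintf("C_split%d", q),
             stats::setNames(c(-1, 1, 0.5), c(sc, ax, xx)), gpr = gSplit)
      addRxn(sprintf("C_waste%d", q), stats::setNames(c(-1, 1), c(xx, we)),
             gpr = gWaste, subsystem = "transport")
      addRxn(sprintf("EX_cwaste%d", q), stats::setNames(-1, we),
             subsystem = "exchange")
      addRxn(sprintf("C_prod%d", q),
             stats::setNames(c(-1, -1, 1), c(ax, xx, pe)), gpr = gProd,
             subsystem = "transport")
      addRxn(sprintf("EX_cprod%d", q), stats::setNames(-1, pe),
             subsystem = "exchange")
      essential <- c(essential, gSplit)           # sole source of the precursor
      nonessential <- c(nonessential, gWaste, gProd)
      precursors <- c(precursors, ax)
      uptake <- c(uptake, ux)
      target_exchange <- c(target_exchange, sprintf("EX_cprod%d", q))
      coupled_waste_genes <- c(coupled_waste_genes, gWaste)
    }
  }

  # biomass drains every precursor with unit coefficients
  addRxn("BIOMASS", stats::setNames(rep(-1, length(precursors)), precursors),
         subsystem = "biomass")

  # isoenzyme pairs and complexes rewrite interior pathway reactions
  stopifnot(spec$n_isoenzyme_pairs + spec$n_complexes <= length(interior))
  pick <- sample(interior, spec$n_isoenzyme_pairs + spec$n_complexes)
  iso <- pick[seq_len(spec$n_isoenzyme_pairs)]
  cpx <- setdiff(pick, iso)
  for (rid in iso) {
    old <- rxn[[rid]]$gpr
    g2 <- newGene()
    rxn[[rid]]$gpr <- paste(old, "or", g2)
    essential <- setdiff(essential, old)
    nonessential <- c(nonessential, old, g2)
  }
  for (rid in cpx) {
    old <- rxn[[rid]]$gpr
    g2 <- newGene()
    rxn[[rid]]$gpr <- paste(old, "and", g2)
    essential <- c(essential, g2)
  }

  deadends <- character(0)
  if (spec$n_deadends > 0) {
    donors <- sample(setdiff(mets, grep("\\[e\\]$", mets, value = TRUE)),
                     spec$n_deadends, replace = TRUE)
    for (d in seq_len(spec$n_deadends)) {
      dm <- sprintf("dead%d[c]", d)
      g <- newGene()
      addRxn(sprintf("D_dead%d", d), stats::setNames(c(-1, 1), c(donors[d], dm)),
             gpr = g, subsystem = "deadend")
      deadends <- c(deadends, dm)
      nonessential <- c(nonessential, g)   # its reaction is blocked anyway
    }
  }

  ids <- names(rxn)
  rtab <- data.frame(
    id = ids,
    lower_bound = vapply(rxn, `[[`, numeric(1), "lb"),
    upper_bound = vapply(rxn, `[[`, numeric(1), "ub"),
    subsystem = vapply(rxn, `[[`, character(1), "subsystem"),
    gpr = vapply(rxn, `[[`, character(1), "gpr"),
    stringsAsFactors = FALSE)
  model <- MetabolicModel(
    metabolites = data.frame(id = mets, stringsAsFactors = FALSE),
    reactions = rtab,
    stoichiometry = lapply(rxn, `[[`, "stoich"),
    biomass = "BIOMASS")

  list(model = model,
       essential_genes = sort(unique(essential)),
       nonessential_genes = sort(unique(nonessential)),
       deadend_metabolites = sort(deadends),
       max_growth = min(uptake[seq_len(spec$n_pathways + spec$n_coupled)]),
       target_exchange = target_exchange,
       coupled_waste_genes = coupled_waste_genes)
}
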