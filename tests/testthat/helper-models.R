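# Shared fixtures and independent oracles, built in code at test time.

# linear chain: EX_a (uptake <= cap) -> a[c] -> b[c] -> c[c] -> demand
chainModel <- function(cap = 3) {
  MetabolicModel(
    metabolites = data.frame(id = c("a[e]", "a[c]", "b[c]", "c[c]")),
    reactions = data.frame(id = c("EX_a", "At", "R1", "R2", "DM_c"),
                           lower_bound = c(-cap, 0, 0, 0, 0),
                           upper_bound = rep(1000, 5)),
    stoichiometry = list(
      EX_a = c(`a[e]` = -1), At = c(`a[e]` = -1, `a[c]` = 1),
      R1 = c(`a[c]` = -1, `b[c]` = 1), R2 = c(`b[c]` = -1, `c[c]` = 1),
      DM_c = c(`c[c]` = -1)),
    biomass = "DM_c")
}

# fermentation/respiration fork: substrate -> A; A -> p (yield 1) or
# A + o2 -> 3 p (yield 3); product exported. Hand-set stoichiometry gives a
# piecewise-linear concave product-vs-oxygen curve.
forkModel <- function(cap = 10) {
  MetabolicModel(
    metabolites = data.frame(id = c("s[e]", "o2[e]", "p[e]", "a[c]", "o2[c]", "p[c]")),
    reactions = data.frame(
      id = c("EX_s", "EX_o2", "EX_p", "St", "O2t", "Pt", "FERM", "RESPIRE"),
      lower_bound = c(-cap, -1000, 0, 0, 0, 0, 0, 0),
      upper_bound = rep(1000, 8)),
    stoichiometry = list(
      EX_s = c(`s[e]` = -1), EX_o2 = c(`o2[e]` = -1), EX_p = c(`p[e]` = -1),
      St = c(`s[e]` = -1, `a[c]` = 1), O2t = c(`o2[e]` = -1, `o2[c]` = 1),
      Pt = c(`p[c]` = -1, `p[e]` = 1),
      FERM = c(`a[c]` = -1, `p[c]` = 1),
      RESPIRE = c(`a[c]` = -1, `o2[c]` = -1, `p[c]` = 3)),
    biomass = "EX_p")
}

# random GPR expression string over the given genes, plus an independent
# evaluator that routes through R's own parser rather than the package's
randomGPRString <- function(genes, depth = 3) {
  build <- function(d) {
    if (d <= 0 || stats::runif(1) < 0.35) return(sample(genes, 1))
    op <- sample(c("and", "or"), 1)
    k <- sample(2:3, 1)
    parts <- vapply(seq_len(k), function(i) build(d - 1), character(1))
    paste0("(", paste(parts, collapse = paste0(" ", op, " ")), ")")
  }
  build(depth)
}

referenceGPREval <- function(gprString, states) {
  expr <- gsub("\\band\\b", "&", gsub("\\bor\\b", "|", gprString))
  eval(parse(text = expr), envir = as.list(states))
}

# FBA objective via the independent dense reference solver
referenceGrowth <- function(model, objective = biomassReaction(model),
                            maximize = TRUE) {
  rxn <- reactions(model)
  referenceFBAObjective(stoichiometry(model), rxn$lower_bound, rxn$upper_bound,
                        match(objective, rxn$id), maximize = maximize)
}

maxStoichResidual <- function(model, sol) {
  v <- fluxes(sol)
  max(abs(stoichiometry(model) %*% v[colnames(stoichiometry(model))]))
}
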