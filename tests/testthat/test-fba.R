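# Medium construction, FBA contracts, robustness scans and flux reports.

test_that("buildMedium encodes the minimal-medium conventions", {
  m <- toyStipitisModel()
  xa <- buildMedium(m, "xylose", 3, "aerobic")
  b <- xa@bounds
  expect_equal(unname(b["EX_xyl", ]), c(-3, 1000))
  expect_equal(unname(b["EX_o2", "lower"]), -1000)
  expect_equal(unname(b["EX_glc", "lower"]), 0)       # other carbon closed
  expect_equal(unname(b["EX_nh4", ]), c(-1000, 1000)) # minimal components open
  expect_equal(unname(b["EX_glu", "lower"]), 0)       # amino acids closed

  gsa <- buildMedium(m, "glucose", 3, "semiaerobic")
  expect_equal(unname(gsa@bounds["EX_o2", "lower"]), -5)
  expect_equal(unname(gsa@bounds["EX_glc", "lower"]), -3)

  glu <- buildMedium(m, "xylose", 3, "aerobic", amino_acid = "glutamate",
                     amino_acid_uptake = 0.1)
  expect_equal(unname(glu@bounds["EX_glu", "lower"]), -0.1)
  expect_true(all(glu@bounds[paste0("EX_", setdiff(FluxBalanceR:::AMINO_ACID_TOKENS,
                                                   "glu")), "lower"] == 0))
  # fixed oxygen mode pins both bounds
  fx <- buildMedium(m, "xylose", 3, oxygen_mode = 2.5)
  expect_equal(unname(fx@bounds["EX_o2", ]), c(-2.5, -2.5))

  expect_error(buildMedium(m, "caffeine"), "no exchange reaction")
  expect_error(buildMedium(m, "xylose", amino_acid = "EX_unobtanium"),
               "not an exchange|no exchange")
})

test_that("FBA honours conservation, bounds, determinism and closed media", {
  m <- toyStipitisModel()
  med <- buildMedium(m, "xylose")
  sol <- solveFBA(m, med)
  expect_identical(solutionStatus(sol), "optimal")
  expect_lt(maxStoichResidual(m, sol), 1e-6)
  ma <- applyMedium(m, med)
  v <- fluxes(sol)[reactions(ma)$id]
  expect_true(all(v >= reactions(ma)$lower_bound - 1e-6))
  expect_true(all(v <= reactions(ma)$upper_bound + 1e-6))
  # repeated solves agree in objective value
  expect_equal(objectiveValue(solveFBA(m, med)), objectiveValue(sol), tolerance = 1e-9)
  # closed medium: zero optimum
  closed <- buildMedium(m, "xylose", carbon_uptake = 0, oxygen_mode = 0)
  expect_equal(objectiveValue(solveFBA(m, closed)), 0, tolerance = 1e-9)
  # statuses returned, not raised
  inf <- solveFBA(m, med, fixedFluxes = NULL,
                  objective = biomassReaction(m), direction = "max")
  expect_identical(solutionStatus(inf), "optimal")
  m2 <- setReactionBounds(applyMedium(m, med), c("EX_o2", "BIOMASS"),
                          c(0, 0.01), c(0, 0.01))
  expect_identical(solutionStatus(solveFBA(m2)), "infeasible")
  expect_error(solveFBA(m, med, objective = "nope"), "unknown objective")
})

test_that("widening a bound never decreases the maximal objective", {
  net <- generateNetwork(syntheticSpec(n_pathways = 3, seed = 21))
  m <- net$model
  base <- objectiveValue(solveFBA(m))
  for (rid in sample(reactions(m)$id, 8)) {
    j <- match(rid, reactions(m)$id)
    m2 <- setReactionBounds(m, rid,
                            reactions(m)$lower_bound[j] - 2,
                            reactions(m)$upper_bound[j] + 2)
    expect_gte(objectiveValue(solveFBA(m2)), base - 1e-6)
  }
})

test_that("parsimonious solve keeps the objective and shrinks total flux", {
  m <- toyStipitisModel()
  med <- buildMedium(m, "glucose")
  plain <- solveFBA(m, med)
  pf <- solveFBA(m, med, pfba = TRUE)
  expect_equal(objectiveValue(pf), objectiveValue(plain), tolerance = 1e-6)
  expect_lte(sum(abs(fluxes(pf))), sum(abs(fluxes(plain))) + 1e-6)
  expect_lt(maxStoichResidual(m, pf), 1e-6)
})

test_that("robustness scan fixes the controlled uptake and flags infeasible points", {
  # fork model: product curve piecewise linear against forced oxygen
  fm <- forkModel(cap = 10)
  rc <- robustnessScan(fm, NULL, "EX_o2", seq(0, 12, by = 1), "EX_p")
  expect_identical(rc@controlledReactionId, "EX_o2")
  # pointwise reference solves
  rxn <- reactions(fm)
  for (i in seq_along(rc@grid)) {
    lb <- rxn$lower_bound; ub <- rxn$upper_bound
    j <- match("EX_o2", rxn$id)
    lb[j] <- ub[j] <- -rc@grid[i]
    ref <- referenceFBAObjective(stoichiometry(fm), lb, ub, match("EX_p", rxn$id))
    if (ref$status == "optimal") {
      expect_equal(rc@responses[i], ref$objective, tolerance = 1e-6)
    } else {
      expect_true(is.na(rc@responses[i]))
    }
  }
  # oxygen > substrate capacity is infeasible, below it the curve is exact
  expect_equal(rc@responses[rc@grid <= 10],
               10 + 2 * rc@grid[rc@grid <= 10], tolerance = 1e-6)
  expect_true(all(is.na(rc@responses[rc@grid > 10])))

  # an objective whose pathway does not use oxygen yields a flat curve
  # (oxygen enters and is consumed by an independent side branch)
  cm2 <- MetabolicModel(
    metabolites = data.frame(id = c("a[e]", "a[c]", "c[c]", "o2[e]", "o2[c]", "ox[c]")),
    reactions = data.frame(id = c("EX_a", "At", "R1", "DM_c",
                                  "EX_o2", "O2t", "OXUSE", "DM_ox"),
                           lower_bound = c(-3, 0, 0, 0, -1000, 0, 0, 0),
                           upper_bound = rep(1000, 8)),
    stoichiometry = list(
      EX_a = c(`a[e]` = -1), At = c(`a[e]` = -1, `a[c]` = 1),
      R1 = c(`a[c]` = -1, `c[c]` = 1), DM_c = c(`c[c]` = -1),
      EX_o2 = c(`o2[e]` = -1), O2t = c(`o2[e]` = -1, `o2[c]` = 1),
      OXUSE = c(`o2[c]` = -1, `ox[c]` = 1), DM_ox = c(`ox[c]` = -1)),
    biomass = "DM_c")
  rc2 <- robustnessScan(cm2, NULL, "EX_o2", 0:5, "DM_c")
  expect_equal(rc2@responses, rep(3, 6), tolerance = 1e-9)

  expect_error(robustnessScan(fm, NULL, "EX_o2", c(1, 3, 2), "EX_p"), "monotone")
})

test_that("fixing growth during a scan is an equality constraint", {
  m <- toyStipitisModel()
  med <- buildMedium(m, "xylose")
  rc <- robustnessScan(m, med, "o2", c(2, 3), "EX_etoh", fixedGrowth = 0.01)
  # at the scanned point, re-solving with growth fixed reproduces the response
  ma <- setReactionBounds(applyMedium(m, med), c("EX_o2", "BIOMASS"),
                          c(-2, 0.01), c(-2, 0.01))
  s <- solveFBA(ma, objective = "EX_etoh")
  expect_equal(objectiveValue(s), rc@responses[1], tolerance = 1e-9)
  expect_equal(unname(fluxes(s)["BIOMASS"]), 0.01, tolerance = 1e-9)
})

test_that("condition flux report is deterministic and mass balanced", {
  m <- toyStipitisModel()
  ids <- c("PGI", "TKL1", "PDC", "IDH_L")
  rep1 <- conditionFluxReport(m, c("XA", "XA"), ids)
  expect_equal(rep1[[2]], rep1[[3]], tolerance = 1e-9)  # identical conditions
  rep2 <- conditionFluxReport(m, c("GA", "XA"), ids)
  # xylose routes carbon through the pentose phosphate pathway
  tkl <- which(rep2$id == "TKL1")
  expect_gt(abs(rep2$XA[tkl]), abs(rep2$GA[tkl]))
  expect_gt(rep2$GA[rep2$id == "growth"], 0)
})
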