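# Dead-end metabolite detection and minimal gap filling.

test_that("an intact chain has no gaps; breaking it flags the right metabolites", {
  m <- chainModel(3)
  g0 <- findGaps(m)
  expect_identical(g0@noProduction, character(0))
  expect_identical(g0@noConsumption, character(0))
  expect_identical(g0@blockedReactions, character(0))

  # remove the interior conversion a[c] -> b[c]
  broken <- MetabolicModel(
    metabolites = metabolites(m),
    reactions = reactions(m)[reactions(m)$id != "R1", ],
    stoichiometry = list(EX_a = c(`a[e]` = -1), At = c(`a[e]` = -1, `a[c]` = 1),
                         R2 = c(`b[c]` = -1, `c[c]` = 1), DM_c = c(`c[c]` = -1)),
    biomass = "DM_c")
  g1 <- findGaps(broken)
  expect_true(all(c("b[c]", "c[c]") %in% g1@noProduction))
  expect_true("a[c]" %in% g1@noConsumption)
  expect_true(all(c("At", "R2", "DM_c") %in% g1@blockedReactions))
})

test_that("an isolated metabolite is flagged in both dead-end sets", {
  m <- MetabolicModel(
    metabolites = data.frame(id = c("a[e]", "a[c]", "lonely[c]")),
    reactions = data.frame(id = c("EX_a", "At", "DM_a"),
                           lower_bound = c(-3, 0, 0), upper_bound = rep(1000, 3)),
    stoichiometry = list(EX_a = c(`a[e]` = -1), At = c(`a[e]` = -1, `a[c]` = 1),
                         DM_a = c(`a[c]` = -1)),
    biomass = "")
  g <- findGaps(m)
  expect_true("lonely[c]" %in% g@noProduction)
  expect_true("lonely[c]" %in% g@noConsumption)
})

test_that("gap sets shrink (weakly) as exchange bounds open", {
  net <- generateNetwork(syntheticSpec(n_pathways = 2, n_deadends = 2, seed = 31))
  m <- net$model
  medClosed <- methods::new("MediumSpec", name = "closed", bounds = {
    ex <- exchangeReactions(m)
    b <- cbind(lower = rep(0, length(ex)), upper = rep(1000, length(ex)))
    rownames(b) <- ex
    b
  })
  gClosed <- findGaps(m, medium = medClosed)
  gOpen <- findGaps(m)
  expect_true(all(gOpen@noProduction %in% gClosed@noProduction))
  expect_true(all(gOpen@noConsumption %in% gClosed@noConsumption))
})

test_that("single missing step is repaired by exactly that pool reaction", {
  m <- chainModel(3)
  broken <- MetabolicModel(
    metabolites = metabolites(m),
    reactions = reactions(m)[reactions(m)$id != "R1", ],
    stoichiometry = list(EX_a = c(`a[e]` = -1), At = c(`a[e]` = -1, `a[c]` = 1),
                         R2 = c(`b[c]` = -1, `c[c]` = 1), DM_c = c(`c[c]` = -1)),
    biomass = "DM_c")
  pool <- MetabolicModel(
    metabolites = data.frame(id = c("a[c]", "b[c]", "x[c]")),
    reactions = data.frame(id = c("U_mend", "U_noise"),
                           lower_bound = 0, upper_bound = 1000),
    stoichiometry = list(U_mend = c(`a[c]` = -1, `b[c]` = 1),
                         U_noise = c(`x[c]` = -1, `b[c]` = 1)),
    biomass = "")
  # already-producible target needs nothing
  expect_identical(fillGaps(broken, pool, "a[c]")[["a[c]"]], character(0))
  res <- fillGaps(broken, pool, "b[c]")
  expect_identical(res[["b[c]"]], "U_mend")
  # after the repair the target is no longer flagged
  fixed <- addPoolReactions(broken, pool, res[["b[c]"]])
  expect_false("b[c]" %in% findGaps(fixed)@noProduction)
})

test_that("two independent breaks need two additions, matching brute force", {
  # chain a -> b -> c -> d with both interior steps missing
  m <- MetabolicModel(
    metabolites = data.frame(id = c("a[e]", "a[c]", "b[c]", "c[c]", "d[c]")),
    reactions = data.frame(id = c("EX_a", "At", "R3", "DM_d"),
                           lower_bound = c(-3, 0, 0, 0), upper_bound = rep(1000, 4)),
    stoichiometry = list(EX_a = c(`a[e]` = -1), At = c(`a[e]` = -1, `a[c]` = 1),
                         R3 = c(`c[c]` = -1, `d[c]` = 1), DM_d = c(`d[c]` = -1)),
    biomass = "")
  pool <- MetabolicModel(
    metabolites = data.frame(id = c("a[c]", "b[c]", "c[c]")),
    reactions = data.frame(id = c("U1", "U2", "U3"),
                           lower_bound = 0, upper_bound = 1000),
    stoichiometry = list(U1 = c(`a[c]` = -1, `b[c]` = 1),
                         U2 = c(`b[c]` = -1, `c[c]` = 1),
                         U3 = c(`b[c]` = -1, `a[c]` = 1)),
    biomass = "")
  res <- fillGaps(m, pool, "d[c]")
  expect_setequal(res[["d[c]"]], c("U1", "U2"))
  # brute force over pool subsets of size <= 2 confirms minimality
  feasible <- function(add) {
    mm <- if (length(add)) addPoolReactions(m, pool, add) else m
    !("d[c]" %in% findGaps(mm)@noProduction)
  }
  expect_false(any(vapply(c("U1", "U2", "U3"), function(u) feasible(u), logical(1))))
  expect_true(feasible(c("U1", "U2")))
  # unknown targets are rejected up front
  expect_error(fillGaps(m, pool, "nope[c]"), "unknown target")
})
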