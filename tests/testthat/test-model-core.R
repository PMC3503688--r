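# Model construction, validation and summary statistics.

test_that("validation rejects malformed models", {
  mets <- data.frame(id = c("a[e]", "a[c]"))
  rx <- data.frame(id = c("EX_a", "At"), lower_bound = c(-3, 0),
                   upper_bound = c(1000, 1000))
  st <- list(EX_a = c(`a[e]` = -1), At = c(`a[e]` = -1, `a[c]` = 1))
  expect_s4_class(MetabolicModel(mets, rx, st, biomass = ""), "MetabolicModel")

  # duplicate metabolite id
  expect_error(MetabolicModel(rbind(mets, mets[1, ]), rx, st, biomass = ""),
               "duplicate")
  # unknown metabolite reference
  st2 <- st; st2$At <- c(`a[e]` = -1, `zz[c]` = 1)
  expect_error(MetabolicModel(mets, rx, st2, biomass = ""), "unknown metabolite")
  # exchange touching two metabolites is rejected
  rx3 <- rx; rx3$is_exchange <- c(TRUE, TRUE)
  expect_error(MetabolicModel(mets, rx3, st, biomass = ""), "exchange")
  # lb > ub
  rx4 <- rx; rx4$lower_bound[2] <- 5; rx4$upper_bound[2] <- 1
  expect_error(MetabolicModel(mets, rx4, st, biomass = ""), "lower_bound")
  # unresolvable biomass id
  expect_error(MetabolicModel(mets, rx, st, biomass = "nope"), "biomass")
  # GPR referencing a gene missing from an explicit gene list
  rx5 <- rx; rx5$gpr <- c("", "gX")
  expect_error(MetabolicModel(mets, rx5, st, biomass = "", genes = "gY"),
               "absent from the gene list")
})

test_that("exchange and transport flags are inferred from stoichiometry", {
  m <- MetabolicModel(
    metabolites = data.frame(id = c("a[e]", "a[c]", "b[c]")),
    reactions = data.frame(id = c("EX_a", "At", "R1"),
                           lower_bound = c(-3, 0, 0), upper_bound = rep(1000, 3)),
    stoichiometry = list(EX_a = c(`a[e]` = -1),
                         At = c(`a[e]` = -1, `a[c]` = 1),
                         R1 = c(`a[c]` = -1, `b[c]` = 1)),
    biomass = "")
  expect_identical(reactions(m)$is_exchange, c(TRUE, FALSE, FALSE))
  expect_identical(reactions(m)$is_transport, c(FALSE, TRUE, FALSE))
  expect_identical(exchangeReactions(m), "EX_a")
  # compartments read off the bracket suffix
  expect_setequal(compartments(m), c("c", "e"))
})

test_that("model statistics count gene associations consistently", {
  net <- generateNetwork(syntheticSpec(n_pathways = 2, length_range = c(3, 3),
                                       n_isoenzyme_pairs = 0, n_complexes = 0,
                                       n_deadends = 0, seed = 11))
  st <- modelStatistics(net$model)
  expect_identical(st$gene_associated + st$non_gene_associated, st$reactions)
  # exactly the six interior conversion steps carry GPRs
  expect_identical(st$gene_associated, 6L)
  expect_identical(st$genes, 6L)

  # a model with all GPRs empty has zero gene-associated reactions
  m0 <- chainModel()
  expect_identical(modelStatistics(m0)$gene_associated, 0L)
})

test_that("setReactionBounds updates bounds and validates", {
  m <- chainModel()
  m2 <- setReactionBounds(m, "R1", 0, 1.5)
  expect_equal(reactions(m2)$upper_bound[match("R1", reactions(m2)$id)], 1.5)
  expect_equal(objectiveValue(solveFBA(m2)), 1.5)
  expect_error(setReactionBounds(m, "nope", 0, 1), "unknown reaction")
  expect_error(setReactionBounds(m, "R1", 2, 1), "lower_bound")
})
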