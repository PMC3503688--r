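# Gene deletion semantics and essentiality classification.

test_that("isoenzymes survive single knockouts, complexes do not", {
  m <- MetabolicModel(
    metabolites = data.frame(id = c("a[c]", "b[c]", "c[c]")),
    reactions = data.frame(id = c("Riso", "Rcpx"),
                           lower_bound = 0, upper_bound = 1000,
                           gpr = c("A or B", "A and B")),
    stoichiometry = list(Riso = c(`a[c]` = -1, `b[c]` = 1),
                         Rcpx = c(`b[c]` = -1, `c[c]` = 1)),
    biomass = "")
  expect_identical(disabledReactions(m, "A"), "Rcpx")
  expect_identical(disabledReactions(m, c("A", "B")), c("Riso", "Rcpx"))
  expect_identical(disabledReactions(m, character(0)), character(0))
  expect_error(disabledReactions(m, "Z"), "unknown gene")
})

test_that("disabled reactions match truth-table evaluation on random GPR trees", {
  set.seed(303)
  genes <- paste0("G", 1:5)
  for (i in 1:30) {
    gprs <- replicate(4, randomGPRString(genes, depth = 2))
    m <- MetabolicModel(
      metabolites = data.frame(id = sprintf("m%d[c]", 1:5)),
      reactions = data.frame(id = sprintf("R%d", 1:4),
                             lower_bound = 0, upper_bound = 1000, gpr = gprs),
      stoichiometry = setNames(lapply(1:4, function(j) {
        setNames(c(-1, 1), sprintf("m%d[c]", c(j, j + 1)))
      }), sprintf("R%d", 1:4)),
      biomass = "", genes = genes)
    ko <- sample(genes, sample(0:4, 1))
    got <- disabledReactions(m, ko)
    states <- setNames(!(genes %in% ko), genes)
    want <- sprintf("R%d", which(!vapply(gprs, referenceGPREval, logical(1),
                                         states = states)))
    expect_identical(got, want)
  }
})

test_that("single-gene deletion recovers the generator's planted truth", {
  net <- generateNetwork(syntheticSpec(n_pathways = 3, length_range = c(2, 4),
                                       n_isoenzyme_pairs = 2, n_complexes = 1,
                                       n_deadends = 1, seed = 77))
  m <- net$model
  del <- singleGeneDeletion(m, NULL)
  expect_identical(sort(del$gene[del$essential]), net$essential_genes)
  # knockout monotonicity: constraints only added
  wt <- attr(del, "wild_type_growth")
  expect_true(all(del$mutant_growth <= wt + 1e-6))
  # a gene with an isoenzyme partner is nonessential
  expect_true(all(!del$essential[del$gene %in% net$nonessential_genes]))
})

test_that("deletion is idempotent and no-op genes leave growth unchanged exactly", {
  net <- generateNetwork(syntheticSpec(n_pathways = 2, n_deadends = 1, seed = 13))
  m <- net$model
  g <- net$essential_genes[1]
  m1 <- knockoutGenes(m, g)
  m2 <- knockoutGenes(m1, g)
  expect_identical(reactions(m1), reactions(m2))
  # the dead-end reaction's gene touches no growth-carrying route
  gd <- setdiff(net$nonessential_genes, unlist(lapply(m@gprTrees, gprGenes)))
  del <- singleGeneDeletion(m, NULL, geneIds = net$nonessential_genes)
  expect_true(all(del$growth_ratio > 1 - 1e-9))
})

test_that("media essentiality comparison returns clean set differences", {
  m <- toyStipitisModel()
  glc <- buildMedium(m, "glucose")
  cmp0 <- compareMediaEssentiality(m, glc, glc)
  expect_identical(cmp0$only_a, character(0))
  expect_identical(cmp0$only_b, character(0))

  xyl <- buildMedium(m, "xylose")
  cmp <- compareMediaEssentiality(m, glc, xyl)
  # the xylose-entry genes appear only in the xylose-essential difference
  expect_true(all(c("XYL1", "XYL2") %in% cmp$only_b))
  expect_false(any(c("XYL1", "XYL2") %in% cmp$essential_a))

  # zero wild-type growth is an actionable error
  closed <- buildMedium(m, "xylose", carbon_uptake = 0, oxygen_mode = 0)
  expect_error(singleGeneDeletion(m, closed), "check the medium")
})
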