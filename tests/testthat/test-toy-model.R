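# The bundled toy S. stipitis central-carbon model.

test_that("the toy model validates and grows on its sugars", {
  m <- toyStipitisModel()
  expect_true(methods::validObject(m))
  st <- modelStatistics(m)
  expect_gte(st$reactions, 60)
  expect_setequal(compartments(m), c("c", "e", "m"))
  # growth on every carbon source the pathway map covers
  for (sugar in c("glucose", "xylose", "mannose", "galactose", "cellobiose",
                  "rhamnose", "arabinose")) {
    carbon <- if (sugar == "arabinose") "larab" else sugar
    g <- objectiveValue(solveFBA(m, buildMedium(m, carbon)))
    expect_gt(g, 0)
  }
  # growth values agree with the independent dense reference solver
  med <- buildMedium(m, "glucose")
  ref <- referenceGrowth(applyMedium(m, med))
  expect_equal(objectiveValue(solveFBA(m, med)), ref$objective, tolerance = 1e-6)
})

test_that("xylose can bypass the xylulokinase through the D-arabinitol route", {
  m <- toyStipitisModel()
  xyl <- buildMedium(m, "xylose")
  del <- singleGeneDeletion(m, xyl, geneIds = c("XKS1", "XYL1", "XYL2"))
  expect_false(del$essential[del$gene == "XKS1"])
  expect_true(all(del$essential[del$gene %in% c("XYL1", "XYL2")]))
  # the bypass disappears when its kinase is removed as well
  m2 <- knockoutGenes(m, c("XKS1", "RKS1"))
  expect_equal(objectiveValue(solveFBA(m2, xyl)), 0, tolerance = 1e-9)
})

test_that("mitochondrial ADH3 carries ethanol only when the cytosolic route is gone", {
  m <- toyStipitisModel()
  ma <- applyMedium(m, buildMedium(m, "xylose"))
  wt <- objectiveValue(solveFBA(ma, objective = "EX_etoh"))
  expect_gt(wt, 0)
  noCyt <- knockoutGenes(ma, c("ADH1", "ADH2", "ADH4", "ADH5"))
  viaMito <- objectiveValue(solveFBA(noCyt, objective = "EX_etoh"))
  expect_gt(viaMito, 0)
  none <- knockoutGenes(noCyt, "ADH3")
  expect_equal(objectiveValue(solveFBA(none, objective = "EX_etoh")), 0,
               tolerance = 1e-9)
})

test_that("closed medium supports no growth", {
  m <- toyStipitisModel()
  closed <- buildMedium(m, "glucose", carbon_uptake = 0, oxygen_mode = 0)
  expect_equal(objectiveValue(solveFBA(m, closed)), 0, tolerance = 1e-9)
})

test_that("gene aliases resolve the published locus tags", {
  al <- geneAliases()
  expect_true(all(c("symbol", "locus_tag") %in% names(al)))
  expect_identical(al$locus_tag[al$symbol == "XYL1"], "PICST_89614")
  expect_identical(al$locus_tag[al$symbol == "GDH3"], "PICST_82969")
  m <- toyStipitisModel()
  expect_true(all(c("XYL1", "XYL2", "XKS1", "ADH3", "GDH3") %in% genes(m)))
})
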