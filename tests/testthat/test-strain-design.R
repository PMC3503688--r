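# OptKnock bilevel designs, enumeration oracle and supplementation scans.

coupledNet <- function(seed, pathways = 1) {
  net <- generateNetwork(syntheticSpec(n_pathways = pathways,
                                       length_range = c(2, 3),
                                       n_isoenzyme_pairs = 1, n_complexes = 0,
                                       n_deadends = 0, n_coupled = 1,
                                       seed = seed))
  # make the plain pathway the growth bottleneck so the waste route carries
  # the redox byproduct in the wild type
  net$model <- setReactionBounds(net$model, "EX_sub1", -10, NA)
  net
}

test_that("zero knockout budget returns the wild-type design", {
  net <- coupledNet(1)
  des <- optKnock(net$model, NULL, net$target_exchange, 0,
                  net$nonessential_genes, min_growth_fraction = 0.05)
  expect_identical(des$knocked_genes[des$n_knockouts == 0], "")
  expect_equal(des$relative_change_pct[des$n_knockouts == 0], 0)
  en <- enumerateKnockouts(net$model, NULL, net$target_exchange,
                           net$nonessential_genes, k = 0)
  expect_identical(nrow(en), 1L)
  expect_identical(en$knocked_genes, "")
})

test_that("the planted growth-coupled drain is the unique optimal single knockout", {
  net <- coupledNet(5)
  en <- enumerateKnockouts(net$model, NULL, net$target_exchange,
                           net$nonessential_genes, k = 1)
  expect_identical(en$knocked_genes[1], net$coupled_waste_genes)
  expect_gt(en$production_rate[1], en$production_rate[en$knocked_genes == ""])
  des <- optKnock(net$model, NULL, net$target_exchange, 1,
                  net$nonessential_genes, min_growth_fraction = 0.05)
  expect_identical(des$knocked_genes[1], net$coupled_waste_genes)
  expect_equal(des$production_rate[1], en$production_rate[1], tolerance = 1e-6)
})

test_that("optKnock equals exhaustive enumeration on random networks", {
  for (seed in c(2, 3, 4)) {
    net <- coupledNet(seed)
    cand <- net$nonessential_genes
    for (k in 1:2) {
      en <- enumerateKnockouts(net$model, NULL, net$target_exchange, cand, k = k)
      des <- optKnock(net$model, NULL, net$target_exchange, k, cand,
                      min_growth_fraction = 0.05)
      expect_equal(des$production_rate[1], en$production_rate[1], tolerance = 1e-6)
      expect_length(attr(des, "diagnostic"), 0)
    }
  }
})

test_that("optKnock objective is non-decreasing in the knockout budget", {
  net <- coupledNet(6)
  cand <- net$nonessential_genes
  prods <- vapply(0:2, function(k) {
    optKnock(net$model, NULL, net$target_exchange, k, cand,
             min_growth_fraction = 0.05)$production_rate[1]
  }, numeric(1))
  expect_true(all(diff(prods) >= -1e-6))
})

test_that("candidate sets containing essential genes are rejected", {
  net <- coupledNet(7)
  expect_error(optKnock(net$model, NULL, net$target_exchange, 1,
                        c(net$nonessential_genes, net$essential_genes[1])),
               "essential")
  expect_error(optKnock(net$model, NULL, net$target_exchange, 1, "nogene"),
               "unknown candidate")
})

test_that("amino-acid supplementation never hurts growth; inert additions equal control", {
  m <- toyStipitisModel()
  med <- buildMedium(m, "xylose")
  aas <- paste0("EX_", FluxBalanceR:::AMINO_ACID_TOKENS)
  scan <- aminoAcidScan(m, med, "EX_etoh", aas)
  ctrl <- scan[scan$amino_acid == "control", ]
  expect_true(all(scan$growth_rate >= ctrl$growth_rate - 1e-6))
  # only glutamate has uptake machinery in the toy model: all other rows
  # equal the control
  inert <- scan[!(scan$amino_acid %in% c("control", "EX_glu")), ]
  expect_equal(inert$growth_rate, rep(ctrl$growth_rate, nrow(inert)), tolerance = 1e-6)
  glu <- scan[scan$amino_acid == "EX_glu", ]
  expect_gt(glu$growth_rate, ctrl$growth_rate + 1e-6)
})
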