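# The synthetic-network generator and its planted ground truth.

test_that("generated models validate and are reproducible from the seed", {
  for (seed in c(1, 9, 123)) {
    n1 <- generateNetwork(syntheticSpec(n_pathways = 3, n_isoenzyme_pairs = 2,
                                        n_complexes = 1, n_deadends = 2,
                                        seed = seed))
    expect_true(methods::validObject(n1$model))
    n2 <- generateNetwork(syntheticSpec(n_pathways = 3, n_isoenzyme_pairs = 2,
                                        n_complexes = 1, n_deadends = 2,
                                        seed = seed))
    expect_identical(reactions(n1$model), reactions(n2$model))
    expect_identical(n1$essential_genes, n2$essential_genes)
  }
})

test_that("FBA reproduces the analytic bottleneck growth", {
  for (seed in 1:8) {
    net <- generateNetwork(syntheticSpec(n_pathways = sample(1:4, 1),
                                         n_isoenzyme_pairs = 1, n_complexes = 1,
                                         n_deadends = 1, seed = seed))
    expect_equal(objectiveValue(solveFBA(net$model)), net$max_growth,
                 tolerance = 1e-8)
  }
})

test_that("a single pathway without isoenzymes makes every pathway gene essential", {
  net <- generateNetwork(syntheticSpec(n_pathways = 1, length_range = c(3, 3),
                                       n_isoenzyme_pairs = 0, n_complexes = 0,
                                       n_deadends = 0, seed = 4))
  ess <- essentialGenes(net$model, NULL)
  expect_identical(ess, net$essential_genes)
  expect_identical(length(ess), 3L)
})

test_that("duplicating every reaction as an isoenzyme pair removes all essentiality", {
  net <- generateNetwork(syntheticSpec(n_pathways = 2, length_range = c(2, 2),
                                       n_isoenzyme_pairs = 4, n_complexes = 0,
                                       n_deadends = 0, seed = 15))
  expect_identical(net$essential_genes, character(0))
  expect_identical(essentialGenes(net$model, NULL), character(0))
})
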