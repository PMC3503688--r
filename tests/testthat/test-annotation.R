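# Homology-hit filtering and draft association merging.

makeHits <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(
    query_gene = sprintf("q%03d", seq_len(n)),
    subject_gene = sprintf("s%03d", seq_len(n)),
    template = sample(c("Sce", "Ppa", "Ani"), n, TRUE),
    e_value = 10^runif(n, -60, -10),
    identity_pct = runif(n, 10, 95),
    coverage_pct = runif(n, 30, 100),
    bidirectional = runif(n) > 0.3,
    stringsAsFactors = FALSE)
}

test_that("threshold boundary semantics follow the stated wording exactly", {
  base <- makeHits(1)
  base$bidirectional <- TRUE
  # identity must be strictly above 40
  h <- base; h$e_value <- 1e-31; h$identity_pct <- 40; h$coverage_pct <- 70
  expect_identical(nrow(filterHits(h)), 0L)
  h$identity_pct <- 40.0001
  expect_identical(nrow(filterHits(h)), 1L)
  # e-value must be strictly below 1e-30
  h2 <- base; h2$e_value <- 1e-30; h2$identity_pct <- 80; h2$coverage_pct <- 100
  expect_identical(nrow(filterHits(h2)), 0L)
  # coverage of exactly 70 is kept ("at least")
  h3 <- base; h3$e_value <- 1e-40; h3$identity_pct <- 50; h3$coverage_pct <- 70
  expect_identical(nrow(filterHits(h3)), 1L)
  # bidirectionality flag
  h3$bidirectional <- FALSE
  expect_identical(nrow(filterHits(h3)), 0L)
  expect_identical(nrow(filterHits(h3, require_bidirectional = FALSE)), 1L)
  expect_error(filterHits(h3, e_max = -1), "thresholds")
})

test_that("survivors equal a record-by-record reference predicate", {
  hits <- makeHits(100, seed = 7)
  surv <- filterHits(hits)
  ref <- vapply(seq_len(nrow(hits)), function(i) {
    hits$e_value[i] < 1e-30 && hits$identity_pct[i] > 40 &&
      hits$coverage_pct[i] >= 70 && hits$bidirectional[i]
  }, logical(1))
  expect_identical(rownames(surv), rownames(hits)[ref])  # order preserved
  expect_identical(nrow(surv), sum(ref))
})

test_that("filtering is idempotent and monotone in each threshold", {
  hits <- makeHits(200, seed = 8)
  surv <- filterHits(hits)
  expect_identical(filterHits(surv), surv)
  n0 <- nrow(surv)
  expect_gte(nrow(filterHits(hits, e_max = 1e-20)), n0)
  expect_gte(nrow(filterHits(hits, identity_min_pct = 30)), n0)
  expect_gte(nrow(filterHits(hits, coverage_min_pct = 50)), n0)
  expect_gte(nrow(filterHits(hits, require_bidirectional = FALSE)), n0)
})

test_that("association merge matches set algebra", {
  pairs <- function(g, r) data.frame(gene = g, reaction_id = r, stringsAsFactors = FALSE)
  a <- pairs(c("g1", "g2", "g3"), c("r1", "r2", "r3"))
  b <- pairs(c("g4", "g5"), c("r4", "r5"))
  m <- mergeAssociations(a, b)
  expect_identical(nrow(m), 5L)
  expect_false(any(m$evidence == "both"))
  m2 <- mergeAssociations(a, a)
  expect_identical(nrow(m2), 3L)
  expect_true(all(m2$evidence == "both"))

  set.seed(9)
  for (i in 1:10) {
    ga <- pairs(sample(letters[1:6], 12, TRUE), sample(paste0("r", 1:6), 12, TRUE))
    gb <- pairs(sample(letters[1:6], 12, TRUE), sample(paste0("r", 1:6), 12, TRUE))
    mm <- mergeAssociations(ga, gb)
    ka <- unique(paste(ga$gene, ga$reaction_id)); kb <- unique(paste(gb$gene, gb$reaction_id))
    expect_identical(nrow(mm), length(union(ka, kb)))
    expect_identical(sum(mm$evidence == "both"), length(intersect(ka, kb)))
    expect_false(is.unsorted(paste(mm$gene, mm$reaction_id)))  # deterministic order
  }
})

test_that("hit and KO tables read from TSV and expand through a KO map", {
  td <- withr::local_tempdir()
  writeLines(c("qseqid\tsseqid\tpident\tlength\tevalue\tqlen\ttemplate\tbidirectional",
               "q1\ts1\t80\t350\t1e-50\t400\tSce\t1",
               "q2\ts2\t35\t100\t1e-50\t400\tSce\t1"),
             file.path(td, "hits.tsv"))
  h <- readHitTable(file.path(td, "hits.tsv"))
  expect_equal(h$coverage_pct, c(87.5, 25))
  expect_identical(nrow(filterHits(h)), 1L)
  writeLines(c("gene\tko_id", "g1\tK00001", "g2\tK00002"), file.path(td, "ko.tsv"))
  ko <- readKOTable(file.path(td, "ko.tsv"))
  komap <- data.frame(ko_id = c("K00001", "K00001", "K00003"),
                      reaction_id = c("r1", "r2", "r9"))
  ex <- expandKOPairs(ko, komap)
  expect_identical(ex$reaction_id, c("r1", "r2"))
  expect_true(all(ex$gene == "g1"))
})
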