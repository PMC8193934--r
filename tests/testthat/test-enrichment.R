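test_that("hypergeometric upper tail matches the worked example and edge cases", {
  # draw 4 from 10 (5 annotated): P(X >= 4) = C(5,4)C(5,0)/C(10,4) = 5/210
  expect_equal(hypergeomUpperTail(4, 5, 4, 10), 5 / 210, tolerance = 1e-12)
  # literal enumeration of all C(10,4) = 210 draws
  draws <- utils::combn(10, 4)
  annotated <- 1:5
  frac <- mean(colSums(matrix(draws %in% annotated, nrow = 4)) >= 4)
  expect_equal(hypergeomUpperTail(4, 5, 4, 10), frac, tolerance = 1e-12)

  expect_equal(hypergeomUpperTail(0, 5, 4, 10), 1)
  expect_equal(hypergeomUpperTail(6, 6, 6, 6), 1)
  expect_error(hypergeomUpperTail(5, 4, 5, 10), "inconsistent")
  expect_error(hypergeomUpperTail(-1, 4, 5, 10), "non-negative")
})

test_that("upper tail equals counting-oracle values on a broad grid", {
  for (N in c(5L, 9L, 12L)) {
    for (K in seq(0L, N, by = 2L)) for (n in seq(1L, N, by = 2L)) {
      for (k in 0:min(K, n)) {
        expect_equal(hypergeomUpperTail(k, K, n, N),
                     oracleHyper(k, K, n, N), tolerance = 1e-10)
      }
    }
  }
})

test_that("BH adjustment matches hand-computed step-up values", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bhAdjust(0.04), 0.04)
  expect_equal(bhAdjust(rep(0.2, 5)), rep(0.2, 5))
  # order-preserving, elementwise >= p, capped at 1
  p <- c(0.001, 0.8, 0.04, 0.3, 0.9)
  adj <- bhAdjust(p)
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
  expect_equal(order(adj), order(p))
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("enrichment flags the identical term and skips disjoint ones", {
  universe <- sprintf("G%02d", 1:15)
  query <- GeneSet(universe[1:4])
  ann <- new("AnnotationSet",
             termId = c("T1", "T2"),
             termName = c("same as query", "disjoint"),
             namespace = c("BP", "BP"),
             genes = list(universe[1:4], universe[10:15]))
  res <- enrich(query, ann, universe = universe)
  t1 <- res[res$term_id == "T1", ]
  t2 <- res[res$term_id == "T2", ]
  expect_equal(t1$k, 4L)
  expect_equal(t1$p, 1 / choose(15, 4), tolerance = 1e-12)
  expect_equal(t2$k, 0L)
  expect_equal(t2$p, 1)
  expect_false(t2$significant)
  expect_true(t1$significant)  # padj = 2 * 1/1365 < 0.05
  expect_equal(res$term_id[1L], "T1")  # sorted by padj
})

test_that("terms are intersected with the universe before testing", {
  universe <- sprintf("G%02d", 1:10)
  ann <- new("AnnotationSet", termId = "T1", termName = "t",
             namespace = "KEGG",
             genes = list(c(universe[1:3], "OUTSIDE1", "OUTSIDE2")))
  res <- enrich(GeneSet(universe[1:3]), ann, universe = universe)
  expect_equal(res$K, 3L)  # out-of-universe members ignored
  expect_equal(res$N, 10L)
  expect_error(enrich(GeneSet("ZZZ"), ann, universe = universe),
               "no gene in the universe")
})

test_that("namespace-wise and pooled adjustment modes differ as expected", {
  set.seed(1)
  universe <- sprintf("G%03d", 1:100)
  ann <- genAnnotations(universe, query = universe[1:20], nTerms = 30L,
                        seed = 12L)$annotations
  q <- GeneSet(universe[1:20])
  byNS <- enrich(q, ann, universe = universe, byNamespace = TRUE)
  pooled <- enrich(q, ann, universe = universe, byNamespace = FALSE)
  expect_setequal(byNS$term_id, pooled$term_id)
  # within one namespace, adjusted values use that family's size
  oneNS <- byNS[byNS$namespace == byNS$namespace[1L], ]
  expect_equal(oneNS$padj, bhAdjust(oneNS$p), tolerance = 1e-12)
  pooledNS <- pooled[match(oneNS$term_id, pooled$term_id), ]
  expect_equal(pooledNS$p, oneNS$p)  # p unchanged, only the family differs
})

test_that("the planted enriched term ranks first in nearly all replicates", {
  universe <- sprintf("G%03d", 1:200)
  hits <- 0L
  reps <- 40L
  for (i in seq_len(reps)) {
    sim <- genAnnotations(universe, query = universe[1:30], nTerms = 30L,
                          plantedOverlap = 0.8, seed = 1000L + i)
    res <- enrich(GeneSet(universe[1:30]), sim$annotations,
                  universe = universe, byNamespace = FALSE)
    if (res$term_id[1L] == sim$ledger$plantedTerm) hits <- hits + 1L
  }
  expect_gte(hits / reps, 0.95)
})
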