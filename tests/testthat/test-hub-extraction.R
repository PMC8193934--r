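test_that("one filter round on the clique-pendant fixture keeps the clique", {
  g <- cliquePendantGraph(5)
  res <- medianFilterRound(g)
  expect_setequal(res$report$retained, sprintf("C%d", 1:5))
  # hand-computed round medians on the 10-node graph
  expect_equal(unname(res$report$medians["dc"]), 3)
  expect_equal(unname(res$report$medians["bc"]), 4)
  expect_equal(unname(res$report$medians["lac"]), 1.2)
  expect_equal(unname(res$report$medians["nc"]), 1.5)
  expect_equal(unname(res$report$medians["cc"]), (9 / 13 + 9 / 21) / 2)
  expect_equal(res$report$nIn, 10L)
  expect_equal(res$report$nOut, 5L)
})

test_that("fully symmetric graphs filter to the empty set", {
  res <- medianFilterRound(completeGraph(4))
  expect_length(res$report$retained, 0L)
  expect_equal(numNodes(res$graph), 0L)
})

test_that("two-round extraction stops early instead of emptying", {
  g <- cliquePendantGraph(5)
  res <- extractHubs(g, rounds = 2)
  expect_setequal(geneSymbols(res$hubs), sprintf("C%d", 1:5))
  expect_equal(res$stopReason, "would_empty")
  expect_length(res$reports, 2L)  # the emptying round is still reported
  expect_equal(res$reports[[2L]]$nOut, 0L)

  zero <- extractHubs(g, rounds = 0)
  expect_setequal(geneSymbols(zero$hubs), nodeNames(g))
  expect_length(zero$reports, 0L)
})

test_that("every retained node strictly exceeds all six round medians", {
  for (seed in 1:15) {
    g <- randomGraph(50, 0.08, seed = seed)
    res <- medianFilterRound(g)
    if (!length(res$report$retained)) next
    ct <- centralityTable(g)
    med <- featureMedians(ct)
    df <- as.data.frame(ct)
    kept <- df[df$node %in% res$report$retained, ]
    for (f in c("bc", "cc", "dc", "ec", "lac", "nc"))
      expect_true(all(kept[[f]] > med[[f]]))
  }
})

test_that("rounds shrink monotonically and respect the strict-majority bound", {
  for (seed in 1:10) {
    g <- randomGraph(50, 0.08, seed = seed)
    res <- extractHubs(g, rounds = 3)
    sets <- c(list(nodeNames(g)),
              lapply(res$reports, `[[`, "retained"))
    for (i in seq_len(length(sets) - 1L)) {
      expect_true(all(sets[[i + 1L]] %in% sets[[i]]))
      nIn <- res$reports[[i]]$nIn
      expect_lte(length(sets[[i + 1L]]), ceiling((nIn - 1) / 2))
    }
  }
})

test_that("hub extraction is deterministic", {
  g <- randomGraph(40, 0.1, seed = 99)
  r1 <- extractHubs(g, rounds = 2)
  r2 <- extractHubs(g, rounds = 2)
  expect_identical(geneSymbols(r1$hubs), geneSymbols(r2$hubs))
  expect_identical(filterReportTable(r1$reports),
                   filterReportTable(r2$reports))
})

test_that("relaxed minFeatures keeps a superset of the conjunctive rule", {
  g <- randomGraph(50, 0.08, seed = 5)
  strict <- medianFilterRound(g, minFeatures = 6)$report$retained
  relaxed <- medianFilterRound(g, minFeatures = 4)$report$retained
  expect_true(all(strict %in% relaxed))
})

test_that("planted-module hubs are recovered with high precision", {
  sim <- genPPI(nBackground = 80L, moduleSize = 20L, pModule = 0.8,
                pBackground = 0.05, pCross = 0.02, seed = 17L)
  g <- buildPPI(sim$edges)
  res <- extractHubs(g, rounds = 2)
  hubs <- geneSymbols(res$hubs)
  precision <- length(intersect(hubs, sim$ledger$module)) / length(hubs)
  expect_gte(precision, 0.8)
})
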