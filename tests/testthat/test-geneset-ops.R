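test_that("merging deletes redundant items and keeps provenance", {
  s1 <- GeneSet(c("A", "B"), name = "db1", sources = "db1")
  s2 <- GeneSet(c("B", "C"), name = "db2", sources = "db2")
  m <- mergeGeneSets(list(s1, s2))
  expect_setequal(geneSymbols(m), c("A", "B", "C"))
  expect_setequal(provenance(m)[["B"]], c("db1", "db2"))
  expect_equal(provenance(m)[["A"]], "db1")

  single <- mergeGeneSets(list(s1))
  expect_setequal(geneSymbols(single), geneSymbols(s1))
})

test_that("five generated sources merge to the planted union size", {
  sim <- genDiseaseSources(nSources = 5L, unionSize = 500L,
                           redundancy = 0.3, seed = 9L)
  sets <- lapply(names(sim$sources), function(lbl)
    GeneSet(sim$sources[[lbl]], name = lbl, sources = lbl))
  m <- mergeGeneSets(sets)
  expect_equal(length(m), 500L)
  expect_setequal(geneSymbols(m), sim$ledger$union)
})

test_that("venn partition matches hand examples", {
  s1 <- GeneSet(c("A", "B"), name = "S1")
  s2 <- GeneSet(c("B", "C"), name = "S2")
  vp <- vennPartition(list(s1, s2))
  expect_equal(vp$regions[["S1"]], "A")
  expect_equal(vp$regions[["S2"]], "C")
  expect_equal(vp$regions[["S1&S2"]], "B")
  expect_equal(sum(vp$counts), 3L)

  same <- vennPartition(list(GeneSet(c("X", "Y"), name = "P"),
                             GeneSet(c("X", "Y"), name = "Q")))
  expect_equal(unname(same$counts[["P&Q"]]), 2L)
  expect_equal(sum(same$counts), 2L)
})

test_that("venn partition equals brute-force membership enumeration", {
  set.seed(77)
  for (rep in 1:5) {
    universe <- sprintf("G%03d", 1:60)
    sets <- lapply(1:3, function(i)
      GeneSet(sample(universe, sample(10:40, 1)),
              name = paste0("S", i)))
    vp <- vennPartition(sets)
    # brute force: classify every union symbol by its membership pattern
    symbols <- unique(unlist(lapply(sets, geneSymbols)))
    for (sym in symbols) {
      inSet <- vapply(sets, function(s) sym %in% geneSymbols(s), logical(1))
      key <- paste(paste0("S", 1:3)[inSet], collapse = "&")
      expect_true(sym %in% vp$regions[[key]])
    }
    # conservation and disjointness
    expect_equal(sum(vp$counts), length(symbols))
    expect_false(anyDuplicated(unlist(vp$regions)) > 0)
  }
})

test_that("venn partition can be recomputed from a merged set alone", {
  s1 <- GeneSet(c("A", "B"), name = "S1", sources = "S1")
  s2 <- GeneSet(c("B", "C"), name = "S2", sources = "S2")
  direct <- vennPartition(list(s1, s2))
  viaMerge <- vennPartition(mergeGeneSets(list(s1, s2)))
  expect_equal(viaMerge$counts, direct$counts)
})

test_that("venn partition enforces the 2-6 set display limit", {
  sets <- lapply(1:7, function(i) GeneSet("A", name = paste0("S", i)))
  expect_error(vennPartition(sets[1]), "2 to 6")
  expect_error(vennPartition(sets), "2 to 6")
})

test_that("drug-disease intersection is correct, commutative and strict on emptiness", {
  drug <- GeneSet(c("TNF", "IL6", "EGFR"), name = "drug")
  disease <- GeneSet(c("TNF", "EGFR", "TP53"), name = "disease")
  ps <- intersectDrugDisease(drug, disease)
  expect_setequal(geneSymbols(ps), c("TNF", "EGFR"))
  expect_equal(geneSetName(ps), "putative_targets")
  expect_true(all(geneSymbols(ps) %in% geneSymbols(drug)))
  expect_true(all(geneSymbols(ps) %in% geneSymbols(disease)))
  expect_setequal(geneSymbols(intersectDrugDisease(disease, drug)),
                  geneSymbols(ps))

  disjoint <- GeneSet(c("MYC"), name = "other")
  expect_error(intersectDrugDisease(drug, disjoint), "disjoint")
})

test_that("planted drug-disease overlap is recovered exactly", {
  shared <- sprintf("S%03d", 1:60)
  drug <- GeneSet(c(shared, sprintf("D%03d", 1:40)), name = "drug")
  disease <- GeneSet(c(shared, sprintf("X%03d", 1:80)), name = "disease")
  ps <- intersectDrugDisease(drug, disease)
  expect_equal(length(ps), 60L)
  expect_setequal(geneSymbols(ps), shared)
})
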