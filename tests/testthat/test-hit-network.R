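makeACS <- function(herbComponents, componentTargets) {
  mols <- unique(unlist(herbComponents, use.names = FALSE))
  flagged <- mols[lengths(componentTargets[mols]) == 0L]
  new("ActiveComponentSet", herbComponents = herbComponents,
      componentTargets = componentTargets[mols], flagged = flagged,
      unionTargets = sort(unique(unlist(componentTargets[mols],
                                        use.names = FALSE))))
}

test_that("shared ingredients keep one node with one edge per herb", {
  acs <- makeACS(list(H1 = "Q", H2 = "Q"),
                 list(Q = c("TNF", "MYC")))
  net <- buildHITNetwork(acs, GeneSet("TNF"))
  expect_equal(ingredientNodes(net), "Q")
  expect_equal(nrow(net@herbEdges), 2L)
  expect_equal(geneNodes(net), "TNF")  # MYC outside the putative set
  expect_equal(nrow(net@targetEdges), 1L)
})

test_that("ingredients targeting only out-of-intersection genes are dropped", {
  acs <- makeACS(list(H1 = c("M1", "M2")),
                 list(M1 = "TNF", M2 = "MYC"))
  net <- buildHITNetwork(acs, GeneSet("TNF"))
  expect_equal(ingredientNodes(net), "M1")
  expect_error(buildHITNetwork(acs, GeneSet("KRAS")), "empty|no ingredient")
})

test_that("tripartite constraints hold and gene-degree equals restricted set size", {
  sim <- genIngredients(seed = 21L)
  kept <- screenIngredients(sim$table)
  tmap <- genTargetMap(sim$table$molecule_id,
                       genePool = sprintf("G%03d", 1:120), seed = 21L,
                       cover = kept$molecule_id)
  acs <- mapTargets(kept, tmap$table)
  putative <- GeneSet(sample(targetUnion(acs), 60))
  net <- buildHITNetwork(acs, putative)
  # edges only between adjacent partitions (validity enforces, re-check)
  expect_true(all(net@herbEdges[, 1L] %in% herbNodes(net)))
  expect_true(all(net@herbEdges[, 2L] %in% ingredientNodes(net)))
  expect_true(all(net@targetEdges[, 1L] %in% ingredientNodes(net)))
  expect_true(all(net@targetEdges[, 2L] %in% geneNodes(net)))
  expect_length(intersect(geneNodes(net), herbNodes(net)), 0L)
  # gene nodes restricted to the putative set
  expect_true(all(geneNodes(net) %in% geneSymbols(putative)))
  # ingredient gene-degree = size of its restricted target set
  deg <- ingredientGeneDegree(net)
  for (m in ingredientNodes(net)) {
    expected <- length(intersect(componentTargets(acs)[[m]],
                                 geneSymbols(putative)))
    expect_equal(unname(deg[m]), expected)
  }
})

test_that("per-herb target partition unions genes through ingredients", {
  acs <- makeACS(list(H1 = c("M1", "M2"), H2 = "M2"),
                 list(M1 = "A", M2 = "B"))
  net <- buildHITNetwork(acs, GeneSet(c("A", "B")))
  part <- herbTargetPartition(net)
  expect_equal(part$H1, c("A", "B"))
  expect_equal(part$H2, "B")

  # degenerate: all ingredients shared -> identical per-herb sets
  acs2 <- makeACS(list(H1 = "M1", H2 = "M1"), list(M1 = c("A", "B")))
  part2 <- herbTargetPartition(buildHITNetwork(acs2, GeneSet(c("A", "B"))))
  expect_equal(part2$H1, part2$H2)
})

test_that("representative components take the max-degree ingredient per herb", {
  acs <- makeACS(list(H1 = c("M1", "M2")),
                 list(M1 = c("A", "B", "C"), M2 = "A"))
  reps <- representativeComponents(acs, GeneSet(c("A", "B", "C")))
  expect_equal(reps$molecule_id, "M1")
  expect_equal(reps$degree, 3L)

  # tie broken lexicographically, with a warning
  acsTie <- makeACS(list(H1 = c("M2", "M1")),
                    list(M1 = c("A", "B"), M2 = c("B", "C")))
  expect_warning(
    repsTie <- representativeComponents(acsTie, GeneSet(c("A", "B", "C"))),
    "tie")
  expect_equal(repsTie$molecule_id, "M1")

  # herb without hub-touching ingredients is omitted with a warning
  acsMiss <- makeACS(list(H1 = "M1", H2 = "M2"),
                     list(M1 = "A", M2 = "Z"))
  expect_warning(
    repsMiss <- representativeComponents(acsMiss, GeneSet("A")),
    "omitted.*H2")
  expect_equal(repsMiss$herb_id, "H1")
})

test_that("representative selection agrees with a brute-force degree recount", {
  set.seed(13)
  mols <- sprintf("M%02d", 1:12)
  herbComponents <- split(mols, rep(paste0("H", 1:3), each = 4))
  genes <- sprintf("G%02d", 1:30)
  componentTargets <- stats::setNames(
    lapply(mols, function(m) sort(sample(genes, sample(3:10, 1)))), mols)
  acs <- makeACS(herbComponents, componentTargets)
  hubs <- GeneSet(sample(genes, 15))
  reps <- suppressWarnings(representativeComponents(acs, hubs))
  for (i in seq_len(nrow(reps))) {
    h <- reps$herb_id[i]
    degs <- vapply(herbComponents[[h]], function(m)
      length(intersect(componentTargets[[m]], geneSymbols(hubs))),
      integer(1))
    expect_equal(reps$degree[i], max(degs))
    expect_equal(reps$molecule_id[i],
                 min(names(degs)[degs == max(degs)]))
  }
})
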