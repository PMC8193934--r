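test_that("closed-form values on K3, paths and stars", {
  k3 <- completeGraph(3)
  expect_equal(unname(degreeCentrality(k3)), rep(2, 3))
  expect_equal(unname(closenessCentrality(k3)), rep(1, 3))
  expect_equal(unname(eigenvectorCentrality(k3)), rep(1 / sqrt(3), 3),
               tolerance = 1e-9)
  expect_equal(unname(localAverageConnectivity(k3)), rep(1, 3))
  expect_equal(unname(networkCentrality(k3)), rep(2, 3))
  expect_equal(unname(betweennessCentrality(k3)), rep(0, 3))

  p3 <- pathGraph(c("a", "b", "c"))
  bc <- betweennessCentrality(p3)
  expect_equal(unname(bc[c("a", "b", "c")]), c(0, 1, 0))
  cc <- closenessCentrality(p3)
  expect_equal(unname(cc["b"]), 1)
  expect_equal(unname(cc["a"]), 2 / 3)
  expect_equal(unname(localAverageConnectivity(p3)["b"]), 0)

  s4 <- starGraph(3)  # hub + 3 leaves
  ec <- eigenvectorCentrality(s4)
  expect_equal(unname(ec["HUB"]), 1 / sqrt(2), tolerance = 1e-9)
  expect_equal(unname(ec["V1"]), 1 / sqrt(6), tolerance = 1e-9)
  expect_equal(unname(degreeCentrality(s4)["HUB"]), 3)
})

test_that("vertex-transitive graphs give constant feature vectors", {
  for (g in list(cycleGraph(5), completeGraph(6), cycleGraph(8))) {
    ct <- centralityTable(g)
    for (f in c("bc", "cc", "dc", "ec", "lac", "nc"))
      expect_lt(diff(range(slot(ct, f))), 1e-10)
  }
})

test_that("trees have zero network centrality (no triangles)", {
  tree <- PPIGraph(cbind(c("R", "R", "A", "A", "B"),
                         c("A", "B", "C", "D", "E")))
  expect_equal(unname(networkCentrality(tree)), rep(0, numNodes(tree)))
  expect_equal(unname(localAverageConnectivity(tree)),
               rep(0, numNodes(tree)))
})

test_that("clique-plus-pendant fixture matches hand-derived values", {
  g <- cliquePendantGraph(5)
  ct <- centralityTable(g)
  df <- as.data.frame(ct)
  clique <- df[startsWith(df$node, "C"), ]
  leaves <- df[startsWith(df$node, "L"), ]
  expect_equal(clique$bc, rep(8, 5))
  expect_equal(clique$dc, rep(5, 5))
  expect_equal(clique$lac, rep(2.4, 5))
  expect_equal(clique$nc, rep(3, 5))
  expect_equal(clique$cc, rep(9 / 13, 5))
  expect_equal(leaves$bc, rep(0, 5))
  expect_equal(leaves$dc, rep(1, 5))
  expect_equal(leaves$lac, rep(0, 5))
  expect_equal(leaves$nc, rep(0, 5))
  expect_equal(leaves$cc, rep(9 / 21, 5))
})

test_that("all six features match brute-force oracles on random graphs", {
  for (seed in 1:20) {
    g <- randomGraph(8, 0.35, seed = seed)
    expect_matches_oracles(g)
  }
  # denser and sparser regimes
  for (seed in 1:5) {
    expect_matches_oracles(randomGraph(10, 0.7, seed = seed))
    expect_matches_oracles(randomGraph(12, 0.15, seed = seed + 100))
  }
})

test_that("degree equals adjacency row sums and is monotone under edge addition", {
  g <- randomGraph(15, 0.2, seed = 2)
  expect_equal(unname(degreeCentrality(g)), unname(rowSums(adjMatrix(g))))
  dcBefore <- degreeCentrality(g)
  nodes <- nodeNames(g)
  A <- adjMatrix(g)
  cand <- which(A == 0 & upper.tri(A), arr.ind = TRUE)[1, ]
  pick <- c(rownames(A)[cand[1]], colnames(A)[cand[2]])
  g2 <- PPIGraph(rbind(edgeMatrix(g), pick), nodes = nodes)
  dcAfter <- degreeCentrality(g2)
  expect_equal(unname(dcAfter[pick]), unname(dcBefore[pick]) + 1)
  others <- setdiff(nodes, pick)
  expect_equal(dcAfter[others], dcBefore[others])
})

test_that("eigenvector centrality has unit norm, converges on bipartite graphs, errors without edges", {
  # even cycles and stars are bipartite: the shifted iteration must converge
  for (g in list(starGraph(5), cycleGraph(6), pathGraph(sprintf("p%d", 1:7)))) {
    ec <- eigenvectorCentrality(g)
    expect_equal(sum(ec^2), 1, tolerance = 1e-9)
    expect_true(all(ec >= 0))
    expect_equal_centrality(ec, oracleEC(g), tol = 1e-7)
  }
  empty <- PPIGraph(matrix(character(), ncol = 2), nodes = c("A", "B"))
  expect_error(eigenvectorCentrality(empty), "at least one edge")
})

test_that("betweenness and closeness respect the component-restricted conventions", {
  # two disjoint triangles: CC = 1 everywhere under the component convention
  g <- PPIGraph(rbind(t(utils::combn(c("A", "B", "C"), 2)),
                      t(utils::combn(c("X", "Y", "Z"), 2))))
  expect_equal(unname(closenessCentrality(g)), rep(1, 6))
  expect_equal(unname(betweennessCentrality(g)), rep(0, 6))
  # cross-component pairs contribute nothing on a disconnected random graph
  g2 <- randomGraph(14, 0.12, seed = 8)
  expect_equal_centrality(betweennessCentrality(g2), oracleBC(g2))
  expect_equal_centrality(closenessCentrality(g2), oracleCC(g2))
})

test_that("normalized betweenness rescales by the pair count", {
  g <- randomGraph(9, 0.4, seed = 6)
  raw <- betweennessCentrality(g)
  norm <- betweennessCentrality(g, normalized = TRUE)
  n <- numNodes(g)
  expect_equal(unname(norm), unname(raw) / ((n - 1) * (n - 2) / 2))
})
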