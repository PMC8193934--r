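# Graph fixtures and brute-force oracles, all independent of the package's
# centrality implementations: distances via Floyd-Warshall on the adjacency
# matrix, geodesic counts via matrix powers, eigenvectors via a dense
# eigen-decomposition, LAC/NC via literal matrix counting.

cliquePendantGraph <- function(k = 5L) {
  clique <- t(utils::combn(sprintf("C%d", seq_len(k)), 2L))
  pendant <- cbind(sprintf("C%d", seq_len(k)), sprintf("L%d", seq_len(k)))
  PPIGraph(rbind(clique, pendant))
}

pathGraph <- function(nodes) {
  PPIGraph(cbind(nodes[-length(nodes)], nodes[-1L]))
}

cycleGraph <- function(n) {
  nodes <- sprintf("V%d", seq_len(n))
  PPIGraph(cbind(nodes, c(nodes[-1L], nodes[1L])))
}

completeGraph <- function(n) {
  PPIGraph(t(utils::combn(sprintf("V%d", seq_len(n)), 2L)))
}

starGraph <- function(nLeaves) {
  PPIGraph(cbind("HUB", sprintf("V%d", seq_len(nLeaves))))
}

# G(n, p) random graph; connected = resample until one component
randomGraph <- function(n, p, seed, connected = FALSE) {
  set.seed(seed)
  repeat {
    pairs <- t(utils::combn(sprintf("N%02d", seq_len(n)), 2L))
    keep <- stats::runif(nrow(pairs)) < p
    if (!any(keep)) next
    g <- PPIGraph(pairs[keep, , drop = FALSE],
                  nodes = sprintf("N%02d", seq_len(n)))
    if (!connected || length(ppiComponents(g)) == 1L &&
        numNodes(g) == n) return(g)
  }
}

adjMatrix <- function(g) {
  nodes <- nodeNames(g)
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  em <- edgeMatrix(g)
  if (nrow(em)) {
    ia <- match(em[, 1L], nodes)
    ib <- match(em[, 2L], nodes)
    A[cbind(ia, ib)] <- 1
    A[cbind(ib, ia)] <- 1
  }
  A
}

floydWarshall <- function(A) {
  n <- nrow(A)
  D <- ifelse(A > 0, 1, Inf)
  diag(D) <- 0
  for (k in seq_len(n)) D <- pmin(D, outer(D[, k], D[k, ], `+`))
  D
}

oracleDC <- function(g) rowSums(adjMatrix(g))

oracleCC <- function(g) {
  A <- adjMatrix(g)
  D <- floydWarshall(A)
  vapply(seq_len(nrow(A)), function(v) {
    reach <- which(is.finite(D[v, ]))
    if (length(reach) <= 1L) return(0)
    (length(reach) - 1) / sum(D[v, reach])
  }, numeric(1)) |> stats::setNames(rownames(A))
}

# geodesic counting: the number of shortest s-t paths equals the number of
# walks of length d(s,t), i.e. (A^d)[s,t]
oracleBC <- function(g) {
  A <- adjMatrix(g)
  n <- nrow(A)
  D <- floydWarshall(A)
  maxd <- max(0, D[is.finite(D)])
  pow <- vector("list", maxd + 1L)
  pow[[1L]] <- diag(n)
  if (maxd >= 1) for (k in seq_len(maxd)) pow[[k + 1L]] <- pow[[k]] %*% A
  sig <- function(s, t) pow[[D[s, t] + 1L]][s, t]
  bc <- numeric(n)
  if (n >= 3L) {
    for (s in seq_len(n - 1L)) for (t in seq(s + 1L, n)) {
      if (!is.finite(D[s, t])) next
      st <- sig(s, t)
      for (v in seq_len(n)) {
        if (v == s || v == t) next
        if (is.finite(D[s, v]) && is.finite(D[v, t]) &&
            D[s, v] + D[v, t] == D[s, t])
          bc[v] <- bc[v] + sig(s, v) * sig(v, t) / st
      }
    }
  }
  stats::setNames(bc, rownames(A))
}

oracleEC <- function(g) {
  A <- adjMatrix(g)
  es <- eigen(A, symmetric = TRUE)
  v <- abs(es$vectors[, 1L])
  stats::setNames(v / sqrt(sum(v^2)), rownames(A))
}

oracleLAC <- function(g) {
  A <- adjMatrix(g)
  vapply(seq_len(nrow(A)), function(v) {
    nb <- which(A[v, ] > 0)
    if (!length(nb)) return(0)
    sub <- A[nb, nb, drop = FALSE]
    sum(sub) / length(nb)  # sum of induced degrees over neighborhood size
  }, numeric(1)) |> stats::setNames(rownames(A))
}

oracleNC <- function(g) {
  A <- adjMatrix(g)
  Z <- A %*% A  # common-neighbor counts
  deg <- rowSums(A)
  n <- nrow(A)
  nc <- numeric(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i || A[i, j] == 0) next
    den <- min(deg[i], deg[j]) - 1
    if (den > 0) {
      ecc <- Z[i, j] / den
      nc[i] <- nc[i] + ecc
      nc[j] <- nc[j] + ecc
    }
  }
  stats::setNames(nc, rownames(A))
}

# closed-form counting oracle for the hypergeometric upper tail
oracleHyper <- function(k, K, n, N) {
  js <- seq(k, min(K, n))
  if (!length(js)) return(0)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

expect_equal_centrality <- function(actual, expected, tol = 1e-8) {
  expect_equal(unname(actual[names(expected)]), unname(expected),
               tolerance = tol)
}

# all six features vs their oracles on one graph
expect_matches_oracles <- function(g, tol = 1e-8) {
  expect_equal_centrality(degreeCentrality(g), oracleDC(g), tol)
  expect_equal_centrality(betweennessCentrality(g), oracleBC(g), tol)
  expect_equal_centrality(closenessCentrality(g), oracleCC(g), tol)
  expect_equal_centrality(localAverageConnectivity(g), oracleLAC(g), tol)
  expect_equal_centrality(networkCentrality(g), oracleNC(g), tol)
  if (numEdges(g) > 0L && length(ppiComponents(g)) == 1L)
    expect_equal_centrality(eigenvectorCentrality(g), oracleEC(g), tol)
}

atlasGraph <- function(i) {
  ig <- igraph::graph_from_atlas(i)
  em <- igraph::as_edgelist(ig)
  n <- igraph::vcount(ig)
  PPIGraph(matrix(sprintf("V%d", em), ncol = 2L),
           nodes = sprintf("V%d", seq_len(n)))
}
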