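# The six node-centrality features used for hub extraction: betweenness
# (BC), closeness (CC), degree (DC), eigenvector (EC), local average
# connectivity (LAC) and network centrality (NC). Conventions follow the
# CytoNCA plugin: BC unnormalized (unordered path-pair units), DC a raw
# neighbor count, CC component-restricted in [0,1], EC the non-negative
# principal adjacency eigenvector at unit Euclidean norm.

#' Degree centrality
#'
#' \eqn{DC(v) = |N(v)|}, the raw neighbor count.
#'
#' @param g a \linkS4class{PPIGraph}.
#' @return named numeric vector over the graph's nodes.
#' @export
degreeCentrality <- function(g) {
  stopifnot(is(g, "PPIGraph"))
  stats::setNames(as.numeric(lengths(.adjList(g))), g@nodes)
}

#' Betweenness centrality (unnormalized)
#'
#' \eqn{BC(v) = \sum_{\{s,t\}, s \ne v \ne t} \sigma_{st}(v)/\sigma_{st}}
#' over unordered pairs, where \eqn{\sigma_{st}} counts shortest s-t paths.
#' Computed with Brandes' dependency-accumulation algorithm (one BFS per
#' source); pairs in different components contribute nothing.
#'
#' @param g a \linkS4class{PPIGraph}.
#' @param normalized divide by \eqn{(n-1)(n-2)/2}; default FALSE (raw scale).
#' @return named numeric vector.
#' @export
betweennessCentrality <- function(g, normalized = FALSE) {
  stopifnot(is(g, "PPIGraph"))
  adj <- .adjList(g)
  n <- numNodes(g)
  bc <- numeric(n)
  for (s in seq_len(n)) {
    sigma <- numeric(n); sigma[s] <- 1
    dist <- rep(-1L, n); dist[s] <- 0L
    preds <- vector("list", n)
    queue <- integer(n); queue[1L] <- s
    head <- 1L; tail <- 1L
    while (head <= tail) {
      v <- queue[head]; head <- head + 1L
      dv <- dist[v]
      for (w in adj[[v]]) {
        if (dist[w] < 0L) {
          tail <- tail + 1L
          queue[tail] <- w
          dist[w] <- dv + 1L
        }
        if (dist[w] == dv + 1L) {
          sigma[w] <- sigma[w] + sigma[v]
          preds[[w]] <- c(preds[[w]], v)
        }
      }
    }
    delta <- numeric(n)
    for (i in seq(tail, 1L)) {
      v <- queue[i]
      coef <- (1 + delta[v]) / sigma[v]
      for (p in preds[[v]]) delta[p] <- delta[p] + sigma[p] * coef
      if (v != s) bc[v] <- bc[v] + delta[v]
    }
  }
  bc <- bc / 2
  if (normalized && n > 2L) bc <- bc / ((n - 1) * (n - 2) / 2)
  stats::setNames(bc, g@nodes)
}

#' Closeness centrality (component-restricted)
#'
#' \eqn{CC(v) = (|C_v| - 1) / \sum_{u \in C_v} d(v, u)} within v's connected
#' component \eqn{C_v}; isolated nodes get 0. Values lie in [0, 1], with 1
#' for a node adjacent to every other node of its component.
#'
#' @param g a \linkS4class{PPIGraph}.
#' @return named numeric vector.
#' @export
closenessCentrality <- function(g) {
  stopifnot(is(g, "PPIGraph"))
  adj <- .adjList(g)
  n <- numNodes(g)
  cc <- numeric(n)
  for (s in seq_len(n)) {
    dist <- rep(-1L, n); dist[s] <- 0L
    queue <- integer(n); queue[1L] <- s
    head <- 1L; tail <- 1L
    total <- 0L
    while (head <= tail) {
      v <- queue[head]; head <- head + 1L
      for (w in adj[[v]]) {
        if (dist[w] < 0L) {
          dist[w] <- dist[v] + 1L
          total <- total + dist[w]
          tail <- tail + 1L
          queue[tail] <- w
        }
      }
    }
    cc[s] <- if (tail > 1L) (tail - 1) / total else 0
  }
  stats::setNames(cc, g@nodes)
}

#' Eigenvector centrality
#'
#' The non-negative principal eigenvector of the adjacency matrix, scaled to
#' unit Euclidean norm. Computed by power iteration on the shifted operator
#' \eqn{A + I} starting from the uniform positive vector: the shift leaves
#' the eigenvectors unchanged but makes the Perron eigenvalue strictly
#' dominant, so bipartite graphs (stars, paths, even cycles) converge too.
#' Convergence is declared when successive normalized iterates differ by
#' less than \code{tol} in max-norm.
#'
#' @param g a \linkS4class{PPIGraph} with at least one edge.
#' @param tol convergence tolerance (max-norm), default 1e-10.
#' @param maxIter iteration cap, default 10000.
#' @return named numeric vector, non-negative, \eqn{\sum EC^2 = 1}.
#' @export
eigenvectorCentrality <- function(g, tol = 1e-10, maxIter = 10000L) {
  stopifnot(is(g, "PPIGraph"))
  if (!numEdges(g))
    stop("eigenvector centrality needs a graph with at least one edge",
         call. = FALSE)
  adj <- .adjList(g)
  n <- numNodes(g)
  x <- rep(1 / sqrt(n), n)
  converged <- FALSE
  for (iter in seq_len(maxIter)) {
    y <- x + vapply(adj, function(nb) sum(x[nb]), numeric(1))
    y <- y / sqrt(sum(y * y))
    if (max(abs(y - x)) < tol) {
      x <- y
      converged <- TRUE
      break
    }
    x <- y
  }
  if (!converged)
    stop("eigenvector centrality did not converge after ", maxIter,
         " iterations", call. = FALSE)
  x <- pmax(x, 0)
  x <- x / sqrt(sum(x * x))
  stats::setNames(x, g@nodes)
}

#' Local average connectivity
#'
#' \eqn{LAC(v)} is the mean degree of v's neighbors within the subgraph
#' induced by those neighbors (v itself excluded): a local density measure.
#' Isolated nodes get 0; a node whose neighbors are pairwise non-adjacent
#' also gets 0.
#'
#' @param g a \linkS4class{PPIGraph}.
#' @return named numeric vector.
#' @export
localAverageConnectivity <- function(g) {
  stopifnot(is(g, "PPIGraph"))
  adj <- .adjList(g)
  n <- numNodes(g)
  lac <- vapply(seq_len(n), function(v) {
    nb <- adj[[v]]
    if (!length(nb)) return(0)
    inside <- vapply(nb, function(w) length(intersect(adj[[w]], nb)),
                     integer(1))
    sum(inside) / length(nb)
  }, numeric(1))
  stats::setNames(lac, g@nodes)
}

#' Network centrality (summed edge clustering coefficients)
#'
#' \eqn{NC(v) = \sum_{u \in N(v)} ECC(v, u)} with the edge clustering
#' coefficient \eqn{ECC(v,u) = z_{vu} / \min(d_v - 1, d_u - 1)}, where
#' \eqn{z_{vu}} is the number of common neighbors of v and u (triangles
#' through the edge). When the denominator is 0 (an endpoint of degree 1)
#' the ECC is defined as 0.
#'
#' @param g a \linkS4class{PPIGraph}.
#' @return named numeric vector.
#' @export
networkCentrality <- function(g) {
  stopifnot(is(g, "PPIGraph"))
  adj <- .adjList(g)
  n <- numNodes(g)
  deg <- lengths(adj)
  nc <- numeric(n)
  if (nrow(g@edges)) {
    ia <- match(g@edges[, 1L], g@nodes)
    ib <- match(g@edges[, 2L], g@nodes)
    for (k in seq_along(ia)) {
      i <- ia[k]; j <- ib[k]
      den <- min(deg[i], deg[j]) - 1L
      if (den > 0L) {
        z <- length(intersect(adj[[i]], adj[[j]]))
        if (z) {
          ecc <- z / den
          nc[i] <- nc[i] + ecc
          nc[j] <- nc[j] + ecc
        }
      }
    }
  }
  stats::setNames(nc, g@nodes)
}

#' Compute all six centrality features of a graph
#'
#' Runs BC, CC, DC, EC, LAC and NC in one pass and reports the per-feature
#' medians as a message.
#'
#' @param g a \linkS4class{PPIGraph} with at least one edge.
#' @param verbose emit the median report message (default FALSE).
#' @return a \linkS4class{CentralityTable}.
#' @export
centralityTable <- function(g, verbose = FALSE) {
  stopifnot(is(g, "PPIGraph"))
  ct <- new("CentralityTable", nodes = g@nodes,
            bc = unname(betweennessCentrality(g)),
            cc = unname(closenessCentrality(g)),
            dc = unname(degreeCentrality(g)),
            ec = unname(eigenvectorCentrality(g)),
            lac = unname(localAverageConnectivity(g)),
            nc = unname(networkCentrality(g)))
  if (verbose) {
    m <- featureMedians(ct)
    message("centrality medians: ",
            paste(sprintf("%s=%.6g", names(m), m), collapse = " "))
  }
  ct
}
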