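# PPI graph construction and the graph contract used by the centrality
# engine.

#' Build the analysis PPI graph
#'
#' Induces the confidence-thresholded edge list on the putative target set
#' and removes isolated nodes, giving the "full PPI network without
#' disconnected nodes" the hub-extraction stage operates on. Removal counts
#' are logged as messages.
#'
#' @param edges thresholded edge list data.frame (see
#'   \code{\link{readWeightedEdges}}).
#' @param restrictTo \linkS4class{GeneSet} or character vector of node
#'   symbols to induce on; \code{NULL} keeps all endpoints.
#' @return a \linkS4class{PPIGraph}.
#' @export
buildPPI <- function(edges, restrictTo = NULL) {
  stopifnot(is.data.frame(edges), ncol(edges) >= 3L)
  a <- toupper(as.character(edges[[1L]]))
  b <- toupper(as.character(edges[[2L]]))
  w <- as.numeric(edges[[3L]])
  if (!is.null(restrictTo)) {
    allowed <- if (is(restrictTo, "GeneSet")) geneSymbols(restrictTo)
      else toupper(as.character(restrictTo))
    keep <- a %in% allowed & b %in% allowed
    dropped <- sum(!keep)
    if (dropped)
      message("buildPPI: dropped ", dropped,
              " edge(s) outside the restriction set")
    a <- a[keep]; b <- b[keep]; w <- w[keep]
    isolated <- setdiff(allowed, c(a, b))
    if (length(isolated))
      message("buildPPI: ", length(isolated),
              " restriction gene(s) end up isolated and are removed")
  }
  if (!length(a))
    stop("empty PPI graph: no edge survives the restriction", call. = FALSE)
  PPIGraph(cbind(a, b), weights = w)
}

# adjacency list of integer neighbor indices, in node order
.adjList <- function(g) {
  n <- length(g@nodes)
  if (!nrow(g@edges))
    return(rep(list(integer()), n))
  ia <- match(g@edges[, 1L], g@nodes)
  ib <- match(g@edges[, 2L], g@nodes)
  adj <- split(c(ib, ia), factor(c(ia, ib), levels = seq_len(n)))
  unname(lapply(adj, function(x) sort(unname(x))))
}

#' Connected components of a PPI graph
#'
#' Breadth-first labelling; returns the partition of the node set by
#' reachability.
#'
#' @param g a \linkS4class{PPIGraph}.
#' @return list of character vectors (sorted node names), largest first.
#' @export
ppiComponents <- function(g) {
  stopifnot(is(g, "PPIGraph"))
  n <- numNodes(g)
  if (!n) return(list())
  adj <- .adjList(g)
  label <- integer(n)
  comp <- 0L
  for (s in seq_len(n)) {
    if (label[s]) next
    comp <- comp + 1L
    queue <- s
    label[s] <- comp
    head <- 1L
    while (head <= length(queue)) {
      v <- queue[head]; head <- head + 1L
      for (w in adj[[v]]) {
        if (!label[w]) {
          label[w] <- comp
          queue <- c(queue, w)
        }
      }
    }
  }
  parts <- split(g@nodes, label)
  parts <- lapply(parts, sort)
  parts[order(-lengths(parts))]
}

#' Induced subgraph on a node subset
#'
#' @param g a \linkS4class{PPIGraph}.
#' @param nodes character vector of nodes to keep.
#' @param dropIsolated drop nodes left without edges (default TRUE, matching
#'   the no-disconnected-nodes convention of the analysis graph).
#' @return a \linkS4class{PPIGraph}.
#' @export
induceSubgraph <- function(g, nodes, dropIsolated = TRUE) {
  stopifnot(is(g, "PPIGraph"))
  nodes <- intersect(g@nodes, nodes)
  keep <- g@edges[, 1L] %in% nodes & g@edges[, 2L] %in% nodes
  edges <- g@edges[keep, , drop = FALSE]
  w <- g@weights[keep]
  nodeSet <- if (dropIsolated) sort(unique(c(edges))) else sort(nodes)
  new("PPIGraph", nodes = nodeSet, edges = edges, weights = w)
}
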