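# Iterative above-median multi-feature filtering: the hub-gene extraction
# procedure. Each round computes the six centralities on the current graph,
# keeps the nodes strictly exceeding every feature's median, and induces the
# subgraph on them (dropping nodes the deletions isolated). Two rounds is
# the published protocol.

#' One round of the above-median centrality filter
#'
#' Computes the \linkS4class{CentralityTable} of \code{g}, takes each
#' feature's median over the current nodes (even counts use the midpoint of
#' the two central order statistics) and retains the nodes whose value
#' strictly exceeds the median for at least \code{minFeatures} of the six
#' features (default: all six, the conjunctive rule). The returned graph is
#' the induced subgraph on the retained nodes with isolated nodes removed.
#'
#' @param g a non-empty \linkS4class{PPIGraph}.
#' @param minFeatures how many of the six medians must be strictly exceeded
#'   (default 6 = all).
#' @return list with \code{report} (round report: \code{nIn},
#'   \code{medians}, \code{retained}, \code{nOut}) and \code{graph} (the
#'   filtered \linkS4class{PPIGraph}; possibly empty).
#' @export
medianFilterRound <- function(g, minFeatures = 6L) {
  stopifnot(is(g, "PPIGraph"), numNodes(g) > 0L,
            minFeatures >= 1L, minFeatures <= 6L)
  ct <- centralityTable(g)
  med <- featureMedians(ct)
  vals <- cbind(bc = ct@bc, cc = ct@cc, dc = ct@dc,
                ec = ct@ec, lac = ct@lac, nc = ct@nc)
  exceeds <- sweep(vals, 2L, med[colnames(vals)], ">")
  retained <- ct@nodes[rowSums(exceeds) >= minFeatures]
  sub <- induceSubgraph(g, retained, dropIsolated = TRUE)
  report <- list(nIn = numNodes(g), medians = med,
                 retained = retained, nOut = numNodes(sub))
  list(report = report, graph = sub)
}

#' Extract hub genes by iterated above-median filtering
#'
#' Applies \code{\link{medianFilterRound}} up to \code{rounds} times
#' (centralities are recomputed on each round's induced subgraph). If a
#' round would leave no node — e.g. a fully symmetric graph, where no node
#' can strictly exceed the median of a constant feature — iteration stops
#' and the previous round's node set is returned with stop reason
#' \code{"would_empty"}. If a round retains every node, iteration stops with
#' \code{"converged"}. Otherwise the stop reason is \code{"completed"}.
#'
#' @param g a non-empty \linkS4class{PPIGraph}.
#' @param rounds number of filter rounds (default 2, the published
#'   protocol); 0 returns the input node set unchanged.
#' @param minFeatures passed to \code{\link{medianFilterRound}}.
#' @return list with \code{hubs} (a \linkS4class{GeneSet} named
#'   \code{"hub_genes"}), \code{graph} (the final subnetwork),
#'   \code{reports} (one per executed round, each with the round index,
#'   input size, six medians, retained nodes and output size) and
#'   \code{stopReason}.
#' @export
extractHubs <- function(g, rounds = 2L, minFeatures = 6L) {
  stopifnot(is(g, "PPIGraph"), rounds >= 0L)
  if (!numNodes(g)) stop("empty input graph", call. = FALSE)
  current <- g
  reports <- list()
  stopReason <- "completed"
  for (r in seq_len(rounds)) {
    res <- medianFilterRound(current, minFeatures = minFeatures)
    res$report$round <- r
    reports[[r]] <- res$report
    if (numNodes(res$graph) == 0L) {
      stopReason <- "would_empty"
      break
    }
    if (numNodes(res$graph) == numNodes(current)) {
      current <- res$graph
      stopReason <- "converged"
      break
    }
    current <- res$graph
  }
  list(hubs = GeneSet(nodeNames(current), name = "hub_genes"),
       graph = current, reports = reports, stopReason = stopReason)
}

#' Per-round filter report as a data.frame
#'
#' One row per executed round with the input size, the six feature medians
#' and the output size — the tabular form of the per-round median vectors.
#'
#' @param reports the \code{reports} element of \code{\link{extractHubs}}.
#' @return data.frame with columns round, n_in, median_bc, median_cc,
#'   median_dc, median_ec, median_lac, median_nc, n_out.
#' @export
filterReportTable <- function(reports) {
  if (!length(reports))
    return(data.frame(round = integer(), n_in = integer(),
                      median_bc = numeric(), median_cc = numeric(),
                      median_dc = numeric(), median_ec = numeric(),
                      median_lac = numeric(), median_nc = numeric(),
                      n_out = integer()))
  do.call(rbind, lapply(reports, function(r)
    data.frame(round = r$round, n_in = r$nIn,
               median_bc = r$medians[["bc"]], median_cc = r$medians[["cc"]],
               median_dc = r$medians[["dc"]], median_ec = r$medians[["ec"]],
               median_lac = r$medians[["lac"]],
               median_nc = r$medians[["nc"]],
               n_out = r$nOut)))
}
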