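#' @rdname GeneSet
#' @export
setMethod("geneSymbols", "GeneSet", function(x) x@symbols)

#' @rdname GeneSet
#' @export
setMethod("geneSetName", "GeneSet", function(x) x@name)

#' @rdname GeneSet
#' @export
setMethod("geneSources", "GeneSet", function(x) x@sources)

#' @rdname GeneSet
#' @export
setMethod("provenance", "GeneSet", function(x) x@provenance)

#' @rdname GeneSet
#' @export
setMethod("length", "GeneSet", function(x) length(x@symbols))

setMethod("show", "GeneSet", function(object) {
  cat(sprintf("GeneSet '%s': %d symbols", object@name, length(object@symbols)))
  if (length(object@sources))
    cat(sprintf(" [sources: %s]", paste(object@sources, collapse = ", ")))
  cat("\n")
  if (length(object@symbols)) {
    head <- utils::head(object@symbols, 6L)
    cat("  ", paste(head, collapse = " "),
        if (length(object@symbols) > 6L) "..." else "", "\n")
  }
})

#' @rdname PPIGraph
#' @export
setMethod("nodeNames", "PPIGraph", function(x) x@nodes)

#' @rdname PPIGraph
#' @export
setMethod("numNodes", "PPIGraph", function(x) length(x@nodes))

#' @rdname PPIGraph
#' @export
setMethod("numEdges", "PPIGraph", function(x) nrow(x@edges))

#' @rdname PPIGraph
#' @export
setMethod("edgeMatrix", "PPIGraph", function(x) x@edges)

#' @rdname PPIGraph
#' @export
setMethod("edgeWeights", "PPIGraph", function(x) x@weights)

setMethod("show", "PPIGraph", function(object) {
  cat(sprintf("PPIGraph: %d nodes, %d edges\n",
              length(object@nodes), nrow(object@edges)))
})

#' @rdname TripartiteNetwork
#' @export
setMethod("herbNodes", "TripartiteNetwork", function(x) x@herbs)

#' @rdname TripartiteNetwork
#' @export
setMethod("ingredientNodes", "TripartiteNetwork", function(x) x@ingredients)

#' @rdname TripartiteNetwork
#' @export
setMethod("geneNodes", "TripartiteNetwork", function(x) x@genes)

setMethod("show", "TripartiteNetwork", function(object) {
  cat(sprintf(
    "TripartiteNetwork: %d herbs, %d ingredients, %d genes; %d + %d edges\n",
    length(object@herbs), length(object@ingredients), length(object@genes),
    nrow(object@herbEdges), nrow(object@targetEdges)))
})

#' @rdname featureMedians
#' @export
setMethod("featureMedians", "CentralityTable", function(x) {
  c(bc = stats::median(x@bc), cc = stats::median(x@cc),
    dc = stats::median(x@dc), ec = stats::median(x@ec),
    lac = stats::median(x@lac), nc = stats::median(x@nc))
})

#' Convert a CentralityTable to a data.frame
#'
#' @param x a \linkS4class{CentralityTable}.
#' @param row.names,optional,... ignored; present for generic consistency.
#' @return data.frame with columns node, bc, cc, dc, ec, lac, nc.
#' @export
as.data.frame.CentralityTable <- function(x, row.names = NULL,
                                          optional = FALSE, ...) {
  data.frame(node = x@nodes, bc = x@bc, cc = x@cc, dc = x@dc,
             ec = x@ec, lac = x@lac, nc = x@nc,
             stringsAsFactors = FALSE)
}

setMethod("show", "CentralityTable", function(object) {
  cat(sprintf("CentralityTable: %d nodes\n", length(object@nodes)))
  m <- featureMedians(object)
  cat("  medians:",
      paste(sprintf("%s=%.4g", names(m), m), collapse = " "), "\n")
})

#' @rdname AnnotationSet
#' @export
setMethod("termIds", "AnnotationSet", function(x) x@termId)

#' @rdname AnnotationSet
#' @export
setMethod("termNames", "AnnotationSet", function(x) x@termName)

#' @rdname AnnotationSet
#' @export
setMethod("termNamespaces", "AnnotationSet", function(x) x@namespace)

#' @rdname AnnotationSet
#' @export
setMethod("termGenes", "AnnotationSet", function(x)
  stats::setNames(x@genes, x@termId))

#' @rdname AnnotationSet
#' @export
setMethod("length", "AnnotationSet", function(x) length(x@termId))

setMethod("show", "AnnotationSet", function(object) {
  cat(sprintf("AnnotationSet: %d terms (%s)\n", length(object@termId),
              paste(sprintf("%s: %d", names(table(object@namespace)),
                            table(object@namespace)), collapse = ", ")))
})

#' @rdname ActiveComponentSet
#' @export
setMethod("targetUnion", "ActiveComponentSet", function(x) x@unionTargets)

#' @rdname ActiveComponentSet
#' @export
setMethod("herbComponents", "ActiveComponentSet", function(x) x@herbComponents)

#' @rdname ActiveComponentSet
#' @export
setMethod("componentTargets", "ActiveComponentSet",
          function(x) x@componentTargets)

#' @rdname ActiveComponentSet
#' @export
setMethod("flaggedComponents", "ActiveComponentSet", function(x) x@flagged)

setMethod("show", "ActiveComponentSet", function(object) {
  cat(sprintf(
    "ActiveComponentSet: %d herbs, %d components (%d flagged), %d target genes\n",
    length(object@herbComponents),
    length(object@componentTargets), length(object@flagged),
    length(object@unionTargets)))
})

#' @rdname asIgraph
#' @export
setMethod("asIgraph", "PPIGraph", function(x) {
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(x@nodes), name = x@nodes)
  if (nrow(x@edges)) {
    idx <- rbind(match(x@edges[, 1L], x@nodes), match(x@edges[, 2L], x@nodes))
    g <- igraph::add_edges(g, as.vector(idx), weight = x@weights)
  }
  g
})

#' @rdname asIgraph
#' @export
setMethod("asIgraph", "TripartiteNetwork", function(x) {
  nodes <- c(x@herbs, x@ingredients, x@genes)
  part <- c(rep("herb", length(x@herbs)),
            rep("ingredient", length(x@ingredients)),
            rep("gene", length(x@genes)))
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(nodes), name = nodes, partition = part)
  he <- x@herbEdges
  te <- x@targetEdges
  em <- rbind(he, te)
  if (nrow(em)) {
    idx <- rbind(match(em[, 1L], nodes), match(em[, 2L], nodes))
    type <- c(rep("contains", nrow(he)), rep("targets", nrow(te)))
    g <- igraph::add_edges(g, as.vector(idx), type = type)
  }
  g
})
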