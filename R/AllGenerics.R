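#' @rdname GeneSet
#' @param x,object a GeneSet
#' @export
setGeneric("geneSymbols", function(x) standardGeneric("geneSymbols"))

#' @rdname GeneSet
#' @export
setGeneric("geneSetName", function(x) standardGeneric("geneSetName"))

#' @rdname GeneSet
#' @export
setGeneric("geneSources", function(x) standardGeneric("geneSources"))

#' @rdname GeneSet
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname PPIGraph
#' @param x,object a PPIGraph
#' @export
setGeneric("nodeNames", function(x) standardGeneric("nodeNames"))

#' @rdname PPIGraph
#' @export
setGeneric("numNodes", function(x) standardGeneric("numNodes"))

#' @rdname PPIGraph
#' @export
setGeneric("numEdges", function(x) standardGeneric("numEdges"))

#' @rdname PPIGraph
#' @export
setGeneric("edgeMatrix", function(x) standardGeneric("edgeMatrix"))

#' @rdname PPIGraph
#' @export
setGeneric("edgeWeights", function(x) standardGeneric("edgeWeights"))

#' Coerce a package object to an igraph graph
#'
#' Used for export (GraphML) and for independent cross-checks; the analysis
#' itself runs on the package's own structures.
#'
#' @param x a \linkS4class{PPIGraph} or \linkS4class{TripartiteNetwork}.
#' @return an \pkg{igraph} graph.
#' @export
setGeneric("asIgraph", function(x) standardGeneric("asIgraph"))

#' @rdname TripartiteNetwork
#' @param x,object a TripartiteNetwork
#' @export
setGeneric("herbNodes", function(x) standardGeneric("herbNodes"))

#' @rdname TripartiteNetwork
#' @export
setGeneric("ingredientNodes", function(x) standardGeneric("ingredientNodes"))

#' @rdname TripartiteNetwork
#' @export
setGeneric("geneNodes", function(x) standardGeneric("geneNodes"))

#' Per-feature medians of a centrality table
#'
#' @param x a \linkS4class{CentralityTable}.
#' @return named numeric vector with elements bc, cc, dc, ec, lac, nc; the
#'   median of an even-length feature is the midpoint of the two central
#'   order statistics.
#' @export
setGeneric("featureMedians", function(x) standardGeneric("featureMedians"))

#' @rdname AnnotationSet
#' @param x,object an AnnotationSet
#' @export
setGeneric("termIds", function(x) standardGeneric("termIds"))

#' @rdname AnnotationSet
#' @export
setGeneric("termNames", function(x) standardGeneric("termNames"))

#' @rdname AnnotationSet
#' @export
setGeneric("termNamespaces", function(x) standardGeneric("termNamespaces"))

#' @rdname AnnotationSet
#' @export
setGeneric("termGenes", function(x) standardGeneric("termGenes"))

#' @rdname ActiveComponentSet
#' @param x,object an ActiveComponentSet
#' @export
setGeneric("targetUnion", function(x) standardGeneric("targetUnion"))

#' @rdname ActiveComponentSet
#' @export
setGeneric("herbComponents", function(x) standardGeneric("herbComponents"))

#' @rdname ActiveComponentSet
#' @export
setGeneric("componentTargets", function(x) standardGeneric("componentTargets"))

#' @rdname ActiveComponentSet
#' @export
setGeneric("flaggedComponents", function(x) standardGeneric("flaggedComponents"))
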