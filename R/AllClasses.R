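#' @import methods
NULL

#' GeneSet: a named, deduplicated set of uppercase gene symbols
#'
#' The unit of all set algebra in the pipeline. Symbols are uppercased and
#' deduplicated on construction; each symbol can carry provenance (which
#' source lists contributed it), so a merged disease set can be partitioned
#' back into its Venn regions without re-reading the inputs.
#'
#' @slot name label for the set (e.g. \code{"putative_targets"}).
#' @slot symbols character vector of unique uppercase gene symbols.
#' @slot sources labels of the source lists that contributed to the set.
#' @slot provenance named list mapping a symbol to the character vector of
#'   source labels it was seen in. May be empty when provenance is unknown.
#'
#' @exportClass GeneSet
setClass("GeneSet",
  representation(
    name = "character",
    symbols = "character",
    sources = "character",
    provenance = "list"
  ),
  prototype(name = "", symbols = character(), sources = character(),
            provenance = list())
)

setValidity("GeneSet", function(object) {
  msg <- character()
  s <- object@symbols
  if (anyNA(s)) msg <- c(msg, "symbols must not contain NA")
  if (any(duplicated(s))) msg <- c(msg, "symbols must be unique")
  if (length(s) && !identical(s, toupper(s)))
    msg <- c(msg, "symbols must be uppercase")
  if (length(s) && any(!nzchar(s))) msg <- c(msg, "symbols must be non-empty")
  if (length(object@provenance) &&
      !all(names(object@provenance) %in% s))
    msg <- c(msg, "provenance names must be a subset of symbols")
  if (length(msg)) msg else TRUE
})

#' Construct a GeneSet
#'
#' Symbols are whitespace-trimmed, uppercased and deduplicated. When a single
#' source label is given, every symbol is attributed to it.
#'
#' @param symbols character vector of gene symbols (any case).
#' @param name set label.
#' @param sources character vector of source labels.
#' @param provenance optional named list symbol -> contributing sources;
#'   computed automatically for a single source.
#' @return a \linkS4class{GeneSet}.
#' @examples
#' gs <- GeneSet(c("tnf", "TNF", "Il6"), name = "demo", sources = "manual")
#' geneSymbols(gs)
#' @export
GeneSet <- function(symbols = character(), name = "", sources = character(),
                    provenance = NULL) {
  symbols <- toupper(trimws(as.character(symbols)))
  symbols <- unique(symbols[nzchar(symbols) & !is.na(symbols)])
  if (is.null(provenance)) {
    provenance <- if (length(sources) == 1L && length(symbols))
      stats::setNames(rep(list(sources), length(symbols)), symbols)
    else list()
  }
  new("GeneSet", name = as.character(name), symbols = symbols,
      sources = as.character(sources), provenance = provenance)
}

#' PPIGraph: a simple undirected weighted graph over gene symbols
#'
#' Substrate of the centrality engine. Self-loops and parallel edges are
#' removed on construction (the maximum confidence is kept for duplicated
#' unordered pairs). Node order is the canonical (sorted) symbol order.
#'
#' @slot nodes character vector of node names (gene symbols).
#' @slot edges two-column character matrix; each row one undirected edge,
#'   endpoints stored in sorted order.
#' @slot weights numeric edge confidences, parallel to rows of \code{edges}.
#'
#' @exportClass PPIGraph
setClass("PPIGraph",
  representation(nodes = "character", edges = "matrix", weights = "numeric"),
  prototype(nodes = character(),
            edges = matrix(character(), ncol = 2L), weights = numeric())
)

setValidity("PPIGraph", function(object) {
  msg <- character()
  e <- object@edges
  if (ncol(e) != 2L) msg <- c(msg, "edges must have two columns")
  if (nrow(e)) {
    if (!all(c(e) %in% object@nodes))
      msg <- c(msg, "edge endpoints must be listed in nodes")
    if (any(e[, 1L] == e[, 2L])) msg <- c(msg, "self-loops are not allowed")
    key <- paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]), sep = "\r")
    if (any(duplicated(key))) msg <- c(msg, "parallel edges are not allowed")
  }
  if (length(object@weights) != nrow(e))
    msg <- c(msg, "one weight per edge required")
  if (any(duplicated(object@nodes))) msg <- c(msg, "duplicate node names")
  if (length(msg)) msg else TRUE
})

#' Construct a PPIGraph
#'
#' @param edges two-column character matrix or data.frame of endpoints, or a
#'   \code{WeightedEdgeList} data.frame as returned by
#'   \code{\link{readWeightedEdges}} (first two columns endpoints, third
#'   scores).
#' @param weights numeric edge confidences; defaults to the third column of
#'   \code{edges} when present, else 1.
#' @param nodes optional node universe; defaults to the edge endpoints.
#'   Extra names yield isolated nodes (dropped by \code{\link{buildPPI}}, but
#'   representable here).
#' @return a \linkS4class{PPIGraph}.
#' @examples
#' g <- PPIGraph(cbind(c("A", "B"), c("B", "C")))
#' numEdges(g)
#' @export
PPIGraph <- function(edges, weights = NULL, nodes = NULL) {
  if (is.data.frame(edges)) {
    if (is.null(weights) && ncol(edges) >= 3L) weights <- as.numeric(edges[[3L]])
    edges <- cbind(as.character(edges[[1L]]), as.character(edges[[2L]]))
  }
  edges <- matrix(as.character(edges), ncol = 2L)
  if (is.null(weights)) weights <- rep(1, nrow(edges))
  keep <- edges[, 1L] != edges[, 2L]
  edges <- edges[keep, , drop = FALSE]
  weights <- weights[keep]
  if (nrow(edges)) {
    a <- pmin(edges[, 1L], edges[, 2L])
    b <- pmax(edges[, 1L], edges[, 2L])
    key <- paste(a, b, sep = "\r")
    ord <- order(key, -weights)
    first <- !duplicated(key[ord])
    sel <- ord[first]
    edges <- cbind(a[sel], b[sel])
    weights <- weights[sel]
  }
  if (is.null(nodes)) nodes <- sort(unique(c(edges)))
  else nodes <- sort(unique(as.character(nodes)))
  new("PPIGraph", nodes = nodes, edges = edges, weights = as.numeric(weights))
}

#' TripartiteNetwork: herb-ingredient-target network
#'
#' Herbs are linked to the ingredients they contain and ingredients to the
#' genes they target; the tripartite constraint (no herb-gene, herb-herb,
#' ingredient-ingredient or gene-gene edges) is enforced by construction and
#' validity. One ingredient node may be shared by several herbs.
#'
#' @slot herbs,ingredients,genes character vectors naming each partition.
#' @slot herbEdges two-column character matrix (herb, ingredient).
#' @slot targetEdges two-column character matrix (ingredient, gene).
#'
#' @exportClass TripartiteNetwork
setClass("TripartiteNetwork",
  representation(
    herbs = "character", ingredients = "character", genes = "character",
    herbEdges = "matrix", targetEdges = "matrix"
  )
)

setValidity("TripartiteNetwork", function(object) {
  msg <- character()
  all3 <- c(object@herbs, object@ingredients, object@genes)
  if (any(duplicated(all3)))
    msg <- c(msg, "partition labels must be pairwise disjoint")
  he <- object@herbEdges
  te <- object@targetEdges
  if (nrow(he)) {
    if (!all(he[, 1L] %in% object@herbs) ||
        !all(he[, 2L] %in% object@ingredients))
      msg <- c(msg, "herb edges must link a herb to an ingredient")
  }
  if (nrow(te)) {
    if (!all(te[, 1L] %in% object@ingredients) ||
        !all(te[, 2L] %in% object@genes))
      msg <- c(msg, "target edges must link an ingredient to a gene")
  }
  if (!all(object@ingredients %in% he[, 2L]))
    msg <- c(msg, "orphan ingredient: every ingredient needs a herb link")
  if (length(msg)) msg else TRUE
})

#' CentralityTable: the six per-node centrality features of one graph
#'
#' Holds betweenness (bc, unnormalized pair units), closeness (cc, in [0,1],
#' component-restricted), degree (dc, raw counts), eigenvector (ec, unit
#' Euclidean norm, non-negative), local average connectivity (lac) and
#' network centrality (nc, summed edge clustering coefficients) for one
#' graph snapshot.
#'
#' @slot nodes node names.
#' @slot bc,cc,dc,ec,lac,nc numeric vectors parallel to \code{nodes}.
#'
#' @exportClass CentralityTable
setClass("CentralityTable",
  representation(
    nodes = "character",
    bc = "numeric", cc = "numeric", dc = "numeric",
    ec = "numeric", lac = "numeric", nc = "numeric"
  )
)

setValidity("CentralityTable", function(object) {
  msg <- character()
  n <- length(object@nodes)
  for (f in c("bc", "cc", "dc", "ec", "lac", "nc")) {
    v <- slot(object, f)
    if (length(v) != n) msg <- c(msg, sprintf("%s must have one value per node", f))
    if (length(v) && (anyNA(v) || any(!is.finite(v)) || any(v < 0)))
      msg <- c(msg, sprintf("%s must be finite and non-negative", f))
  }
  if (length(msg)) msg else TRUE
})

#' AnnotationSet: GO/KEGG-style term membership
#'
#' A collection of annotation terms (as read from a GMT file), each with a
#' namespace tag (BP, CC, MF or KEGG) and a non-empty uppercase gene list.
#'
#' @slot termId,termName,namespace parallel character vectors.
#' @slot genes list of uppercase member-symbol vectors, parallel to
#'   \code{termId}.
#'
#' @exportClass AnnotationSet
setClass("AnnotationSet",
  representation(
    termId = "character", termName = "character",
    namespace = "character", genes = "list"
  )
)

setValidity("AnnotationSet", function(object) {
  msg <- character()
  k <- length(object@termId)
  if (length(object@termName) != k || length(object@namespace) != k ||
      length(object@genes) != k)
    msg <- c(msg, "termId, termName, namespace, genes must be parallel")
  if (any(duplicated(object@termId))) msg <- c(msg, "duplicate term ids")
  if (k) {
    if (!all(object@namespace %in% c("BP", "CC", "MF", "KEGG")))
      msg <- c(msg, "namespace must be one of BP, CC, MF, KEGG")
    sizes <- lengths(object@genes)
    if (any(sizes == 0L)) msg <- c(msg, "every term must be non-empty")
    up <- vapply(object@genes, function(g) identical(g, toupper(g)), logical(1))
    if (!all(up)) msg <- c(msg, "member symbols must be uppercase")
  }
  if (length(msg)) msg else TRUE
})

#' ActiveComponentSet: screened ingredients with their mapped target genes
#'
#' Produced by \code{\link{mapTargets}}: for every retained molecule the
#' deduplicated gene symbols it targets, grouped per herb, plus the global
#' target union. Molecules with no mappable target are kept but flagged.
#'
#' @slot herbComponents named list herb_id -> molecule ids.
#' @slot componentTargets named list molecule_id -> uppercase gene symbols
#'   (possibly empty for flagged molecules).
#' @slot flagged molecule ids with zero mapped targets.
#' @slot unionTargets global union of mapped gene symbols.
#'
#' @exportClass ActiveComponentSet
setClass("ActiveComponentSet",
  representation(
    herbComponents = "list", componentTargets = "list",
    flagged = "character", unionTargets = "character"
  )
)

setValidity("ActiveComponentSet", function(object) {
  msg <- character()
  mols <- unique(unlist(object@herbComponents, use.names = FALSE))
  if (!setequal(names(object@componentTargets), mols))
    msg <- c(msg, "componentTargets must cover exactly the herb components")
  u <- sort(unique(unlist(object@componentTargets, use.names = FALSE)))
  if (!setequal(u, object@unionTargets))
    msg <- c(msg, "unionTargets must equal the union of per-component targets")
  if (!all(object@flagged %in% mols))
    msg <- c(msg, "flagged molecules must be components")
  if (length(msg)) msg else TRUE
})
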