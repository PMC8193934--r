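# Herb-ingredient-target tripartite network construction and degree-based
# representative-component selection.

#' Build the herb-ingredient-target network
#'
#' Ingredient-gene edges are restricted to the putative target set (the
#' drug-disease intersection); ingredients left with zero restricted targets
#' are dropped, together with any herb link to them. Shared components (one
#' ingredient contained in several herbs) keep a single ingredient node with
#' one containment edge per herb.
#'
#' @param active an \linkS4class{ActiveComponentSet}.
#' @param putativeTargets \linkS4class{GeneSet} (or character vector) of
#'   genes allowed as target nodes.
#' @return a \linkS4class{TripartiteNetwork}.
#' @export
buildHITNetwork <- function(active, putativeTargets) {
  stopifnot(is(active, "ActiveComponentSet"))
  allowed <- if (is(putativeTargets, "GeneSet"))
    geneSymbols(putativeTargets) else toupper(as.character(putativeTargets))
  if (!length(allowed)) stop("empty putative target set", call. = FALSE)
  restricted <- lapply(componentTargets(active), intersect, allowed)
  keptMols <- names(restricted)[lengths(restricted) > 0L]
  if (!length(keptMols))
    stop("no ingredient targets any putative gene: empty HIT network",
         call. = FALSE)
  hc <- lapply(herbComponents(active), intersect, keptMols)
  hc <- hc[lengths(hc) > 0L]
  herbEdges <- do.call(rbind, lapply(names(hc), function(h)
    cbind(h, hc[[h]])))
  targetEdges <- do.call(rbind, lapply(keptMols, function(m)
    cbind(m, restricted[[m]])))
  genes <- sort(unique(targetEdges[, 2L]))
  new("TripartiteNetwork",
      herbs = sort(names(hc)), ingredients = sort(keptMols), genes = genes,
      herbEdges = herbEdges, targetEdges = targetEdges)
}

#' Per-herb target partition of a HIT network
#'
#' For each herb, the union of genes reachable through its ingredients.
#' Herb sets may overlap (shared components), so the sum of the parts can
#' exceed the union.
#'
#' @param net a \linkS4class{TripartiteNetwork}.
#' @return named list herb -> sorted gene symbols.
#' @export
herbTargetPartition <- function(net) {
  stopifnot(is(net, "TripartiteNetwork"))
  molTargets <- split(net@targetEdges[, 2L], net@targetEdges[, 1L])
  herbMols <- split(net@herbEdges[, 2L], net@herbEdges[, 1L])
  out <- lapply(herbMols, function(mols)
    sort(unique(unlist(molTargets[mols], use.names = FALSE))))
  out[sort(names(out))]
}

#' Gene-degree of every ingredient node
#'
#' The degree of an ingredient with respect to the gene partition, i.e. the
#' size of its restricted target set.
#'
#' @param net a \linkS4class{TripartiteNetwork}.
#' @return named integer vector molecule_id -> gene degree.
#' @export
ingredientGeneDegree <- function(net) {
  stopifnot(is(net, "TripartiteNetwork"))
  deg <- stats::setNames(integer(length(net@ingredients)), net@ingredients)
  tab <- table(net@targetEdges[, 1L])
  deg[names(tab)] <- as.integer(tab)
  deg
}

#' Select one representative component per herb by gene degree
#'
#' The network is rebuilt with gene nodes restricted to the hub set; within
#' each herb the ingredient of maximal gene-degree is chosen. Ties are broken
#' deterministically by the lexicographically smallest molecule id (with a
#' warning); herbs whose ingredients touch no hub gene are omitted with a
#' warning.
#'
#' @param active an \linkS4class{ActiveComponentSet} (the pre-restriction
#'   component structure).
#' @param hubGenes \linkS4class{GeneSet} (or character vector) of hub genes.
#' @return data.frame with columns herb_id, molecule_id, degree.
#' @export
representativeComponents <- function(active, hubGenes) {
  net <- buildHITNetwork(active, hubGenes)
  deg <- ingredientGeneDegree(net)
  herbMols <- split(net@herbEdges[, 2L], net@herbEdges[, 1L])
  allHerbs <- names(herbComponents(active))
  missing <- setdiff(allHerbs, names(herbMols))
  if (length(missing))
    warning("herb(s) with no ingredient touching a hub gene omitted: ",
            paste(sort(missing), collapse = ", "), call. = FALSE)
  rows <- lapply(sort(names(herbMols)), function(h) {
    mols <- sort(herbMols[[h]])
    d <- deg[mols]
    top <- mols[d == max(d)]
    if (length(top) > 1L)
      warning("degree tie in herb ", h, " between ",
              paste(top, collapse = ", "), "; choosing ", min(top),
              call. = FALSE)
    data.frame(herb_id = h, molecule_id = min(top),
               degree = as.integer(max(d)), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
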