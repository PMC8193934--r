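# Multi-source gene-set aggregation, Venn partitioning and the
# drug-target x disease-gene intersection.

#' Merge gene sets from several sources, deleting redundant items
#'
#' Union of the inputs with per-symbol provenance: each symbol remembers
#' every source set that contributed it, so Venn regions can be recomputed
#' from the merged object alone.
#'
#' @param sets list of \linkS4class{GeneSet} objects (at least one).
#' @param name label for the merged set.
#' @return a \linkS4class{GeneSet} whose sources are the input set names.
#' @export
mergeGeneSets <- function(sets, name = "merged") {
  stopifnot(length(sets) >= 1L,
            all(vapply(sets, is, logical(1), "GeneSet")))
  labels <- vapply(seq_along(sets), function(i) {
    lbl <- geneSetName(sets[[i]])
    if (nzchar(lbl)) lbl else paste0("set", i)
  }, character(1))
  if (any(duplicated(labels)))
    labels <- make.unique(labels)
  prov <- list()
  for (i in seq_along(sets)) {
    for (s in geneSymbols(sets[[i]]))
      prov[[s]] <- c(prov[[s]], labels[i])
  }
  GeneSet(names(prov), name = name, sources = labels, provenance = prov)
}

#' Venn partition of 2-6 gene sets
#'
#' Every symbol of the union is assigned to exactly one region, keyed by the
#' sorted labels of the sets containing it (e.g. \code{"A&C"}). Regions are
#' disjoint and their counts sum to the union size.
#'
#' @param sets list of 2-6 \linkS4class{GeneSet} objects, or a single merged
#'   set carrying provenance (as from \code{\link{mergeGeneSets}}).
#' @return list with \code{regions} (named list region key -> member
#'   symbols), \code{counts} (named integer vector over all 2^k - 1 keys,
#'   zeros included) and \code{labels}.
#' @export
vennPartition <- function(sets) {
  if (is(sets, "GeneSet")) {
    prov <- provenance(sets)
    if (!length(prov))
      stop("merged set carries no provenance; pass the source sets",
           call. = FALSE)
    labels <- sort(unique(unlist(prov, use.names = FALSE)))
    membership <- prov
  } else {
    stopifnot(all(vapply(sets, is, logical(1), "GeneSet")))
    if (length(sets) < 2L || length(sets) > 6L)
      stop("vennPartition supports 2 to 6 sets", call. = FALSE)
    labels <- vapply(seq_along(sets), function(i) {
      lbl <- geneSetName(sets[[i]])
      if (nzchar(lbl)) lbl else paste0("set", i)
    }, character(1))
    if (any(duplicated(labels))) labels <- make.unique(labels)
    membership <- list()
    for (i in seq_along(sets))
      for (s in geneSymbols(sets[[i]]))
        membership[[s]] <- c(membership[[s]], labels[i])
  }
  k <- length(labels)
  if (k < 2L || k > 6L)
    stop("vennPartition supports 2 to 6 sets", call. = FALSE)
  keyOf <- vapply(membership, function(src)
    paste(labels[labels %in% src], collapse = "&"), character(1))
  regions <- split(names(keyOf), keyOf)
  regions <- lapply(regions, sort)
  allKeys <- unlist(lapply(seq_len(k), function(m)
    utils::combn(labels, m, paste, collapse = "&", simplify = FALSE)))
  counts <- stats::setNames(integer(length(allKeys)), allKeys)
  counts[names(regions)] <- lengths(regions)
  list(regions = regions, counts = counts, labels = labels)
}

#' Intersect drug targets with disease genes
#'
#' The putative therapeutic target set: genes both targeted by the formula's
#' active ingredients and associated with the disease. An empty intersection
#' stops the pipeline (downstream network stages need nodes).
#'
#' @param drugTargets \linkS4class{GeneSet} of compound target genes.
#' @param disease \linkS4class{GeneSet} of disease-associated genes.
#' @param name label for the result (default \code{"putative_targets"}).
#' @return a \linkS4class{GeneSet}.
#' @export
intersectDrugDisease <- function(drugTargets, disease,
                                 name = "putative_targets") {
  stopifnot(is(drugTargets, "GeneSet"), is(disease, "GeneSet"),
            length(drugTargets) > 0L, length(disease) > 0L)
  shared <- intersect(geneSymbols(drugTargets), geneSymbols(disease))
  if (!length(shared))
    stop("drug targets and disease genes are disjoint: ",
         "no putative targets to analyse", call. = FALSE)
  GeneSet(shared, name = name,
          sources = c(geneSetName(drugTargets), geneSetName(disease)))
}
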