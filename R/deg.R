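# Threshold classification of differential-expression tables.

#' Classify genes as up-, down-regulated or unchanged
#'
#' A gene is called \code{up} iff \code{padj < padjMax} and
#' \code{log2fc > lfcMin}; \code{down} iff \code{padj < padjMax} and
#' \code{log2fc < -lfcMin}; otherwise \code{unchanged}. Both thresholds are
#' strict ("below 0.05", "more than 1"), so boundary rows with
#' \code{log2fc = 1} or \code{padj = 0.05} are unchanged. The fold-change
#' rule is the absolute-value reading: the same magnitude cut applies to
#' both directions.
#'
#' @param tab validated DE table (see \code{\link{readDETable}}).
#' @param padjMax adjusted-p threshold (default 0.05).
#' @param lfcMin log2 fold-change magnitude threshold (default 1).
#' @return list with \code{calls} (data.frame gene, class, log2fc, padj) and
#'   \code{summary} (named vector n_up, n_down, n_de).
#' @export
callDEGs <- function(tab, padjMax = 0.05, lfcMin = 1) {
  stopifnot(is.data.frame(tab),
            all(c("gene", "log2fc", "padj") %in% names(tab)),
            padjMax > 0, padjMax <= 1, lfcMin >= 0)
  cls <- rep("unchanged", nrow(tab))
  sig <- tab$padj < padjMax
  cls[sig & tab$log2fc > lfcMin] <- "up"
  cls[sig & tab$log2fc < -lfcMin] <- "down"
  calls <- data.frame(gene = tab$gene, class = cls,
                      log2fc = tab$log2fc, padj = tab$padj,
                      stringsAsFactors = FALSE)
  nUp <- sum(cls == "up")
  nDown <- sum(cls == "down")
  list(calls = calls,
       summary = c(n_up = nUp, n_down = nDown, n_de = nUp + nDown))
}

#' Extract the up- or down-regulated gene set from DEG calls
#'
#' @param calls the \code{calls} data.frame from \code{\link{callDEGs}}.
#' @param direction \code{"up"} or \code{"down"}.
#' @return a \linkS4class{GeneSet} (possibly empty, with a warning).
#' @export
degGeneSet <- function(calls, direction = c("up", "down")) {
  direction <- match.arg(direction)
  genes <- calls$gene[calls$class == direction]
  if (!length(genes))
    warning("no ", direction, "-regulated genes", call. = FALSE)
  GeneSet(genes, name = paste0(direction, "_regulated"))
}
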