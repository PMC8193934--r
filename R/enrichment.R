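# Hypergeometric over-representation analysis with Benjamini-Hochberg
# correction.

#' Hypergeometric upper-tail probability
#'
#' \eqn{P(X \ge k)} for \eqn{X \sim} Hypergeometric(N, K, n): the chance of
#' drawing at least k annotated genes when n genes are drawn without
#' replacement from a universe of N genes of which K are annotated.
#' Delegates to \code{stats::phyper}, which works on log scale internally,
#' so small tail probabilities are stable.
#'
#' @param k observed overlap count.
#' @param K term size within the universe.
#' @param n query size within the universe.
#' @param N universe size.
#' @return upper-tail probability in [0, 1].
#' @examples
#' hypergeomUpperTail(4, 5, 4, 10)  # 5/210
#' @export
hypergeomUpperTail <- function(k, K, n, N) {
  stopifnot(length(k) == 1L, length(K) == 1L, length(n) == 1L,
            length(N) == 1L)
  if (any(c(k, K, n, N) %% 1 != 0) || any(c(k, K, n, N) < 0))
    stop("k, K, n, N must be non-negative integers", call. = FALSE)
  if (K > N || n > N || k > min(K, n))
    stop("inconsistent hypergeometric arguments: need K,n <= N and ",
         "k <= min(K, n)", call. = FALSE)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment (\code{stats::p.adjust}, method \code{"BH"}):
#' \eqn{padj_{(i)} = \min_{j \ge i} \min(m \, p_{(j)} / j, 1)} along the
#' sorted p-values. Order-preserving and elementwise \eqn{\ge p}.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return adjusted values, same order as the input.
#' @export
bhAdjust <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Over-representation analysis of a gene set against annotation terms
#'
#' For each term, the overlap of the query with the term (both intersected
#' with the universe) is scored by the hypergeometric upper tail; terms with
#' zero universe overlap are skipped. BH adjustment is applied within each
#' namespace separately by default (BP, CC, MF and KEGG panels are separate
#' test families), or pooled across all tested terms with
#' \code{byNamespace = FALSE}. Rows are sorted by padj then p, and flagged
#' significant iff \code{padj < alpha} (strict).
#'
#' @param query \linkS4class{GeneSet} or character vector of query genes.
#' @param annotations an \linkS4class{AnnotationSet}.
#' @param universe background \linkS4class{GeneSet} or character vector;
#'   default (\code{NULL}) is every gene appearing in the annotations.
#' @param alpha significance threshold on the adjusted p-value
#'   (default 0.05).
#' @param byNamespace adjust within namespaces (default TRUE).
#' @return data.frame with columns term_id, term_name, namespace, k, K, n,
#'   N, p, padj, significant.
#' @export
enrich <- function(query, annotations, universe = NULL, alpha = 0.05,
                   byNamespace = TRUE) {
  stopifnot(is(annotations, "AnnotationSet"))
  qs <- if (is(query, "GeneSet")) geneSymbols(query)
    else unique(toupper(as.character(query)))
  uni <- if (is.null(universe))
    sort(unique(unlist(annotations@genes, use.names = FALSE)))
  else if (is(universe, "GeneSet")) geneSymbols(universe)
  else unique(toupper(as.character(universe)))
  q <- intersect(qs, uni)
  if (!length(q))
    stop("query has no gene in the universe", call. = FALSE)
  n <- length(q)
  N <- length(uni)
  rows <- lapply(seq_along(annotations@termId), function(i) {
    members <- intersect(annotations@genes[[i]], uni)
    if (!length(members)) return(NULL)
    k <- length(intersect(q, members))
    K <- length(members)
    data.frame(term_id = annotations@termId[i],
               term_name = annotations@termName[i],
               namespace = annotations@namespace[i],
               k = k, K = K, n = n, N = N,
               p = hypergeomUpperTail(k, K, n, N),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    stop("no annotation term overlaps the universe", call. = FALSE)
  out <- do.call(rbind, rows)
  if (byNamespace) {
    out$padj <- stats::ave(out$p, out$namespace, FUN = bhAdjust)
  } else {
    out$padj <- bhAdjust(out$p)
  }
  out$significant <- out$padj < alpha
  out <- out[order(out$padj, out$p, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
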