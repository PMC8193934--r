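# Readers and writers for every external format the pipeline touches.
# All downstream modules operate on validated in-memory objects only.

.read_delim <- function(path, sep = "\t", header = TRUE, ...) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.table(path, sep = sep, header = header, quote = "",
                    comment.char = "", stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}

#' Read a herb-ingredient table with OB and DL values
#'
#' Expects a delimited table with one row per (herb, molecule) holding the
#' oral bioavailability (OB, percent on 0-100) and drug-likeness (DL,
#' unitless on 0-1) of each ingredient, as exported from TCMSP-style
#' databases.
#'
#' @param path file path.
#' @param sep field separator; `"\t"` (canonical) or `","`.
#' @param headerMap named character vector mapping the canonical column roles
#'   \code{herb}, \code{molecule}, \code{name}, \code{ob}, \code{dl} to the
#'   header names used in the file.
#' @return data.frame with columns \code{herb_id}, \code{molecule_id},
#'   \code{molecule_name}, \code{ob}, \code{dl}; (herb, molecule) pairs are
#'   unique and OB/DL validated in range.
#' @export
readIngredientTable <- function(path, sep = "\t",
                                headerMap = c(herb = "herb",
                                              molecule = "molecule",
                                              name = "name",
                                              ob = "ob", dl = "dl")) {
  raw <- .read_delim(path, sep = sep)
  need <- c("herb", "molecule", "ob", "dl")
  missing <- setdiff(unname(headerMap[need]), names(raw))
  if (length(missing))
    stop("ingredient table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  nameCol <- headerMap[["name"]]
  tab <- data.frame(
    herb_id = as.character(raw[[headerMap[["herb"]]]]),
    molecule_id = as.character(raw[[headerMap[["molecule"]]]]),
    molecule_name = if (!is.na(nameCol) && nameCol %in% names(raw))
      as.character(raw[[nameCol]]) else "",
    ob = suppressWarnings(as.numeric(raw[[headerMap[["ob"]]]])),
    dl = suppressWarnings(as.numeric(raw[[headerMap[["dl"]]]])),
    stringsAsFactors = FALSE
  )
  validateIngredientTable(tab)
}

#' Validate an ingredient table
#'
#' @param tab data.frame with columns herb_id, molecule_id, molecule_name,
#'   ob, dl.
#' @return the validated table (invisibly unchanged).
#' @export
validateIngredientTable <- function(tab) {
  bad <- which(!is.finite(tab$ob) | !is.finite(tab$dl))
  if (length(bad))
    stop("non-numeric or missing OB/DL in row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  oor <- which(tab$ob < 0 | tab$ob > 100 | tab$dl < 0 | tab$dl > 1)
  if (length(oor))
    stop("OB outside [0,100] or DL outside [0,1] in row(s): ",
         paste(oor, collapse = ", "), call. = FALSE)
  key <- paste(tab$herb_id, tab$molecule_id, sep = "\r")
  if (any(duplicated(key)))
    stop("duplicate (herb, molecule) pair(s) in row(s): ",
         paste(which(duplicated(key)), collapse = ", "), call. = FALSE)
  tab
}

#' Write an ingredient table
#'
#' Round-trips losslessly with \code{\link{readIngredientTable}} under the
#' default header map.
#'
#' @param tab validated ingredient table.
#' @param path output path.
#' @param sep field separator.
#' @export
writeIngredientTable <- function(tab, path, sep = "\t") {
  out <- data.frame(herb = tab$herb_id, molecule = tab$molecule_id,
                    name = tab$molecule_name, ob = tab$ob, dl = tab$dl,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a one-symbol-per-line gene list
#'
#' Blank lines and \code{#} comments are skipped; symbols are
#' whitespace-trimmed, uppercased and deduplicated.
#'
#' @param path file path.
#' @param source label recorded as the set's provenance (defaults to the
#'   file name).
#' @return a \linkS4class{GeneSet}.
#' @export
readGeneList <- function(path, source = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines))
    stop("gene list is empty after removing blanks/comments: ", path,
         call. = FALSE)
  GeneSet(lines, name = source, sources = source)
}

#' Write a gene set as a plain list
#'
#' @param x a \linkS4class{GeneSet} or character vector.
#' @param path output path.
#' @export
writeGeneList <- function(x, path) {
  if (is(x, "GeneSet")) x <- geneSymbols(x)
  writeLines(x, path)
  invisible(path)
}

#' Read a STRING-style weighted edge list and apply a confidence threshold
#'
#' The score scale is auto-detected: if any score exceeds 1 the file is taken
#' to be on the STRING 0-999 scale and the unit-interval threshold is
#' multiplied by 1000. Self-loops are dropped, duplicated unordered pairs are
#' collapsed to their maximum score, and rows below the threshold are
#' removed (ties at the threshold are kept, i.e. the comparison is >=).
#'
#' @param path 3+ column delimited file: node_a, node_b, combined score.
#' @param threshold confidence threshold on the unit interval
#'   (default 0.7).
#' @param sep field separator.
#' @param header whether the file has a header line.
#' @return data.frame with columns \code{node_a}, \code{node_b},
#'   \code{score} (original scale), attribute \code{score_scale} set to
#'   \code{"unit"} or \code{"999"}.
#' @export
readWeightedEdges <- function(path, threshold = 0.7, sep = "\t",
                              header = TRUE) {
  raw <- .read_delim(path, sep = sep, header = header)
  if (ncol(raw) < 3L)
    stop("weighted edge list needs at least 3 columns, got ", ncol(raw),
         call. = FALSE)
  score <- suppressWarnings(as.numeric(raw[[3L]]))
  if (anyNA(score)) stop("non-numeric score values", call. = FALSE)
  if (any(score < 0)) stop("negative confidence score", call. = FALSE)
  a <- toupper(trimws(as.character(raw[[1L]])))
  b <- toupper(trimws(as.character(raw[[2L]])))
  scale <- if (any(score > 1)) "999" else "unit"
  cut <- if (scale == "999") threshold * 1000 else threshold
  keep <- a != b
  a <- a[keep]; b <- b[keep]; score <- score[keep]
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  ord <- order(key, -score)
  first <- !duplicated(key[ord])
  sel <- ord[first]
  out <- data.frame(node_a = lo[sel], node_b = hi[sel], score = score[sel],
                    stringsAsFactors = FALSE)
  out <- out[out$score >= cut, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "score_scale") <- scale
  out
}

#' Write a weighted edge list
#'
#' @param edges data.frame as returned by \code{\link{readWeightedEdges}}.
#' @param path output path.
#' @export
writeWeightedEdges <- function(edges, path) {
  utils::write.table(
    data.frame(protein1 = edges$node_a, protein2 = edges$node_b,
               combined_score = edges$score),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT annotation file
#'
#' Broad-dialect GMT: one term per line, tab-separated fields
#' \code{term_id}, \code{description}, members... A namespace tag may be
#' embedded in the description as \code{"BP|actual description"}; without a
#' tag the \code{namespace} default applies.
#'
#' @param path GMT file.
#' @param namespace default namespace for untagged terms (BP, CC, MF or
#'   KEGG).
#' @return an \linkS4class{AnnotationSet}.
#' @export
readGMT <- function(path, namespace = "BP") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  ids <- nm <- ns <- character(length(lines))
  genes <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop("malformed GMT line ", i, ": fewer than 3 fields", call. = FALSE)
    ids[i] <- f[1L]
    desc <- f[2L]
    tag <- sub("\\|.*$", "", desc)
    if (grepl("|", desc, fixed = TRUE) && tag %in% c("BP", "CC", "MF", "KEGG")) {
      ns[i] <- tag
      nm[i] <- sub("^[^|]*\\|", "", desc)
    } else {
      ns[i] <- namespace
      nm[i] <- desc
    }
    genes[[i]] <- unique(toupper(trimws(f[-(1:2)])))
  }
  new("AnnotationSet", termId = ids, termName = nm, namespace = ns,
      genes = genes)
}

#' Write an AnnotationSet as GMT
#'
#' The namespace is embedded in the description field
#' (\code{"BP|description"}), so \code{\link{readGMT}} round-trips it.
#'
#' @param ann an \linkS4class{AnnotationSet}.
#' @param path output path.
#' @export
writeGMT <- function(ann, path) {
  lines <- vapply(seq_along(ann@termId), function(i) {
    paste(c(ann@termId[i], paste0(ann@namespace[i], "|", ann@termName[i]),
            ann@genes[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a differential-expression result table
#'
#' Expects columns \code{gene}, \code{log2fc}, \code{pvalue}, \code{padj}.
#' p-values and adjusted p-values must lie in [0,1]; \code{padj >= pvalue}
#' is NOT required (some DE tools report independent-filtered or otherwise
#' non-monotone adjusted values). Gene symbols are uppercased and must be
#' unique.
#'
#' @param path delimited file.
#' @param sep field separator.
#' @return data.frame with columns gene, log2fc, pvalue, padj.
#' @export
readDETable <- function(path, sep = "\t") {
  raw <- .read_delim(path, sep = sep)
  need <- c("gene", "log2fc", "pvalue", "padj")
  missing <- setdiff(need, names(raw))
  if (length(missing))
    stop("DE table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  tab <- data.frame(gene = toupper(trimws(as.character(raw$gene))),
                    log2fc = as.numeric(raw$log2fc),
                    pvalue = as.numeric(raw$pvalue),
                    padj = as.numeric(raw$padj),
                    stringsAsFactors = FALSE)
  validateDETable(tab)
}

#' Validate a differential-expression table
#'
#' @param tab data.frame with columns gene, log2fc, pvalue, padj.
#' @return the validated table.
#' @export
validateDETable <- function(tab) {
  if (any(duplicated(tab$gene)))
    stop("duplicate gene symbols in DE table", call. = FALSE)
  bad <- which(!is.finite(tab$log2fc) |
                 !is.finite(tab$pvalue) | tab$pvalue < 0 | tab$pvalue > 1 |
                 !is.finite(tab$padj) | tab$padj < 0 | tab$padj > 1)
  if (length(bad))
    stop("invalid log2fc/pvalue/padj (p outside [0,1]?) in row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  tab
}

#' Write a DE table
#'
#' @param tab DE table data.frame.
#' @param path output path.
#' @export
writeDETable <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a two-column target-name to gene-symbol mapping
#'
#' Stands in for a protein-name to human-gene-symbol lookup (e.g. a local
#' UniProt export). First column: target protein name; second column: gene
#' symbol.
#'
#' @param path delimited file with columns \code{target} and \code{symbol}.
#' @param sep field separator.
#' @return named character vector target name -> uppercase symbol.
#' @export
readSymbolMap <- function(path, sep = "\t") {
  raw <- .read_delim(path, sep = sep)
  if (ncol(raw) < 2L)
    stop("symbol map needs two columns (target, symbol)", call. = FALSE)
  stats::setNames(toupper(trimws(as.character(raw[[2L]]))),
                  trimws(as.character(raw[[1L]])))
}

#' Read an ingredient-to-target mapping table
#'
#' Columns: \code{molecule} (molecule id), \code{target} (free-text target
#' protein name) and optionally \code{symbol} (gene symbol, may be empty for
#' unmapped targets). Duplicate (molecule, symbol) pairs are collapsed.
#'
#' @param path delimited file.
#' @param sep field separator.
#' @return data.frame with columns molecule_id, target_name, gene_symbol
#'   (\code{""} when unmapped).
#' @export
readTargetMap <- function(path, sep = "\t") {
  raw <- .read_delim(path, sep = sep)
  need <- c("molecule", "target")
  missing <- setdiff(need, names(raw))
  if (length(missing))
    stop("target map is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  sym <- if ("symbol" %in% names(raw))
    toupper(trimws(as.character(raw$symbol))) else ""
  sym[is.na(sym)] <- ""
  tab <- data.frame(molecule_id = as.character(raw$molecule),
                    target_name = as.character(raw$target),
                    gene_symbol = sym, stringsAsFactors = FALSE)
  key <- paste(tab$molecule_id, tab$gene_symbol, sep = "\r")
  dup <- duplicated(key) & nzchar(tab$gene_symbol)
  tab <- tab[!dup, , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Write a target map
#'
#' @param tab target map data.frame.
#' @param path output path.
#' @export
writeTargetMap <- function(tab, path) {
  out <- data.frame(molecule = tab$molecule_id, target = tab$target_name,
                    symbol = tab$gene_symbol, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a graph to SIF, GraphML or edge-TSV
#'
#' GraphML preserves node names, partition labels (tripartite networks) and
#' edge weights/types; SIF carries topology with a relation tag; edge-TSV
#' carries endpoints plus weight.
#'
#' @param g a \linkS4class{PPIGraph} or \linkS4class{TripartiteNetwork}.
#' @param path output path.
#' @param format one of \code{"graphml"}, \code{"sif"}, \code{"tsv"}.
#' @export
writeGraphFile <- function(g, path, format = c("graphml", "sif", "tsv")) {
  format <- match.arg(format)
  ig <- asIgraph(g)
  if (format == "graphml") {
    igraph::write_graph(ig, path, format = "graphml")
  } else if (format == "sif") {
    em <- igraph::as_edgelist(ig)
    rel <- if (is(g, "TripartiteNetwork"))
      igraph::E(ig)$type else rep("pp", nrow(em))
    writeLines(paste(em[, 1L], rel, em[, 2L], sep = "\t"), path)
  } else {
    em <- igraph::as_edgelist(ig)
    w <- if (is(g, "PPIGraph")) g@weights else rep(1, nrow(em))
    utils::write.table(
      data.frame(node_a = em[, 1L], node_b = em[, 2L], score = w),
      path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a graph written by writeGraphFile back into a PPIGraph
#'
#' @param path input path.
#' @param format \code{"graphml"} or \code{"tsv"} (SIF is export-only).
#' @return a \linkS4class{PPIGraph}.
#' @export
readGraphFile <- function(path, format = c("graphml", "tsv")) {
  format <- match.arg(format)
  if (format == "graphml") {
    ig <- igraph::read_graph(path, format = "graphml")
    em <- igraph::as_edgelist(ig)
    w <- if ("weight" %in% igraph::edge_attr_names(ig))
      igraph::E(ig)$weight else rep(1, nrow(em))
    PPIGraph(em, weights = w, nodes = igraph::V(ig)$name)
  } else {
    edges <- readWeightedEdges(path, threshold = 0)
    PPIGraph(edges)
  }
}

#' Write a generic table as TSV
#'
#' @param rows data.frame.
#' @param path output path.
#' @export
writeTable <- function(rows, path) {
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
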