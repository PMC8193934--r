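# Synthetic-data generators. Every generator is a pure function of its
# parameters and seed and returns, next to the data, a "ledger" of planted
# ground truth (pass sets, union sizes, module membership, planted term,
# DE counts) that fully determines the expected output of each deterministic
# pipeline stage on the generated instance.

.withSeed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Generate a herb-ingredient table with a known screening pass set
#'
#' Passing rows draw OB ~ Uniform(20, 60) and DL ~ Uniform(0.1, 0.6);
#' failing rows violate at least one bound (low OB, low DL, or both). The
#' number of passers is exactly \code{round(fracPass * nHerbs * nPerHerb)}.
#'
#' @param nHerbs number of herbs.
#' @param nPerHerb molecules per herb.
#' @param fracPass fraction of rows passing both screening bounds, in (0,1).
#' @param seed RNG seed.
#' @return list with \code{table} (ingredient table data.frame) and
#'   \code{ledger} (\code{passSet}: molecule ids of planted passers;
#'   \code{nPass}).
#' @export
genIngredients <- function(nHerbs = 10L, nPerHerb = 12L, fracPass = 0.4,
                           seed = 1L) {
  stopifnot(fracPass > 0, fracPass < 1)
  .withSeed(seed, {
    nTotal <- nHerbs * nPerHerb
    nPass <- round(fracPass * nTotal)
    herbs <- sprintf("HERB%02d", rep(seq_len(nHerbs), each = nPerHerb))
    mols <- sprintf("MOL%04d", seq_len(nTotal))
    passIdx <- sort(sample(nTotal, nPass))
    ob <- dl <- numeric(nTotal)
    ob[passIdx] <- stats::runif(nPass, 20, 60)
    dl[passIdx] <- stats::runif(nPass, 0.1, 0.6)
    failIdx <- setdiff(seq_len(nTotal), passIdx)
    mode <- sample(3L, length(failIdx), replace = TRUE)
    lowOB <- failIdx[mode != 2L]
    okOB <- failIdx[mode == 2L]
    lowDL <- failIdx[mode != 1L]
    okDL <- failIdx[mode == 1L]
    ob[lowOB] <- stats::runif(length(lowOB), 0, 19.5)
    ob[okOB] <- stats::runif(length(okOB), 20, 60)
    dl[lowDL] <- stats::runif(length(lowDL), 0, 0.095)
    dl[okDL] <- stats::runif(length(okDL), 0.1, 0.6)
    tab <- data.frame(herb_id = herbs, molecule_id = mols,
                      molecule_name = paste0("compound_", mols),
                      ob = ob, dl = dl, stringsAsFactors = FALSE)
    list(table = tab,
         ledger = list(passSet = mols[passIdx], nPass = nPass, seed = seed))
  })
}

#' Generate per-source disease gene lists with controlled redundancy
#'
#' Every union gene is assigned to one primary source uniformly at random
#' and, independently, to each other source with probability
#' \code{redundancy}, so each gene belongs to at least one list and the
#' union of the lists is exactly the planted universe.
#'
#' @param nSources number of source databases (default 5).
#' @param unionSize size of the planted union.
#' @param redundancy probability a gene also appears in each non-primary
#'   source.
#' @param seed RNG seed.
#' @param genes optional explicit union symbols (length \code{unionSize});
#'   default \code{DIS0001...}.
#' @param labels source labels (default \code{source1...}).
#' @return list with \code{sources} (named list label -> symbol vector) and
#'   \code{ledger} (\code{unionSize}, \code{union}, per-source sizes,
#'   pairwise overlap matrix).
#' @export
genDiseaseSources <- function(nSources = 5L, unionSize = 500L,
                              redundancy = 0.3, seed = 1L, genes = NULL,
                              labels = paste0("source", seq_len(nSources))) {
  stopifnot(nSources >= 1L, redundancy >= 0, redundancy <= 1,
            length(labels) == nSources)
  if (is.null(genes)) genes <- sprintf("DIS%04d", seq_len(unionSize))
  stopifnot(length(genes) == unionSize)
  genes <- toupper(genes)
  .withSeed(seed, {
    primary <- sample(nSources, unionSize, replace = TRUE)
    member <- matrix(stats::runif(unionSize * nSources) < redundancy,
                     nrow = unionSize)
    member[cbind(seq_len(unionSize), primary)] <- TRUE
    sources <- stats::setNames(
      lapply(seq_len(nSources), function(j) sort(genes[member[, j]])),
      labels)
    overlap <- crossprod(member)
    dimnames(overlap) <- list(labels, labels)
    list(sources = sources,
         ledger = list(unionSize = unionSize, union = sort(genes),
                       perSource = lengths(sources),
                       overlap = overlap, seed = seed))
  })
}

#' Generate an ingredient-to-target table covering a planted gene universe
#'
#' Each molecule draws a uniform number of targets from the pool; genes the
#' draws leave uncovered are then assigned to random molecules of the
#' \code{cover} subset, so the target union over \code{cover} equals the
#' pool exactly.
#'
#' @param molecules molecule ids to annotate.
#' @param genePool character vector of target gene symbols.
#' @param targetsPerMol integer range (min, max) of targets per molecule.
#' @param seed RNG seed.
#' @param cover subset of \code{molecules} whose union must equal
#'   \code{genePool} (default: all).
#' @return list with \code{table} (target map data.frame: molecule_id,
#'   target_name, gene_symbol) and \code{ledger} (\code{union}, per-molecule
#'   target lists).
#' @export
genTargetMap <- function(molecules, genePool, targetsPerMol = c(5L, 20L),
                         seed = 1L, cover = molecules) {
  stopifnot(length(molecules) >= 1L, length(genePool) >= 1L,
            all(cover %in% molecules))
  genePool <- toupper(genePool)
  .withSeed(seed, {
    perMol <- stats::setNames(lapply(molecules, function(m) {
      k <- sample(seq(targetsPerMol[1L], targetsPerMol[2L]), 1L)
      sort(sample(genePool, min(k, length(genePool))))
    }), molecules)
    covered <- unique(unlist(perMol[cover], use.names = FALSE))
    for (gene in setdiff(genePool, covered)) {
      m <- sample(cover, 1L)
      perMol[[m]] <- sort(c(perMol[[m]], gene))
    }
    tab <- do.call(rbind, lapply(names(perMol), function(m)
      data.frame(molecule_id = m,
                 target_name = paste0("protein_", perMol[[m]]),
                 gene_symbol = perMol[[m]], stringsAsFactors = FALSE)))
    rownames(tab) <- NULL
    list(table = tab,
         ledger = list(union = sort(unique(unlist(perMol[cover],
                                                  use.names = FALSE))),
                       perMolecule = perMol, seed = seed))
  })
}

#' Generate a PPI edge list with a planted dense module
#'
#' Erdos-Renyi-style draws: pairs inside the planted module connect with
#' probability \code{pModule}, background pairs with \code{pBackground} and
#' module-background pairs with \code{pCross}. Emitted edges carry
#' confidence scores Uniform(0.7, 0.999), so everything survives the 0.7
#' reader threshold.
#'
#' @param nBackground number of background nodes.
#' @param moduleSize number of planted-module nodes.
#' @param pModule,pBackground,pCross Bernoulli edge probabilities.
#' @param seed RNG seed.
#' @param nodes optional node symbols (length \code{nBackground +
#'   moduleSize}); default \code{GENE0001...}. The module is a random
#'   subset.
#' @return list with \code{edges} (data.frame node_a, node_b, score) and
#'   \code{ledger} (\code{module} membership, per-block and total edge
#'   counts, \code{nodesWithEdge}).
#' @export
genPPI <- function(nBackground = 170L, moduleSize = 30L, pModule = 0.8,
                   pBackground = 0.05, pCross = 0.02, seed = 1L,
                   nodes = NULL) {
  nTotal <- nBackground + moduleSize
  if (is.null(nodes)) nodes <- sprintf("GENE%04d", seq_len(nTotal))
  stopifnot(length(nodes) == nTotal)
  nodes <- toupper(nodes)
  .withSeed(seed, {
    module <- sort(sample(nodes, moduleSize))
    background <- setdiff(nodes, module)
    drawBlock <- function(pairs, p) {
      if (!ncol(pairs) || p <= 0) return(pairs[, 0, drop = FALSE])
      pairs[, stats::runif(ncol(pairs)) < p, drop = FALSE]
    }
    modPairs <- if (moduleSize >= 2L) utils::combn(module, 2L)
      else matrix(character(), nrow = 2L)
    bgPairs <- if (nBackground >= 2L) utils::combn(background, 2L)
      else matrix(character(), nrow = 2L)
    crossPairs <- rbind(rep(module, each = nBackground),
                        rep(background, times = moduleSize))
    eMod <- drawBlock(modPairs, pModule)
    eBg <- drawBlock(bgPairs, pBackground)
    eCross <- drawBlock(crossPairs, pCross)
    em <- cbind(eMod, eBg, eCross)
    edges <- data.frame(node_a = pmin(em[1L, ], em[2L, ]),
                        node_b = pmax(em[1L, ], em[2L, ]),
                        score = round(stats::runif(ncol(em), 0.7, 0.999), 3),
                        stringsAsFactors = FALSE)
    ord <- order(edges$node_a, edges$node_b)
    edges <- edges[ord, , drop = FALSE]
    rownames(edges) <- NULL
    list(edges = edges,
         ledger = list(module = module,
                       nModuleEdges = ncol(eMod),
                       nBackgroundEdges = ncol(eBg),
                       nCrossEdges = ncol(eCross),
                       nEdges = nrow(edges),
                       nodesWithEdge =
                         sort(unique(c(edges$node_a, edges$node_b))),
                       seed = seed))
  })
}

#' Generate annotation terms with one planted enriched term
#'
#' Null terms draw members uniformly from the universe; when
#' \code{planted = TRUE} the first term instead contains a fraction
#' \code{plantedOverlap} of the designated query plus uniform fillers, so a
#' hypergeometric over-representation test should rank it first.
#'
#' @param universe character vector of background symbols.
#' @param query character vector the planted term must overlap.
#' @param nTerms number of terms.
#' @param termSizeRange integer range (min, max) of term sizes.
#' @param plantedOverlap fraction of the query planted into term 1.
#' @param planted plant an enriched term (default TRUE); FALSE gives an
#'   all-null annotation set.
#' @param seed RNG seed.
#' @return list with \code{annotations} (\linkS4class{AnnotationSet}) and
#'   \code{ledger} (\code{plantedTerm} id or NA, planted member list).
#' @export
genAnnotations <- function(universe, query = character(), nTerms = 50L,
                           termSizeRange = c(10L, 40L), plantedOverlap = 0.8,
                           planted = TRUE, seed = 1L) {
  universe <- toupper(universe)
  query <- intersect(toupper(query), universe)
  stopifnot(nTerms >= 1L, !planted || length(query) >= 1L)
  .withSeed(seed, {
    ids <- sprintf("TERM%03d", seq_len(nTerms))
    ns <- sample(c("BP", "CC", "MF", "KEGG"), nTerms, replace = TRUE)
    genes <- vector("list", nTerms)
    sizes <- sample(seq(termSizeRange[1L], termSizeRange[2L]), nTerms,
                    replace = TRUE)
    start <- 1L
    plantedGenes <- character()
    if (planted) {
      core <- sample(query, ceiling(plantedOverlap * length(query)))
      size <- max(length(core), sizes[1L])
      fill <- sample(setdiff(universe, core), size - length(core))
      genes[[1L]] <- sort(c(core, fill))
      plantedGenes <- sort(core)
      start <- 2L
    }
    for (i in seq(start, nTerms)) {
      genes[[i]] <- sort(sample(universe, min(sizes[i], length(universe))))
    }
    ann <- new("AnnotationSet", termId = ids,
               termName = paste0("synthetic term ", seq_len(nTerms)),
               namespace = ns, genes = genes)
    list(annotations = ann,
         ledger = list(plantedTerm = if (planted) ids[1L] else NA_character_,
                       plantedGenes = plantedGenes, seed = seed))
  })
}

#' Generate a DE table with planted up/down counts
#'
#' Exactly \code{nUp} rows get \code{log2fc > 1} with \code{padj < 0.05},
#' exactly \code{nDown} rows \code{log2fc < -1} with \code{padj < 0.05};
#' every other row fails at least one strict threshold (either
#' \eqn{|log2fc| \le 1} or \eqn{padj \ge 0.05}). Row order is shuffled.
#'
#' @param nGenes total rows.
#' @param nUp planted up-regulated count.
#' @param nDown planted down-regulated count.
#' @param seed RNG seed.
#' @return list with \code{table} (DE data.frame: gene, log2fc, pvalue,
#'   padj) and \code{ledger} (\code{nUp}, \code{nDown}, planted gene ids).
#' @export
genDETable <- function(nGenes = 15000L, nUp = 141L, nDown = 643L,
                       seed = 1L) {
  stopifnot(nUp + nDown <= nGenes)
  .withSeed(seed, {
    genes <- sprintf("DEG%05d", seq_len(nGenes))
    log2fc <- numeric(nGenes)
    padj <- numeric(nGenes)
    idx <- sample(nGenes, nUp + nDown)
    upIdx <- idx[seq_len(nUp)]
    downIdx <- idx[nUp + seq_len(nDown)]
    nullIdx <- setdiff(seq_len(nGenes), idx)
    log2fc[upIdx] <- stats::runif(nUp, 1.0001, 6)
    log2fc[downIdx] <- -stats::runif(nDown, 1.0001, 6)
    padj[c(upIdx, downIdx)] <- stats::runif(nUp + nDown, 0, 0.0499)
    smallFC <- stats::runif(length(nullIdx)) < 0.5
    log2fc[nullIdx[smallFC]] <- stats::runif(sum(smallFC), -1, 1)
    padj[nullIdx[smallFC]] <- stats::runif(sum(smallFC), 0, 1)
    log2fc[nullIdx[!smallFC]] <- stats::runif(sum(!smallFC), -6, 6)
    padj[nullIdx[!smallFC]] <- stats::runif(sum(!smallFC), 0.05, 1)
    pvalue <- padj * stats::runif(nGenes, 0.1, 1)
    tab <- data.frame(gene = genes, log2fc = log2fc, pvalue = pvalue,
                      padj = padj, stringsAsFactors = FALSE)
    tab <- tab[sample(nGenes), , drop = FALSE]
    rownames(tab) <- NULL
    list(table = tab,
         ledger = list(nUp = nUp, nDown = nDown,
                       upGenes = sort(genes[upIdx]),
                       downGenes = sort(genes[downIdx]), seed = seed))
  })
}

#' Simulate a complete pipeline input set at the published scale
#'
#' Writes every input file the pipeline consumes, with a coherent planted
#' structure: a 200-gene drug-disease intersection (the putative target
#' set), a 500-gene disease union split over five sources, a 400-gene drug
#' target union, a 200-node PPI substrate with a 30-node dense module,
#' annotation terms with one term planted on the module, and a DE table
#' with a planted 141 up / 643 down split. The returned config can be passed
#' straight to \code{\link{runPipeline}}; the ledger (also written as
#' \code{ledger.json}) records all planted ground truth.
#'
#' @param seed RNG seed driving every generator.
#' @param outdir directory to write inputs into (created if needed).
#' @return list with \code{config} (pipeline configuration list) and
#'   \code{ledger}.
#' @export
simulatePaperlike <- function(seed = 7L, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(seed)
  intersection <- sprintf("GENE%04d", 1:200)
  diseaseOnly <- sprintf("GENE%04d", 201:500)
  drugOnly <- sprintf("GENE%04d", 501:700)

  ing <- genIngredients(nHerbs = 10L, nPerHerb = 12L, fracPass = 0.4,
                        seed = seed + 1L)
  active <- ing$table$molecule_id %in% ing$ledger$passSet
  tmap <- genTargetMap(ing$table$molecule_id,
                       genePool = c(intersection, drugOnly),
                       targetsPerMol = c(5L, 20L), seed = seed + 2L,
                       cover = ing$table$molecule_id[active])
  dis <- genDiseaseSources(nSources = 5L, unionSize = 500L,
                           redundancy = 0.3, seed = seed + 3L,
                           genes = c(intersection, diseaseOnly),
                           labels = c("genecards", "drugbank", "omim",
                                      "pharmgkb", "ttd"))
  ppi <- genPPI(nBackground = 170L, moduleSize = 30L, pModule = 0.8,
                pBackground = 0.05, pCross = 0.02, seed = seed + 4L,
                nodes = intersection)
  ann <- genAnnotations(universe = intersection, query = ppi$ledger$module,
                        nTerms = 50L, termSizeRange = c(10L, 40L),
                        plantedOverlap = 0.8, planted = TRUE,
                        seed = seed + 5L)
  de <- genDETable(nGenes = 15000L, nUp = 141L, nDown = 643L,
                   seed = seed + 6L)

  paths <- list(
    ingredients = file.path(outdir, "ingredients.tsv"),
    targets = file.path(outdir, "targets.tsv"),
    disease_lists = file.path(outdir,
                              paste0("disease_", names(dis$sources), ".txt")),
    ppi_edges = file.path(outdir, "ppi_edges.tsv"),
    gmt = file.path(outdir, "annotations.gmt"),
    de_table = file.path(outdir, "de_table.tsv")
  )
  writeIngredientTable(ing$table, paths$ingredients)
  writeTargetMap(tmap$table, paths$targets)
  for (i in seq_along(dis$sources))
    writeLines(dis$sources[[i]], paths$disease_lists[i])
  writeWeightedEdges(ppi$edges, paths$ppi_edges)
  writeGMT(ann$annotations, paths$gmt)
  writeDETable(de$table, paths$de_table)

  # generator-side bookkeeping of what each deterministic stage must find
  activeMols <- ing$ledger$passSet
  perMol <- tmap$ledger$perMolecule[activeMols]
  hitMols <- activeMols[vapply(perMol, function(g)
    length(intersect(g, intersection)) > 0L, logical(1))]
  ledger <- list(
    seed = seed,
    nIngredients = nrow(ing$table),
    nActive = ing$ledger$nPass,
    passSet = ing$ledger$passSet,
    drugTargetUnion = tmap$ledger$union,
    nDrugTargets = length(tmap$ledger$union),
    diseaseUnion = dis$ledger$union,
    nDiseaseGenes = dis$ledger$unionSize,
    perSource = as.list(dis$ledger$perSource),
    intersection = sort(intersection),
    nPutative = length(intersection),
    ppiModule = ppi$ledger$module,
    nPPIEdges = ppi$ledger$nEdges,
    ppiNodesWithEdge = ppi$ledger$nodesWithEdge,
    nHITIngredients = length(hitMols),
    plantedTerm = ann$ledger$plantedTerm,
    nUp = de$ledger$nUp,
    nDown = de$ledger$nDown
  )
  jsonlite::write_json(ledger, file.path(outdir, "ledger.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  config <- list(
    inputs = list(
      ingredients = paths$ingredients,
      targets = paths$targets,
      disease_lists = paths$disease_lists,
      ppi_edges = paths$ppi_edges,
      gmt = paths$gmt,
      de_table = paths$de_table
    ),
    thresholds = list(ob_min = 20, dl_min = 0.1, ppi_confidence = 0.7,
                      filter_rounds = 2L, alpha = 0.05, padj_max = 0.05,
                      lfc_min = 1),
    outdir = file.path(outdir, "results")
  )
  yaml::write_yaml(config, file.path(outdir, "config.yaml"))
  list(config = config, ledger = ledger)
}
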