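# End-to-end orchestration: screen -> map -> merge -> intersect -> HIT
# network -> PPI -> centralities -> hubs -> enrichment (-> DEG filter when a
# DE table is supplied), from a single config.

.defaultThresholds <- list(ob_min = 20, dl_min = 0.1, ppi_confidence = 0.7,
                           filter_rounds = 2L, alpha = 0.05,
                           padj_max = 0.05, lfc_min = 1)

.validateThresholds <- function(th) {
  th <- utils::modifyList(.defaultThresholds, th)
  stopifnot(th$ob_min >= 0, th$ob_min <= 100,
            th$dl_min >= 0, th$dl_min <= 1,
            th$ppi_confidence >= 0, th$ppi_confidence <= 1,
            th$filter_rounds >= 0,
            th$alpha > 0, th$alpha <= 1,
            th$padj_max > 0, th$padj_max <= 1,
            th$lfc_min >= 0)
  th
}

#' Run the full network-pharmacology pipeline
#'
#' Executes every stage from a configuration (a list, or the path of a YAML
#' file with the same structure): ingredient screening, target mapping,
#' disease-source merging and Venn partitioning, drug-disease intersection,
#' HIT network construction, PPI graph building, centrality computation,
#' iterative hub extraction, over-representation analysis of the hubs and —
#' when a DE table is configured — DEG threshold classification. All
#' intermediate artifacts are written under \code{outdir}; a failing stage
#' aborts with the stage name and leaves a \code{FAILED} marker next to the
#' partial outputs. The run report (stage counts, config echo, package
#' version) is returned and written as \code{report.json}; it contains no
#' timestamp, so identical inputs give byte-identical reports.
#'
#' @param config list with elements \code{inputs} (paths:
#'   \code{ingredients}, \code{targets}, optional \code{symbol_map},
#'   \code{disease_lists} (vector), \code{ppi_edges}, \code{gmt}, optional
#'   \code{de_table}), optional \code{thresholds} (\code{ob_min},
#'   \code{dl_min}, \code{ppi_confidence}, \code{filter_rounds},
#'   \code{alpha}, \code{padj_max}, \code{lfc_min}; defaults 20, 0.1, 0.7,
#'   2, 0.05, 0.05, 1) and \code{outdir}; or the path of a YAML file.
#' @param quiet suppress stage progress messages (default FALSE).
#' @return the run report, a nested list (invisibly).
#' @export
runPipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$inputs),
            !is.null(config$outdir))
  th <- .validateThresholds(config$thresholds %||% list())
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  failedMarker <- file.path(outdir, "FAILED")
  if (file.exists(failedMarker)) unlink(failedMarker)

  note <- function(...) if (!quiet) message("[netpharm] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(paste0("stage ", name, ": ", conditionMessage(e)),
                 failedMarker)
      stop("stage ", name, ": ", conditionMessage(e), call. = FALSE)
    })
  }
  inp <- config$inputs
  report <- list(package = "netpharm",
                 version = as.character(utils::packageVersion("netpharm")),
                 config = list(inputs = inp, thresholds = th,
                               outdir = outdir))

  ingredients <- stage("screen", {
    tab <- readIngredientTable(inp$ingredients)
    screened <- screenIngredients(tab, obMin = th$ob_min, dlMin = th$dl_min)
    writeIngredientTable(screened, file.path(outdir, "screened.tsv"))
    note("screen: ", nrow(screened), "/", nrow(tab), " ingredients retained")
    report$screen <- list(n_in = nrow(tab), n_active = nrow(screened))
    screened
  })

  active <- stage("map-targets", {
    tmap <- readTargetMap(inp$targets)
    smap <- if (!is.null(inp$symbol_map)) readSymbolMap(inp$symbol_map)
    acs <- mapTargets(ingredients, tmap, symbolMap = smap)
    writeGeneList(targetUnion(acs), file.path(outdir, "drug_targets.txt"))
    note("map-targets: ", length(targetUnion(acs)), " target genes, ",
         length(flaggedComponents(acs)), " flagged molecules")
    report$targets <- list(n_union = length(targetUnion(acs)),
                            n_flagged = length(flaggedComponents(acs)))
    acs
  })

  disease <- stage("disease-merge", {
    paths <- inp$disease_lists
    if (!length(paths)) stop("no disease lists configured", call. = FALSE)
    sets <- lapply(paths, function(p)
      readGeneList(p, source = sub("\\.[^.]*$", "", basename(p))))
    merged <- mergeGeneSets(sets, name = "disease_genes")
    writeGeneList(merged, file.path(outdir, "disease_union.txt"))
    if (length(sets) >= 2L && length(sets) <= 6L) {
      vp <- vennPartition(sets)
      writeTable(data.frame(region = names(vp$counts),
                            count = as.integer(vp$counts)),
                 file.path(outdir, "venn.tsv"))
      report$venn <- as.list(vp$counts)
    }
    note("disease-merge: ", length(merged), " genes from ",
         length(sets), " sources")
    report$disease <- list(n_sources = length(sets),
                            n_union = length(merged))
    merged
  })

  putative <- stage("intersect", {
    drugSet <- GeneSet(targetUnion(active), name = "drug_targets")
    ps <- intersectDrugDisease(drugSet, disease)
    writeGeneList(ps, file.path(outdir, "putative_targets.txt"))
    note("intersect: ", length(ps), " putative targets")
    report$intersection <- list(n_putative = length(ps))
    ps
  })

  hit <- stage("hit-network", {
    net <- buildHITNetwork(active, putative)
    writeGraphFile(net, file.path(outdir, "hit_network.graphml"), "graphml")
    perHerb <- herbTargetPartition(net)
    writeTable(data.frame(herb_id = names(perHerb),
                          n_targets = lengths(perHerb),
                          targets = vapply(perHerb, paste,
                                           character(1), collapse = ",")),
               file.path(outdir, "herb_targets.tsv"))
    note("hit-network: ", length(herbNodes(net)), " herbs, ",
         length(ingredientNodes(net)), " ingredients, ",
         length(geneNodes(net)), " genes")
    report$hit <- list(n_herbs = length(herbNodes(net)),
                        n_ingredients = length(ingredientNodes(net)),
                        n_genes = length(geneNodes(net)))
    net
  })

  graph <- stage("ppi", {
    edges <- readWeightedEdges(inp$ppi_edges,
                               threshold = th$ppi_confidence)
    g <- buildPPI(edges, restrictTo = putative)
    writeGraphFile(g, file.path(outdir, "ppi_network.graphml"), "graphml")
    note("ppi: ", numNodes(g), " nodes, ", numEdges(g), " edges")
    report$ppi <- list(n_nodes = numNodes(g), n_edges = numEdges(g))
    g
  })

  hubs <- stage("hubs", {
    ct <- centralityTable(graph)
    writeTable(as.data.frame(ct), file.path(outdir, "centrality.tsv"))
    res <- extractHubs(graph, rounds = th$filter_rounds)
    writeGeneList(res$hubs, file.path(outdir, "hub_genes.txt"))
    writeTable(filterReportTable(res$reports),
               file.path(outdir, "filter_report.tsv"))
    note("hubs: ", length(res$hubs), " hub genes (stop: ",
         res$stopReason, ")")
    report$hubs <- list(
      n_hubs = length(res$hubs), stop_reason = res$stopReason,
      rounds = lapply(res$reports, function(r)
        list(round = r$round, n_in = r$nIn, n_out = r$nOut,
             medians = as.list(r$medians))))
    res$hubs
  })

  stage("enrich", {
    ann <- readGMT(inp$gmt)
    et <- enrich(hubs, ann, alpha = th$alpha)
    writeTable(et, file.path(outdir, "enrichment.tsv"))
    nSig <- sum(et$significant)
    note("enrich: ", nSig, "/", nrow(et), " terms significant")
    report$enrichment <- list(
      n_terms = nrow(et), n_significant = nSig,
      top_term = et$term_id[1L])
    invisible(NULL)
  })

  stage("representatives", {
    reps <- representativeComponents(active, hubs)
    writeTable(reps, file.path(outdir, "representatives.tsv"))
    report$representatives <- list(n_herbs = nrow(reps))
    invisible(NULL)
  })

  if (!is.null(inp$de_table)) {
    stage("deg-filter", {
      de <- readDETable(inp$de_table)
      res <- callDEGs(de, padjMax = th$padj_max, lfcMin = th$lfc_min)
      writeTable(res$calls, file.path(outdir, "deg_calls.tsv"))
      writeTable(data.frame(t(res$summary)),
                 file.path(outdir, "deg_summary.tsv"))
      note("deg-filter: ", res$summary[["n_up"]], " up, ",
           res$summary[["n_down"]], " down")
      report$deg <- as.list(res$summary)
      invisible(NULL)
    })
  }

  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
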