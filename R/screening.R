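# Active-ingredient screening and ingredient -> target mapping.

#' Screen ingredients by oral bioavailability and drug-likeness
#'
#' Retains rows with \code{ob >= obMin} and \code{dl >= dlMin}; both bounds
#' are inclusive ("greater or equal"), so a boundary ingredient with
#' OB = 20 and DL = 0.1 passes under the defaults. Row order is preserved.
#' A per-herb kept/dropped report is attached as attribute
#' \code{"screen_report"}.
#'
#' @param tab validated ingredient table
#'   (see \code{\link{readIngredientTable}}).
#' @param obMin minimum oral bioavailability, percent (default 20).
#' @param dlMin minimum drug-likeness, unitless (default 0.1).
#' @return the retained rows, same columns, with the report attribute.
#' @examples
#' tab <- data.frame(herb_id = "H1", molecule_id = c("M1", "M2"),
#'                   molecule_name = "", ob = c(20, 19.99), dl = c(0.1, 0.9))
#' screenIngredients(tab)  # keeps only M1
#' @export
screenIngredients <- function(tab, obMin = 20, dlMin = 0.1) {
  stopifnot(is.data.frame(tab), obMin >= 0, obMin <= 100,
            dlMin >= 0, dlMin <= 1)
  keep <- tab$ob >= obMin & tab$dl >= dlMin
  out <- tab[keep, , drop = FALSE]
  rownames(out) <- NULL
  herbs <- unique(tab$herb_id)
  report <- data.frame(
    herb_id = herbs,
    n_in = vapply(herbs, function(h) sum(tab$herb_id == h), integer(1)),
    n_kept = vapply(herbs, function(h) sum(keep & tab$herb_id == h),
                    integer(1)),
    stringsAsFactors = FALSE
  )
  report$n_dropped <- report$n_in - report$n_kept
  attr(out, "screen_report") <- report
  out
}

#' Map screened ingredients to per-herb target gene sets
#'
#' Joins the active ingredient table with an ingredient-to-target table.
#' Targets already carrying a gene symbol are used directly; otherwise the
#' free-text target name is looked up in \code{symbolMap}. Target names that
#' stay unmapped are dropped with a logged count. Molecules with zero mapped
#' targets are kept in the component list but flagged.
#'
#' @param active screened ingredient table (output of
#'   \code{\link{screenIngredients}}).
#' @param targets target map data.frame (see \code{\link{readTargetMap}}).
#' @param symbolMap optional named character vector target name -> symbol
#'   (see \code{\link{readSymbolMap}}).
#' @return an \linkS4class{ActiveComponentSet}.
#' @export
mapTargets <- function(active, targets, symbolMap = NULL) {
  stopifnot(is.data.frame(active), is.data.frame(targets))
  sym <- targets$gene_symbol
  needMap <- !nzchar(sym)
  if (any(needMap) && !is.null(symbolMap)) {
    looked <- unname(symbolMap[targets$target_name[needMap]])
    looked[is.na(looked)] <- ""
    sym[needMap] <- toupper(looked)
  }
  unmapped <- sum(!nzchar(sym))
  if (unmapped)
    message("mapTargets: dropped ", unmapped,
            " target row(s) without a gene symbol")
  tmap <- split(sym[nzchar(sym)], targets$molecule_id[nzchar(sym)])
  tmap <- lapply(tmap, function(x) sort(unique(x)))

  mols <- unique(active$molecule_id)
  componentTargets <- stats::setNames(
    lapply(mols, function(m) if (m %in% names(tmap)) tmap[[m]]
           else character()),
    mols)
  herbComponents <- lapply(split(active$molecule_id, active$herb_id), unique)
  flagged <- mols[lengths(componentTargets) == 0L]
  if (length(flagged))
    message("mapTargets: ", length(flagged),
            " molecule(s) have no mapped target (flagged)")
  unionTargets <- sort(unique(unlist(componentTargets, use.names = FALSE)))
  if (!length(unionTargets))
    stop("no ingredient maps to any gene symbol: empty target union",
         call. = FALSE)
  new("ActiveComponentSet", herbComponents = herbComponents,
      componentTargets = componentTargets, flagged = flagged,
      unionTargets = unionTargets)
}

#' Per-herb target gene sets of an ActiveComponentSet
#'
#' @param acs an \linkS4class{ActiveComponentSet}.
#' @return named list herb_id -> sorted gene symbols (union over the herb's
#'   components).
#' @export
herbTargetSets <- function(acs) {
  stopifnot(is(acs, "ActiveComponentSet"))
  lapply(acs@herbComponents, function(mols)
    sort(unique(unlist(acs@componentTargets[mols], use.names = FALSE))))
}
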