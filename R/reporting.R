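#' @include AllClasses.R connectome-io.R stability.R synthetic.R
NULL

#' Pairwise squared correlations between microstructural indices
#'
#' Concatenates the raw (unstandardised) edge values of each index panel
#' across all subjects into one long vector and reports the squared Pearson
#' correlation for every index pair.  R-squared is sign-blind, so an index
#' anti-correlated with another still scores high.  All panels must be
#' restricted to the same jointly retained edge set and subject order.
#'
#' @param panels named list of unstandardised [ConnectomePanel-class]
#'   objects, one per index, with identical edge rows and subject columns.
#' @return an [IndexCorrelationTable-class].
#' @export
pairwiseR2 <- function(panels) {
  if (length(panels) < 2L) stop("need at least two index panels")
  if (is.null(names(panels))) stop("panels must be named by index")
  ref <- rownames(panels[[1L]]@values)
  refSub <- colnames(panels[[1L]]@values)
  for (p in panels) {
    if (!identical(rownames(p@values), ref))
      stop("all panels must share the same retained edge set")
    if (!identical(colnames(p@values), refSub))
      stop("all panels must share the subject order")
    if (isTRUE(p@standardized))
      stop("pairwise R^2 uses raw values; per-edge standardisation would ",
           "distort cross-index relationships")
  }
  nIdx <- length(panels)
  r2 <- matrix(1, nIdx, nIdx, dimnames = list(names(panels), names(panels)))
  for (i in seq_len(nIdx - 1L)) {
    for (j in (i + 1L):nIdx) {
      r <- stats::cor(as.vector(panels[[i]]@values),
                      as.vector(panels[[j]]@values))
      r2[i, j] <- r2[j, i] <- r^2
    }
  }
  new("IndexCorrelationTable", r2 = r2,
      nPoints = as.integer(length(ref) * length(refSub)))
}

#' Hemispheric fingerprint of selected edges
#'
#' Counts and fractions of the above-chance-selected edges per hemispheric
#' class (intra-left, intra-right, interhemispheric).  This is the summary
#' that distinguishes indices whose structure-function coupling is carried
#' by intra-hemispheric connections from those dominated by
#' interhemispheric ones.
#'
#' @param decision a [SelectionDecision-class].
#' @param idx an [EdgeIndex-class] covering the decision's edges.
#' @return data.frame with columns `hemiclass`, `count`, `fraction`.
#' @export
hemisphericSummary <- function(decision, idx) {
  classes <- c("intra-left", "intra-right", "inter")
  hc <- hemiClass(idx)
  sel <- decision@selected
  if (length(setdiff(sel, names(hc))))
    stop("decision contains edges absent from the edge index")
  counts <- vapply(classes, function(cl) sum(hc[sel] == cl), integer(1L))
  frac <- if (length(sel)) counts / length(sel) else rep(0, 3L)
  data.frame(hemiclass = classes, count = as.integer(counts),
             fraction = as.numeric(frac), row.names = NULL)
}

#' Export a selection-probability map
#'
#' Writes the per-edge selection probabilities back into a symmetric
#' region-by-region matrix, ordered left-hemisphere regions first and then
#' right, so the bottom-left quadrant holds intra-left connections, the
#' top-right quadrant intra-right, and the off-quadrants the
#' interhemispheric ones.  Edges never available in any resample are marked
#' missing.
#'
#' @param res a [StabilityResult-class].
#' @param idx the [EdgeIndex-class] used for the run.
#' @param path optional TSV output path.
#' @param panel `"structural"` or `"functional"`.
#' @return the probability map as a [ConnectivityMatrix-class] (invisibly
#'   when writing).
#' @export
exportProbabilityMap <- function(res, idx, path = NULL,
                                 panel = c("structural", "functional")) {
  panel <- match.arg(panel)
  prob <- selectionProbabilities(res, panel)
  tested <- if (panel == "structural") res@testedX else res@testedY
  prob[tested == 0L] <- NA_real_
  cm <- devectorizeEdges(prob, idx, modality = "probability",
                         subject = paste0(panel, "-probability"))
  ord <- order(match(idx@atlas@hemisphere, c("left", "right")))
  v <- cm@values[ord, ord]
  miss <- cm@missing[ord, ord]
  cm <- new("ConnectivityMatrix", values = v,
            atlas = regionAtlas(idx@atlas@labels[ord]),
            modality = "probability",
            subject = paste0(panel, "-probability"), missing = miss)
  if (!is.null(path)) {
    writeConnectome(cm, path)
    return(invisible(cm))
  }
  cm
}

#' Export selected edges as a GraphML graph
#'
#' @param decision a [SelectionDecision-class].
#' @param idx the [EdgeIndex-class] for the atlas.
#' @param path GraphML output path.
#' @return `path`, invisibly.
#' @export
exportSelectedGraph <- function(decision, idx, path) {
  labs <- idx@atlas@labels
  sel <- match(decision@selected, idx@labels)
  el <- cbind(labs[idx@from[sel]], labs[idx@to[sel]])
  g <- igraph::graph_from_data_frame(
    as.data.frame(el, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = labs,
                          hemisphere = idx@atlas@hemisphere,
                          stringsAsFactors = FALSE))
  prob <- decision@table$probability[match(decision@selected,
                                           decision@table$edge)]
  igraph::E(g)$probability <- prob
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Run the full coupling pipeline
#'
#' Drives simulate/load, panel assembly, bootstrap stability selection,
#' binomial accept/reject decisions and report export for one or more
#' (structural index, functional modality) pairs.  The configuration is a
#' list (or YAML file) with blocks:
#' \describe{
#'   \item{simulate}{synthetic scenario parameters, see [syntheticConfig()];
#'     or instead}
#'   \item{inputs}{named lists of file paths per modality, read with
#'     [readConnectome()]}
#'   \item{stability}{`B`, `alpha`, `seed` and sparse-CCA settings}
#'   \item{output}{directory for TSV maps, decision tables and the JSON
#'     summary (omit to skip writing)}
#' }
#'
#' @param config a list or path to a YAML file.
#' @return a result bundle: per pair, the [StabilityResult-class], the
#'   [SelectionDecision-class], the fingerprint and the summary list.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stab <- config$stability
  scfg <- sccaConfig(cU = stab$cU %||% 2.4, cV = stab$cV %||% 2.4,
                     weakness = stab$weakness %||% 0.6)
  sconf <- stabilityConfig(B = stab$B %||% 1000L,
                           alpha = stab$alpha %||% 0.05,
                           seed = stab$seed %||% 1L, scca = scfg)

  if (!is.null(config$simulate)) {
    sim <- config$simulate
    cfg <- syntheticConfig(m = sim$m %||% 17L, n = sim$n %||% 68L,
                           sX = sim$sX %||% 10L, sY = sim$sY %||% 10L,
                           coupling = sim$coupling %||% 3,
                           missingRate = sim$missingRate %||% 0.05,
                           interOdds = sim$interOdds %||% 1,
                           seed = sim$seed %||% sconf$seed)
    panels <- generateCoupledPanels(cfg)
    stacks <- generateConnectomeStacks(cfg, panels)
    pairs <- list(list(name = "synthetic",
                       structural = stacks$structural,
                       functional = stacks$functional,
                       idx = panels$edgeIndex))
  } else if (!is.null(config$inputs)) {
    inp <- config$inputs
    readStack <- function(files, modality)
      lapply(files, readConnectome, modality = modality)
    pairs <- list()
    for (sIdx in names(inp$structural)) {
      for (fMod in names(inp$functional)) {
        sStack <- readStack(inp$structural[[sIdx]], sIdx)
        fStack <- readStack(inp$functional[[fMod]], fMod)
        idx <- buildEdgeIndex(sStack[[1L]]@atlas)
        pairs[[length(pairs) + 1L]] <-
          list(name = paste(sIdx, fMod, sep = "-"),
               structural = sStack, functional = fStack, idx = idx)
      }
    }
  } else stop("config needs a 'simulate' or an 'inputs' block")

  outDir <- config$output
  if (!is.null(outDir) && !dir.exists(outDir))
    dir.create(outDir, recursive = TRUE)

  bundle <- list()
  for (pair in pairs) {
    res <- bootstrapStability(pair$structural, pair$functional, sconf,
                              idx = pair$idx)
    decision <- classifyEdges(res, alpha = sconf$alpha)
    fp <- hemisphericSummary(decision, pair$idx)
    summary <- list(pair = pair$name,
                    B = res@B,
                    pChance = chanceProbability(res),
                    meanAvailable = mean(res@availablePerIter),
                    meanSelected = mean(res@selectedPerIter),
                    nSelected = length(decision@selected),
                    nRejected = length(decision@rejected),
                    nUndetermined = length(decision@undetermined),
                    fingerprint = fp)
    if (!is.null(outDir)) {
      base <- file.path(outDir, pair$name)
      exportProbabilityMap(res, pair$idx,
                           path = paste0(base, "-probability-map.tsv"))
      utils::write.table(decisionTable(decision),
                         paste0(base, "-decisions.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      jsonlite::write_json(summary, paste0(base, "-summary.json"),
                           auto_unbox = TRUE, digits = NA, dataframe = "rows")
    }
    bundle[[pair$name]] <- list(stability = res, decision = decision,
                                fingerprint = fp, summary = summary)
  }
  bundle
}

`%||%` <- function(a, b) if (is.null(a)) b else a
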