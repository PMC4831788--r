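#' @include AllGenerics.R
NULL

#' Accessors for sfCCA classes
#'
#' Small accessor layer over the S4 value classes; user code should prefer
#' these over direct slot access.
#'
#' @param x an sfCCA object.
#' @param panel which side of the fit: structural (X) or functional (Y).
#' @param ... unused.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("regionLabels", "RegionAtlas", function(x) x@labels)
#' @rdname accessors
#' @export
setMethod("regionLabels", "ConnectivityMatrix", function(x) x@atlas@labels)
#' @rdname accessors
#' @export
setMethod("hemisphere", "RegionAtlas", function(x) {
  stats::setNames(x@hemisphere, x@labels)
})
#' @rdname accessors
#' @export
setMethod("nRegions", "RegionAtlas", function(x) length(x@labels))
#' @rdname accessors
#' @export
setMethod("nRegions", "ConnectivityMatrix", function(x) length(x@atlas@labels))
#' @rdname accessors
#' @export
setMethod("connValues", "ConnectivityMatrix", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("missingMask", "ConnectivityMatrix", function(x) x@missing)
#' @rdname accessors
#' @export
setMethod("modality", "ConnectivityMatrix", function(x) x@modality)
#' @rdname accessors
#' @export
setMethod("modality", "ConnectomePanel", function(x) x@modality)
#' @rdname accessors
#' @export
setMethod("subjectID", "ConnectivityMatrix", function(x) x@subject)
#' @rdname accessors
#' @export
setMethod("edgeLabels", "EdgeIndex", function(x) x@labels)
#' @rdname accessors
#' @export
setMethod("edgeLabels", "ConnectomePanel", function(x) rownames(x@values))
#' @rdname accessors
#' @export
setMethod("hemiClass", "EdgeIndex", function(x) {
  stats::setNames(x@hemiclass, x@labels)
})
#' @rdname accessors
#' @export
setMethod("hemiClass", "ConnectomePanel", function(x) {
  stats::setNames(x@hemiclass, rownames(x@values))
})
#' @rdname accessors
#' @export
setMethod("panelValues", "ConnectomePanel", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("subjects", "ConnectomePanel", function(x) colnames(x@values))
#' @rdname accessors
#' @export
setMethod("isStandardized", "ConnectomePanel", function(x) x@standardized)
#' @rdname accessors
#' @export
setMethod("canonicalU", "SccaFit", function(x) x@u)
#' @rdname accessors
#' @export
setMethod("canonicalV", "SccaFit", function(x) x@v)
#' @rdname accessors
#' @export
setMethod("canonicalCor", "SccaFit", function(x) x@rho)

#' @rdname accessors
#' @export
setMethod("selectionCounts", "StabilityResult", function(x, panel) {
  panel <- match.arg(panel, c("structural", "functional"))
  if (panel == "structural") x@countsX else x@countsY
})

#' @rdname accessors
#' @export
setMethod("selectionProbabilities", "StabilityResult", function(x, panel) {
  panel <- match.arg(panel, c("structural", "functional"))
  counts <- if (panel == "structural") x@countsX else x@countsY
  counts / x@B
})

#' @rdname accessors
#' @export
setMethod("chanceProbability", "StabilityResult", function(x, ...) x@pChance)

#' @rdname accessors
#' @export
setMethod("selectedEdges", "SelectionDecision", function(x) x@selected)
#' @rdname accessors
#' @export
setMethod("rejectedEdges", "SelectionDecision", function(x) x@rejected)
#' @rdname accessors
#' @export
setMethod("decisionTable", "SelectionDecision", function(x) x@table)

#' @rdname accessors
#' @export
setMethod("show", "RegionAtlas", function(object) {
  h <- table(factor(object@hemisphere, c("left", "right")))
  cat(sprintf("RegionAtlas with %d regions (%d left, %d right)\n",
              length(object@labels), h[["left"]], h[["right"]]))
  cat("  labels:", paste(utils::head(object@labels, 4L), collapse = ", "),
      if (length(object@labels) > 4L) "..." else "", "\n")
})

#' @rdname accessors
#' @export
setMethod("show", "ConnectivityMatrix", function(object) {
  n <- nRegions(object)
  nmiss <- sum(object@missing[upper.tri(object@missing)])
  cat(sprintf("ConnectivityMatrix [%s] subject '%s': %d x %d, %d missing edge(s)\n",
              object@modality, object@subject, n, n, nmiss))
})

#' @rdname accessors
#' @export
setMethod("show", "EdgeIndex", function(object) {
  cat(sprintf("EdgeIndex over %d regions: %d edges (%d intra-left, %d intra-right, %d inter)\n",
              length(object@atlas@labels), length(object@from),
              sum(object@hemiclass == "intra-left"),
              sum(object@hemiclass == "intra-right"),
              sum(object@hemiclass == "inter")))
})

#' @rdname accessors
#' @export
setMethod("show", "ConnectomePanel", function(object) {
  cat(sprintf("ConnectomePanel [%s]: %d edges x %d subjects, %sstandardised\n",
              object@modality, nrow(object@values), ncol(object@values),
              if (object@standardized) "" else "not "))
})

#' @rdname accessors
#' @export
setMethod("show", "SccaFit", function(object) {
  cat(sprintf("SccaFit: |supp(u)| = %d, |supp(v)| = %d, rho = %.4f, %s in %d iteration(s)\n",
              sum(object@u != 0), sum(object@v != 0), object@rho,
              if (object@converged) "converged" else "NOT converged",
              object@iterations))
})

#' @rdname accessors
#' @export
setMethod("show", "StabilityResult", function(object) {
  cat(sprintf("StabilityResult: B = %d bootstrap iterations\n", object@B))
  cat(sprintf("  structural edges: %d tested at least once; available %.1f +/- %.1f, selected %.1f +/- %.1f per iteration\n",
              sum(object@testedX > 0L), mean(object@availablePerIter),
              stats::sd(object@availablePerIter), mean(object@selectedPerIter),
              stats::sd(object@selectedPerIter)))
  cat(sprintf("  chance probability: %.4f\n", object@pChance))
})

#' @rdname accessors
#' @export
setMethod("show", "SelectionDecision", function(object) {
  cat(sprintf("SelectionDecision (B = %d, p0 = %.4f, alpha = %.3f): kLo = %s, kHi = %s\n",
              object@B, object@pChance, object@alpha,
              ifelse(is.na(object@kLo), "none", object@kLo),
              ifelse(is.na(object@kHi), "none", object@kHi)))
  cat(sprintf("  %d selected / %d rejected / %d undetermined\n",
              length(object@selected), length(object@rejected),
              length(object@undetermined)))
})

#' @rdname accessors
#' @export
setMethod("show", "IndexCorrelationTable", function(object) {
  cat(sprintf("IndexCorrelationTable over %d (edge, subject) points\n",
              object@nPoints))
  print(round(object@r2, 3))
})
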