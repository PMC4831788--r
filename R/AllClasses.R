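#' @import methods
NULL

## Modality vocabulary used throughout: functional connectomes (fMRI and the
## five electrophysiological bands) and the seven structural edge weightings.
.FUNCTIONAL_MODALITIES <- c("fMRI", "delta", "theta", "alpha", "beta", "gamma")
.STRUCTURAL_MODALITIES <- c("NSTREAMS", "WFA", "WMD", "WICVF", "WISO", "WODI",
                            "Wkappa")
.ALL_MODALITIES <- c(.FUNCTIONAL_MODALITIES, .STRUCTURAL_MODALITIES)

#' Region atlas
#'
#' An ordered set of cortical region labels with a hemisphere tag per region,
#' parsed from the `lh_`/`rh_` naming convention (configurable for other
#' atlases), and optionally a per-region size in voxels.
#'
#' @slot labels character vector of unique region names, in matrix order.
#' @slot hemisphere character vector, one of `"left"`/`"right"` per region.
#' @slot size integer vector of per-region voxel counts (`NA` when unknown).
#' @export
setClass("RegionAtlas",
  representation(labels = "character", hemisphere = "character",
                 size = "integer"))

setValidity("RegionAtlas", function(object) {
  msg <- character()
  if (anyDuplicated(object@labels))
    msg <- c(msg, "region labels must be unique")
  if (length(object@hemisphere) != length(object@labels))
    msg <- c(msg, "hemisphere must have one tag per label")
  if (!all(object@hemisphere %in% c("left", "right")))
    msg <- c(msg, "hemisphere tags must be 'left' or 'right'")
  if (length(object@size) != length(object@labels))
    msg <- c(msg, "size must have one entry per label")
  if (any(!is.na(object@size) & object@size <= 0L))
    msg <- c(msg, "region sizes must be positive")
  if (length(msg)) msg else TRUE
})

#' Single-subject connectivity matrix
#'
#' A symmetric region-by-region graph for one subject and one modality or
#' microstructural index.  Missing connections are carried as an explicit
#' symmetric mask, never as zeros: microstructural averages are undefined on
#' empty tracts.
#'
#' @slot values numeric n-by-n matrix; entries under the missing mask are `NA`.
#' @slot atlas a [RegionAtlas-class] describing the rows/columns.
#' @slot modality character tag, e.g. `"fMRI"`, `"alpha"`, `"WFA"`.
#' @slot subject subject identifier.
#' @slot missing logical n-by-n symmetric mask of undefined connections.
#' @export
setClass("ConnectivityMatrix",
  representation(values = "matrix", atlas = "RegionAtlas",
                 modality = "character", subject = "character",
                 missing = "matrix"))

setValidity("ConnectivityMatrix", function(object) {
  n <- length(object@atlas@labels)
  v <- object@values
  msg <- character()
  if (!is.numeric(v) || nrow(v) != n || ncol(v) != n)
    msg <- c(msg, sprintf("values must be a numeric %d x %d matrix", n, n))
  if (!is.logical(object@missing) || !identical(dim(object@missing), dim(v)))
    msg <- c(msg, "missing must be a logical matrix matching values")
  else {
    if (!identical(object@missing, t(object@missing)))
      msg <- c(msg, "missing mask must be symmetric")
    off <- upper.tri(v)
    def <- off & !object@missing
    if (any(!is.finite(v[def])))
      msg <- c(msg, "defined off-diagonal values must be finite")
    if (is.numeric(v) && any(abs(v[def] - t(v)[def]) > 1e-6, na.rm = TRUE))
      msg <- c(msg, "values must be symmetric where defined")
  }
  if (length(object@modality) != 1L)
    msg <- c(msg, "modality must be a single tag")
  if (length(msg)) msg else TRUE
})

#' Canonical edge enumeration for an atlas
#'
#' All unordered region pairs (i < j) in row-major upper-triangle order, each
#' tagged by hemispheric class: within the left hemisphere, within the right,
#' or interhemispheric.
#'
#' @slot from,to integer region indices with `from < to`.
#' @slot labels character edge labels, `"<regionA>--<regionB>"`.
#' @slot hemiclass character, `"intra-left"`, `"intra-right"` or `"inter"`.
#' @slot atlas the [RegionAtlas-class] the pairs index into.
#' @export
setClass("EdgeIndex",
  representation(from = "integer", to = "integer", labels = "character",
                 hemiclass = "character", atlas = "RegionAtlas"))

setValidity("EdgeIndex", function(object) {
  n <- length(object@atlas@labels)
  k <- n * (n - 1L) / 2L
  msg <- character()
  if (length(object@from) != k || length(object@to) != k)
    msg <- c(msg, sprintf("edge index must enumerate all %d pairs", k))
  if (any(object@from >= object@to))
    msg <- c(msg, "pairs must satisfy from < to")
  hemi <- object@atlas@hemisphere
  inter <- hemi[object@from] != hemi[object@to]
  if (!all((object@hemiclass == "inter") == inter))
    msg <- c(msg, "hemiclass 'inter' must match hemisphere tags")
  if (length(msg)) msg else TRUE
})

#' Edge-by-subject data panel
#'
#' The k-by-m matrix fed to sparse CCA: one row per retained connection, one
#' column per subject.  Rows are a subset of a canonical [EdgeIndex-class];
#' after standardisation each row has zero mean and unit sample standard
#' deviation (denominator m - 1).
#'
#' @slot values numeric k-by-m matrix with edge labels as rownames and subject
#'   identifiers as colnames.
#' @slot hemiclass hemispheric class per retained edge.
#' @slot modality modality/index tag of the source connectomes.
#' @slot standardized logical flag.
#' @export
setClass("ConnectomePanel",
  representation(values = "matrix", hemiclass = "character",
                 modality = "character", standardized = "logical"))

setValidity("ConnectomePanel", function(object) {
  v <- object@values
  msg <- character()
  if (!is.numeric(v) || is.null(rownames(v)) || is.null(colnames(v)))
    msg <- c(msg, "values must be numeric with edge rownames and subject colnames")
  if (anyNA(v))
    msg <- c(msg, "panel must not contain missing values")
  if (length(object@hemiclass) != nrow(v))
    msg <- c(msg, "hemiclass must have one tag per edge row")
  if (isTRUE(object@standardized) && ncol(v) >= 2L) {
    mu <- rowMeans(v)
    sdv <- apply(v, 1L, stats::sd)
    if (any(abs(mu) > 1e-8) || any(abs(sdv - 1) > 1e-8))
      msg <- c(msg, "standardised panel rows must have mean 0 and unit SD")
  }
  if (length(msg)) msg else TRUE
})

#' Rank-1 sparse CCA fit
#'
#' @slot u,v sparse canonical vectors over the structural and functional edge
#'   panels (named by edge).
#' @slot rho Pearson correlation of the two canonical projections across
#'   subjects.
#' @slot iterations number of alternating updates performed.
#' @slot converged logical.
#' @slot objective value of u' X Y' v at the solution.
#' @export
setClass("SccaFit",
  representation(u = "numeric", v = "numeric", rho = "numeric",
                 iterations = "integer", converged = "logical",
                 objective = "numeric"))

setValidity("SccaFit", function(object) {
  msg <- character()
  if (sqrt(sum(object@u^2)) > 1 + 1e-6 || sqrt(sum(object@v^2)) > 1 + 1e-6)
    msg <- c(msg, "canonical vectors must have L2 norm <= 1")
  if (!is.na(object@rho) && abs(object@rho) > 1 + 1e-8)
    msg <- c(msg, "rho must lie in [-1, 1]")
  if (length(msg)) msg else TRUE
})

#' Bootstrap stability-selection result
#'
#' Per-edge selection counts over bootstrap resamples, per-edge counts of
#' iterations in which the edge was available for selection, per-iteration
#' available/selected sizes, and the pooled chance probability
#' mean(selected) / mean(available).
#'
#' @slot countsX,countsY named integer selection counts (structural,
#'   functional).
#' @slot testedX,testedY named integer counts of iterations each edge was
#'   available.
#' @slot loadingSumX,loadingSumY running sums of canonical loadings, for
#'   averaged-weight reporting.
#' @slot availablePerIter,selectedPerIter per-iteration structural panel size
#'   and structural support size.
#' @slot availablePerIterY,selectedPerIterY the functional-panel analogues.
#' @slot pChance pooled chance probability for the structural panel.
#' @slot B number of bootstrap iterations.
#' @slot hemiclassX hemispheric class per structural edge (reporting).
#' @slot droppedConstant number of edge-iteration pairs dropped because the
#'   resampled row was constant.
#' @export
setClass("StabilityResult",
  representation(countsX = "integer", countsY = "integer",
                 testedX = "integer", testedY = "integer",
                 loadingSumX = "numeric", loadingSumY = "numeric",
                 availablePerIter = "integer", selectedPerIter = "integer",
                 availablePerIterY = "integer", selectedPerIterY = "integer",
                 pChance = "numeric", B = "integer",
                 hemiclassX = "character", droppedConstant = "integer"))

setValidity("StabilityResult", function(object) {
  msg <- character()
  if (any(object@countsX > object@testedX))
    msg <- c(msg, "an edge cannot be selected more often than it was tested")
  if (!is.na(object@pChance) && (object@pChance <= 0 || object@pChance >= 1))
    msg <- c(msg, "pChance must lie in (0, 1)")
  if (length(object@availablePerIter) != object@B)
    msg <- c(msg, "one available count per iteration required")
  if (length(msg)) msg else TRUE
})

#' Binomial accept/reject decision over edges
#'
#' Partition of the tested edges into those selected significantly above
#' chance (count >= kHi), rejected significantly below chance (count <= kLo),
#' and undetermined, using exact binomial tails at level alpha.
#'
#' @slot selected,rejected,undetermined character vectors of edge labels.
#' @slot kHi,kLo integer count thresholds (`kHi = NA` when no count reaches
#'   upper-tail significance; `kLo = NA` when none reaches the lower tail).
#' @slot pChance,alpha,B the binomial null parameters.
#' @slot table per-edge data.frame: count, tested, probability, mean loading,
#'   hemiclass, class.
#' @export
setClass("SelectionDecision",
  representation(selected = "character", rejected = "character",
                 undetermined = "character", kHi = "integer", kLo = "integer",
                 pChance = "numeric", alpha = "numeric", B = "integer",
                 table = "data.frame"))

setValidity("SelectionDecision", function(object) {
  msg <- character()
  if (length(intersect(object@selected, object@rejected)))
    msg <- c(msg, "selected and rejected sets must be disjoint")
  if (length(msg)) msg else TRUE
})

#' Ground truth of a synthetic coupled-panel draw
#'
#' @slot supportX,supportY edge labels carrying the latent factor.
#' @slot loadingsX,loadingsY signed loadings on the supported edges.
#' @slot latent per-subject latent scores.
#' @export
setClass("GroundTruth",
  representation(supportX = "character", supportY = "character",
                 loadingsX = "numeric", loadingsY = "numeric",
                 latent = "numeric"))

#' Regional time series
#'
#' @slot data numeric T-by-n matrix (time by region), region labels as
#'   colnames.
#' @slot samplingRate sampling rate in Hz.
#' @slot atlas the [RegionAtlas-class] for the columns.
#' @export
setClass("RegionTimeSeries",
  representation(data = "matrix", samplingRate = "numeric",
                 atlas = "RegionAtlas"))

setValidity("RegionTimeSeries", function(object) {
  msg <- character()
  if (object@samplingRate <= 0)
    msg <- c(msg, "sampling rate must be positive")
  if (ncol(object@data) != length(object@atlas@labels))
    msg <- c(msg, "one column per atlas region required")
  if (length(msg)) msg else TRUE
})

#' Pairwise microstructural index correlation table
#'
#' @slot r2 symmetric matrix of squared Pearson correlations between
#'   concatenated edge-value vectors.
#' @slot nPoints number of (edge, subject) points in each vector.
#' @export
setClass("IndexCorrelationTable",
  representation(r2 = "matrix", nPoints = "integer"))

setValidity("IndexCorrelationTable", function(object) {
  msg <- character()
  if (any(object@r2 < -1e-12 | object@r2 > 1 + 1e-12))
    msg <- c(msg, "R^2 entries must lie in [0, 1]")
  if (max(abs(object@r2 - t(object@r2))) > 1e-12)
    msg <- c(msg, "R^2 table must be symmetric")
  if (length(msg)) msg else TRUE
})
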