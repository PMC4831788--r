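#' @include AllClasses.R connectome-io.R scca.R
NULL

#' Stability-selection configuration
#'
#' @param B number of bootstrap-with-replacement iterations (default 1000).
#' @param alpha binomial tail level for accept/reject decisions, in (0, 0.5).
#' @param seed integer RNG seed; the (seed, inputs) pair fully determines the
#'   result.
#' @param scca an [sccaConfig()] list used in every iteration (the sparsity
#'   parameters stay fixed across iterations and indices).
#' @return a list of class `stabilityConfig`.
#' @export
stabilityConfig <- function(B = 1000L, alpha = 0.05, seed = 1L,
                            scca = sccaConfig()) {
  if (B < 1L) stop("B must be >= 1")
  if (alpha <= 0 || alpha >= 0.5) stop("alpha must lie in (0, 0.5)")
  structure(list(B = as.integer(B), alpha = alpha, seed = as.integer(seed),
                 scca = scca),
            class = "stabilityConfig")
}

#' Pooled chance selection probability
#'
#' Under a uniform null every available connection is equally likely to enter
#' the sparse support, so the chance probability of selection is the mean
#' per-iteration support size over the mean per-iteration number of
#' available connections.  With the study-scale per-iteration means of 20
#' selected out of 453 available this is 0.044.
#'
#' @param selectedPerIter per-iteration support sizes (or a scalar mean).
#' @param availablePerIter per-iteration available-edge counts (or a scalar
#'   mean).
#' @param ... unused.
#' @return the scalar chance probability.
#' @export
setMethod("chanceProbability", "numeric",
          function(x, availablePerIter, ...) {
  mean(x) / mean(availablePerIter)
})

## row sample SDs without apply(); exact zeros preserved for constant rows
.rowSds <- function(x) {
  m <- ncol(x)
  mu <- rowMeans(x)
  sqrt(rowSums((x - mu)^2) / (m - 1L))
}

#' Bootstrap stability selection of coupled connections
#'
#' Repeats the rank-1 sparse CCA over `B` bootstrap resamples of subjects.
#' Each iteration draws m subjects with replacement, recomputes the
#' common-edge mask on the resample (so the number of available connections
#' varies across iterations), assembles and standardises both panels, draws
#' fresh randomised penalty factors, fits the sparse CCA, and counts every
#' edge with a nonzero canonical loading as selected.  Edges whose resampled
#' row is constant (duplicated subjects can cause this) are dropped for that
#' iteration only.
#'
#' @param structStack list of structural [ConnectivityMatrix-class] objects,
#'   one per subject.
#' @param funcStack list of functional connectomes for the same subjects, in
#'   the same order.
#' @param config a [stabilityConfig()] list.
#' @param idx optional [EdgeIndex-class]; built from the shared atlas when
#'   omitted.
#' @return a [StabilityResult-class].
#' @export
bootstrapStability <- function(structStack, funcStack, config = stabilityConfig(),
                               idx = buildEdgeIndex(structStack[[1L]]@atlas)) {
  m <- length(structStack)
  if (length(funcStack) != m)
    stop("structural and functional stacks must cover the same subjects")
  if (m < 8L) stop("bootstrap stability needs at least 8 subjects")
  subjS <- vapply(structStack, function(cm) cm@subject, character(1L))
  subjF <- vapply(funcStack, function(cm) cm@subject, character(1L))
  if (!identical(subjS, subjF))
    stop("subject identifiers differ between the stacks")

  k <- length(idx@labels)
  # pre-vectorise once; resampling then only permutes columns
  Xfull <- vapply(structStack, vectorizeUpper, numeric(k), idx = idx)
  Yfull <- vapply(funcStack, vectorizeUpper, numeric(k), idx = idx)

  countsX <- countsY <- testedX <- testedY <- integer(k)
  loadSumX <- loadSumY <- numeric(k)
  availX <- selX <- availY <- selY <- integer(config$B)
  dropped <- 0L

  set.seed(config$seed)
  for (b in seq_len(config$B)) {
    take <- sample.int(m, m, replace = TRUE)
    xs <- Xfull[, take, drop = FALSE]
    ys <- Yfull[, take, drop = FALSE]
    okX <- rowSums(is.na(xs)) == 0L
    okY <- rowSums(is.na(ys)) == 0L
    # constant rows cannot be standardised within this resample
    sdX <- .rowSds(xs)
    sdY <- .rowSds(ys)
    constX <- okX & !is.na(sdX) & sdX == 0
    constY <- okY & !is.na(sdY) & sdY == 0
    dropped <- dropped + sum(constX) + sum(constY)
    okX <- okX & !constX
    okY <- okY & !constY
    if (sum(okX) < 2L || sum(okY) < 2L)
      stop("resample retains fewer than 2 edges; data too sparse")
    xb <- (xs[okX, , drop = FALSE] - rowMeans(xs[okX, , drop = FALSE])) /
      sdX[okX]
    yb <- (ys[okY, , drop = FALSE] - rowMeans(ys[okY, , drop = FALSE])) /
      sdY[okY]
    wU <- randomizedWeights(nrow(xb), config$scca$weakness)
    wV <- randomizedWeights(nrow(yb), config$scca$weakness)
    cfg <- config$scca
    cfg$cU <- min(cfg$cU, sqrt(nrow(xb)))
    cfg$cV <- min(cfg$cV, sqrt(nrow(yb)))
    fit <- sccaRank1(xb, yb, cfg, wU = wU, wV = wV)
    selXb <- fit@u != 0
    selYb <- fit@v != 0
    testedX[okX] <- testedX[okX] + 1L
    testedY[okY] <- testedY[okY] + 1L
    countsX[okX] <- countsX[okX] + selXb
    countsY[okY] <- countsY[okY] + selYb
    loadSumX[okX] <- loadSumX[okX] + fit@u
    loadSumY[okY] <- loadSumY[okY] + fit@v
    availX[b] <- sum(okX)
    selX[b] <- sum(selXb)
    availY[b] <- sum(okY)
    selY[b] <- sum(selYb)
  }

  names(countsX) <- names(countsY) <- names(testedX) <- names(testedY) <-
    names(loadSumX) <- names(loadSumY) <- idx@labels
  new("StabilityResult",
      countsX = countsX, countsY = countsY,
      testedX = testedX, testedY = testedY,
      loadingSumX = loadSumX, loadingSumY = loadSumY,
      availablePerIter = availX, selectedPerIter = selX,
      availablePerIterY = availY, selectedPerIterY = selY,
      pChance = chanceProbability(as.numeric(selX), as.numeric(availX)),
      B = config$B, hemiclassX = unname(idx@hemiclass),
      droppedConstant = dropped)
}

#' Exact binomial tail thresholds
#'
#' For selection counts `K ~ Binomial(B, p0)` under the chance null, returns
#' `kHi`, the smallest count with upper-tail probability `P(K >= k) < alpha`
#' (select above chance), and `kLo`, the largest count with lower-tail
#' probability `P(K <= k) < alpha` (reject below chance).  Tails are exact
#' binomial sums; no normal approximation.  `NA` is returned for a tail that
#' no attainable count reaches.
#'
#' @param B number of bootstrap iterations.
#' @param p0 chance probability in (0, 1).
#' @param alpha tail level in (0, 0.5).
#' @return named integer vector `c(kLo, kHi)`.
#' @examples
#' binomialThresholds(10, 0.5, 0.05)   # kLo = 1, kHi = 9
#' @export
binomialThresholds <- function(B, p0, alpha = 0.05) {
  if (p0 <= 0 || p0 >= 1) stop("p0 must lie strictly in (0, 1)")
  if (alpha <= 0 || alpha >= 0.5) stop("alpha must lie in (0, 0.5)")
  upper <- stats::pbinom(0:B - 1L, B, p0, lower.tail = FALSE)  # P(K >= k)
  kHi <- which(upper < alpha)
  kHi <- if (length(kHi)) as.integer(kHi[1L] - 1L) else NA_integer_
  lower <- stats::pbinom(0:B, B, p0)                           # P(K <= k)
  kLo <- which(lower < alpha)
  kLo <- if (length(kLo)) as.integer(kLo[length(kLo)] - 1L) else NA_integer_
  c(kLo = kLo, kHi = kHi)
}

#' Classify edges by binomial accept/reject
#'
#' Applies the exact binomial thresholds at the pooled chance probability to
#' the per-edge selection counts: counts at or above `kHi` are selected
#' significantly above chance, counts at or below `kLo` are rejected
#' significantly below chance, and the remainder is undetermined.  The
#' per-edge averaged canonical loading is attached for reporting.  By
#' default the structural panel is classified; functional-edge probabilities
#' are available through the same interface.
#'
#' @param res a [StabilityResult-class].
#' @param alpha tail level (default 0.05).
#' @param panel `"structural"` (default) or `"functional"`.
#' @param p0 chance probability for the null; defaults to the pooled
#'   `chanceProbability(res)`.
#' @return a [SelectionDecision-class].
#' @export
classifyEdges <- function(res, alpha = 0.05,
                          panel = c("structural", "functional"),
                          p0 = chanceProbability(res)) {
  panel <- match.arg(panel)
  counts <- if (panel == "structural") res@countsX else res@countsY
  tested <- if (panel == "structural") res@testedX else res@testedY
  loadSum <- if (panel == "structural") res@loadingSumX else res@loadingSumY
  thr <- binomialThresholds(res@B, p0, alpha)
  isTested <- tested > 0L
  cls <- rep("untested", length(counts))
  cls[isTested] <- "undetermined"
  if (!is.na(thr[["kHi"]]))
    cls[isTested & counts >= thr[["kHi"]]] <- "selected"
  if (!is.na(thr[["kLo"]]))
    cls[isTested & counts <= thr[["kLo"]]] <- "rejected"
  tab <- data.frame(edge = names(counts),
                    count = as.integer(counts),
                    tested = as.integer(tested),
                    probability = as.numeric(counts) / res@B,
                    meanLoading = ifelse(tested > 0L, loadSum / pmax(tested, 1L), NA_real_),
                    hemiclass = res@hemiclassX,
                    class = cls,
                    row.names = NULL)
  new("SelectionDecision",
      selected = names(counts)[cls == "selected"],
      rejected = names(counts)[cls == "rejected"],
      undetermined = names(counts)[cls == "undetermined"],
      kHi = thr[["kHi"]], kLo = thr[["kLo"]],
      pChance = p0, alpha = alpha, B = res@B, table = tab)
}
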