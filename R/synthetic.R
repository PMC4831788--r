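#' @include AllClasses.R connectome-io.R
NULL

#' Synthetic-study configuration
#'
#' Describes a simulated cohort with a single shared latent factor coupling a
#' sparse set of structural edges to a sparse set of functional edges.  The
#' defaults mirror the study conditions the pipeline targets: 17 subjects and
#' a 68-region cortical parcellation with `lh_`/`rh_` hemisphere labels.
#' Noise is unit-SD everywhere, so `coupling` reads directly as an effect
#' size in SD units.
#'
#' @param m number of subjects (default 17).
#' @param n number of regions (default 68); the left hemisphere takes the
#'   first ceiling(n/2) regions.
#' @param sX,sY true support sizes on the structural and functional panels.
#' @param coupling loading magnitude relative to the unit noise SD (>= 0;
#'   0 decouples the panels).
#' @param missingRate per-edge per-subject probability that a structural
#'   connection is absent, in [0, 0.5).
#' @param interOdds odds multiplier for missingness of interhemispheric
#'   edges (default 1 = uniform; > 1 emulates tractography's underestimation
#'   of long-range connectivity).
#' @param seed integer RNG seed.
#' @return a list of class `syntheticConfig`.
#' @export
syntheticConfig <- function(m = 17L, n = 68L, sX = 10L, sY = 10L,
                            coupling = 3, missingRate = 0.05, interOdds = 1,
                            seed = 1L) {
  k <- n * (n - 1L) / 2L
  if (n < 2L) stop("n must be >= 2")
  if (sX > k || sY > k) stop("support sizes cannot exceed the edge count")
  if (coupling < 0) stop("coupling must be non-negative")
  if (missingRate < 0 || missingRate >= 0.5)
    stop("missingRate must lie in [0, 0.5)")
  structure(list(m = as.integer(m), n = as.integer(n), k = as.integer(k),
                 sX = as.integer(sX), sY = as.integer(sY),
                 coupling = coupling, missingRate = missingRate,
                 interOdds = interOdds, seed = as.integer(seed)),
            class = "syntheticConfig")
}

#' Atlas of synthetic regions
#'
#' `ceiling(n/2)` left regions `lh_r01, lh_r02, ...` followed by the right
#' counterparts, so hemisphere parsing and quadrant layout are exercised.
#'
#' @param n number of regions (>= 2).
#' @return a [RegionAtlas-class].
#' @export
syntheticAtlas <- function(n = 68L) {
  nl <- as.integer(ceiling(n / 2))
  regionAtlas(c(sprintf("lh_r%02d", seq_len(nl)),
                sprintf("rh_r%02d", seq_len(n - nl))))
}

#' Generate latently coupled edge panels with ground truth
#'
#' Per subject s a latent score `z_s ~ N(0, 1)` is drawn.  Rows on the true
#' supports are `loading * z_s + noise` with loadings of magnitude
#' `coupling` and random signs; all other rows are pure unit-normal noise.
#' This is exactly the one-factor structure the rank-1 sparse CCA model
#' assumes, so recovery of the supports is a well-posed test.
#'
#' @param config a [syntheticConfig()] list.
#' @return list with unstandardised [ConnectomePanel-class] elements `X`
#'   (structural), `Y` (functional) and a [GroundTruth-class] `truth`.
#' @export
generateCoupledPanels <- function(config = syntheticConfig()) {
  set.seed(config$seed)
  idx <- buildEdgeIndex(syntheticAtlas(config$n))
  k <- config$k
  m <- config$m
  z <- stats::rnorm(m)
  supX <- sort(sample.int(k, config$sX))
  supY <- sort(sample.int(k, config$sY))
  loadX <- config$coupling * sample(c(-1, 1), config$sX, replace = TRUE)
  loadY <- config$coupling * sample(c(-1, 1), config$sY, replace = TRUE)
  x <- matrix(stats::rnorm(k * m), k, m)
  y <- matrix(stats::rnorm(k * m), k, m)
  x[supX, ] <- x[supX, ] + loadX %o% z
  y[supY, ] <- y[supY, ] + loadY %o% z
  subj <- sprintf("sub%02d", seq_len(m))
  dimnames(x) <- dimnames(y) <- list(idx@labels, subj)
  panel <- function(vals, mod) new("ConnectomePanel", values = vals,
                                   hemiclass = unname(idx@hemiclass),
                                   modality = mod, standardized = FALSE)
  list(X = panel(x, "synthetic-structural"),
       Y = panel(y, "synthetic-functional"),
       truth = new("GroundTruth",
                   supportX = idx@labels[supX], supportY = idx@labels[supY],
                   loadingsX = stats::setNames(loadX, idx@labels[supX]),
                   loadingsY = stats::setNames(loadY, idx@labels[supY]),
                   latent = stats::setNames(z, subj)),
       edgeIndex = idx)
}

#' Devectorise panels into per-subject connectome stacks
#'
#' Turns each subject column into a symmetric labeled matrix and knocks out
#' structural edges independently with probability `missingRate`
#' (interhemispheric edges with odds multiplied by `interOdds`).  Functional
#' connectomes are returned complete: precision matrices have no missing
#' cells.
#'
#' @param config the [syntheticConfig()] used for the panels.
#' @param panels output of [generateCoupledPanels()].
#' @return list of two lists of [ConnectivityMatrix-class] objects:
#'   `structural` and `functional`, one entry per subject.
#' @export
generateConnectomeStacks <- function(config, panels) {
  idx <- panels$edgeIndex
  m <- config$m
  # knockout probabilities per edge: odds-scaled for interhemispheric edges
  pMiss <- rep(config$missingRate, config$k)
  if (config$interOdds != 1 && config$missingRate > 0) {
    odds <- config$missingRate / (1 - config$missingRate) * config$interOdds
    pMiss[idx@hemiclass == "inter"] <- odds / (1 + odds)
  }
  set.seed(config$seed + 1L)
  structural <- functional <- vector("list", m)
  subj <- colnames(panels$X@values)
  for (s in seq_len(m)) {
    xv <- panels$X@values[, s]
    knock <- stats::runif(config$k) < pMiss
    xv[knock] <- NA_real_
    structural[[s]] <- devectorizeEdges(xv, idx,
                                        modality = "synthetic-structural",
                                        subject = subj[s])
    functional[[s]] <- devectorizeEdges(panels$Y@values[, s], idx,
                                        modality = "synthetic-functional",
                                        subject = subj[s])
  }
  list(structural = structural, functional = functional)
}

#' Draw Gaussian time series with a known precision matrix
#'
#' T i.i.d. samples from the zero-mean multivariate normal whose inverse
#' covariance is `precision`, via a Cholesky factor of the covariance.  The
#' test bed for precision-matrix connectome estimation: the estimated
#' precision should recover the known zero pattern.
#'
#' @param precision symmetric positive definite n-by-n matrix (region labels
#'   as dimnames, or labels are generated).
#' @param T number of samples.
#' @param samplingRate nominal sampling rate in Hz for the result.
#' @param seed integer RNG seed.
#' @return a [RegionTimeSeries-class].
#' @export
generateGaussianTimeseries <- function(precision, T, samplingRate = 1,
                                       seed = 1L) {
  n <- nrow(precision)
  if (max(abs(precision - t(precision))) > 1e-10)
    stop("precision must be symmetric")
  ch <- tryCatch(chol(precision), error = function(e)
    stop("precision must be positive definite"))
  sigma <- chol2inv(ch)
  set.seed(seed)
  z <- matrix(stats::rnorm(T * n), T, n)
  x <- z %*% chol(sigma)
  if (is.null(rownames(precision))) {
    half <- ceiling(n / 2)
    labs <- c(sprintf("lh_r%02d", seq_len(half)),
              sprintf("rh_r%02d", seq_len(n - half)))
  } else labs <- rownames(precision)
  colnames(x) <- labs
  regionTimeSeries(x, samplingRate)
}

## unit-variance slow signal: low-pass filtered white noise rescaled
.slowSignal <- function(T, rate, cutoff, n = 1L) {
  bf <- signal::butter(2L, min(cutoff / (rate / 2), 0.99), type = "low")
  out <- matrix(stats::rnorm(T * n), T, n)
  apply(out, 2L, function(col) {
    f <- signal::filtfilt(bf, col)
    (f - mean(f)) / stats::sd(f)
  })
}

#' Generate band-limited oscillations with coupled envelopes
#'
#' Each region carries a sinusoid at the band centre frequency (random
#' phase) amplitude-modulated by a slowly varying positive envelope.  Region
#' pairs listed in `envelopeCoupling` share a common envelope component with
#' weight `sqrt(share)`, so their Hilbert envelopes are correlated about
#' `share` while uncoupled pairs are uncorrelated.  The test bed for the
#' electrophysiological envelope-connectome pipeline.
#'
#' @param n number of regions (even).
#' @param band a [bandDefinition()].
#' @param envelopeCoupling list of integer region pairs sharing an envelope
#'   component.
#' @param T number of samples.
#' @param samplingRate sampling rate in Hz.
#' @param share variance share of the common envelope component, in (0, 1).
#' @param seed integer RNG seed.
#' @return a [RegionTimeSeries-class].
#' @export
generateBandOscillations <- function(n, band, envelopeCoupling = list(),
                                     T = 10000L, samplingRate = 200,
                                     share = 0.6, seed = 1L) {
  if (band$high >= samplingRate / 2)
    stop("band must lie below the Nyquist frequency")
  set.seed(seed)
  f0 <- (band$low + band$high) / 2
  envCut <- min(band$low / 2, 1)           # envelope much slower than carrier
  own <- .slowSignal(T, samplingRate, envCut, n)
  g <- own
  if (length(envelopeCoupling)) {
    shared <- .slowSignal(T, samplingRate, envCut, length(envelopeCoupling))
    for (p in seq_along(envelopeCoupling)) {
      pair <- envelopeCoupling[[p]]
      g[, pair] <- sqrt(share) * shared[, p] +
        sqrt(1 - share) * own[, pair]
    }
  }
  env <- 1 + 0.4 * g
  env[env < 0.05] <- 0.05                  # envelopes are positive
  tt <- seq_len(T) / samplingRate
  phases <- stats::runif(n, 0, 2 * pi)
  x <- vapply(seq_len(n), function(i)
    env[, i] * sin(2 * pi * f0 * tt + phases[i]), numeric(T))
  colnames(x) <- syntheticAtlas(n)@labels
  regionTimeSeries(x, samplingRate)
}

#' Generate a streamline visitation record
#'
#' Random per-voxel microstructural values and visitation counts for one
#' edge, for testing weighted edge averaging.
#'
#' @param edge character vector of the two region labels.
#' @param nVoxels number of voxels on the tract.
#' @param countRange integer range of per-voxel visitation counts.
#' @param valueRange range of the microstructural index values.
#' @param seed integer RNG seed.
#' @return a list with fields `edge`, `values`, `counts`, `streamlines`.
#' @export
generateStreamlineVisitation <- function(edge = c("lh_r01", "rh_r01"),
                                         nVoxels = 50L,
                                         countRange = c(1L, 20L),
                                         valueRange = c(0.2, 0.8),
                                         seed = 1L) {
  if (countRange[1L] < 1L || countRange[1L] > countRange[2L])
    stop("invalid count range")
  if (valueRange[1L] > valueRange[2L]) stop("invalid value range")
  set.seed(seed)
  counts <- sample(countRange[1L]:countRange[2L], nVoxels, replace = TRUE)
  list(edge = edge,
       values = stats::runif(nVoxels, valueRange[1L], valueRange[2L]),
       counts = counts,
       streamlines = max(counts))
}
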