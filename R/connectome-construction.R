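#' @include AllClasses.R connectome-io.R
NULL

#' Construct a regional time-series object
#'
#' @param data numeric T-by-n matrix, one column per region; colnames are the
#'   region labels unless an atlas is supplied.
#' @param samplingRate sampling rate in Hz.
#' @param atlas optional [RegionAtlas-class]; built from colnames otherwise.
#' @return a [RegionTimeSeries-class].
#' @export
regionTimeSeries <- function(data, samplingRate, atlas = NULL) {
  data <- as.matrix(data)
  if (is.null(atlas)) {
    if (is.null(colnames(data)))
      stop("data needs region colnames or an explicit atlas")
    atlas <- regionAtlas(colnames(data))
  }
  colnames(data) <- atlas@labels
  new("RegionTimeSeries", data = data, samplingRate = samplingRate,
      atlas = atlas)
}

#' Electrophysiological band definitions
#'
#' The five conventional bands: delta (1-4 Hz), theta (4-8 Hz),
#' alpha (8-13 Hz), beta (13-30 Hz) and gamma (30-70 Hz).
#'
#' @param name band name, one of `"delta"`, `"theta"`, `"alpha"`, `"beta"`,
#'   `"gamma"`, or any name when `low`/`high` are given explicitly.
#' @param low,high band edges in Hz; defaults looked up from `name`.
#' @return a list with elements `name`, `low`, `high`.
#' @export
bandDefinition <- function(name, low = NULL, high = NULL) {
  canon <- list(delta = c(1, 4), theta = c(4, 8), alpha = c(8, 13),
                beta = c(13, 30), gamma = c(30, 70))
  if (is.null(low) || is.null(high)) {
    if (!name %in% names(canon))
      stop("unknown band '", name, "'; give low and high explicitly")
    low <- canon[[name]][1L]
    high <- canon[[name]][2L]
  }
  if (!(low > 0 && low < high))
    stop("band edges must satisfy 0 < low < high")
  list(name = name, low = low, high = high)
}

## Schafer-Strimmer style shrinkage intensity: shrink off-diagonal sample
## covariances toward zero (diagonal target) by the ratio of their estimated
## sampling variance to their squared magnitude.
.shrinkageIntensity <- function(x) {
  T <- nrow(x)
  xc <- scale(x, center = TRUE, scale = FALSE)
  s <- crossprod(xc) / (T - 1)
  num <- 0
  den <- 0
  for (i in seq_len(ncol(x) - 1L)) {
    for (j in (i + 1L):ncol(x)) {
      wij <- xc[, i] * xc[, j]
      num <- num + T / (T - 1)^3 * sum((wij - mean(wij))^2)
      den <- den + s[i, j]^2
    }
  }
  if (den == 0) return(1)
  max(0, min(1, num / den))
}

#' Precision-matrix functional connectome
#'
#' Estimates the inverse covariance (precision) of regional time series.  The
#' off-diagonal entries of a precision matrix encode conditional dependence
#' between regions given all others, which is the functional-connectivity
#' representation used throughout the package.  With few samples relative to
#' regions the raw inverse is unstable, so the default shrinks the
#' off-diagonal covariances toward the diagonal with an analytically chosen
#' intensity before inverting; `shrinkage = "none"` inverts the raw sample
#' covariance.
#'
#' @param ts a [RegionTimeSeries-class].
#' @param shrinkage `"ledoit-wolf"` (default) or `"none"`.
#' @param subject subject identifier for the result.
#' @param modality modality tag for the result (default `"fMRI"`).
#' @return a [ConnectivityMatrix-class] holding the symmetric positive
#'   definite precision matrix.
#' @export
precisionConnectome <- function(ts, shrinkage = c("ledoit-wolf", "none"),
                                subject = "subject", modality = "fMRI") {
  shrinkage <- match.arg(shrinkage)
  x <- ts@data
  if (any(apply(x, 2L, stats::sd) == 0))
    stop("constant region time series: ",
         paste(colnames(x)[apply(x, 2L, stats::sd) == 0], collapse = ", "))
  s <- stats::cov(x)
  if (shrinkage == "ledoit-wolf") {
    lambda <- .shrinkageIntensity(x)
    target <- diag(diag(s))
    s <- (1 - lambda) * s + lambda * target
  }
  p <- tryCatch(chol2inv(chol(s)), error = function(e)
    stop("sample covariance is singular; use shrinkage"))
  dimnames(p) <- list(ts@atlas@labels, ts@atlas@labels)
  p <- (p + t(p)) / 2
  miss <- matrix(FALSE, ncol(x), ncol(x))
  new("ConnectivityMatrix", values = p, atlas = ts@atlas,
      modality = modality, subject = subject, missing = miss)
}

## Analytic signal via FFT: zero the negative frequencies, double the
## positive ones (Marple's convention for even/odd T).
.analyticSignal <- function(x) {
  T <- length(x)
  X <- stats::fft(x)
  h <- numeric(T)
  if (T %% 2L == 0L) {
    h[c(1L, T / 2L + 1L)] <- 1
    h[2L:(T / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2L:((T + 1L) / 2L)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / T
}

#' Band-limited Hilbert envelope
#'
#' Band-pass filters each regional series (zero-phase forward-backward
#' Butterworth, order `order`) and returns the magnitude of its analytic
#' signal: the slow amplitude envelope of the band-limited oscillation.
#'
#' @param ts a [RegionTimeSeries-class].
#' @param band a band from [bandDefinition()].
#' @param order Butterworth order (default 4).
#' @return a [RegionTimeSeries-class] of non-negative envelopes at the same
#'   sampling rate.
#' @export
bandEnvelope <- function(ts, band, order = 4L) {
  nyq <- ts@samplingRate / 2
  if (band$high >= nyq)
    stop(sprintf("band edge %.1f Hz reaches the Nyquist frequency %.1f Hz",
                 band$high, nyq))
  bf <- signal::butter(order, c(band$low, band$high) / nyq, type = "pass")
  env <- apply(ts@data, 2L, function(col) {
    filt <- signal::filtfilt(bf, col)
    Mod(.analyticSignal(filt))
  })
  regionTimeSeries(env, ts@samplingRate, ts@atlas)
}

#' Envelope precision connectome
#'
#' Composition of [bandEnvelope()] and [precisionConnectome()]: the precision
#' matrix of the band-limited amplitude envelopes, the electrophysiological
#' functional-connectome representation.
#'
#' @inheritParams bandEnvelope
#' @inheritParams precisionConnectome
#' @return a [ConnectivityMatrix-class] tagged with the band name.
#' @export
envelopePrecisionConnectome <- function(ts, band,
                                        shrinkage = c("ledoit-wolf", "none"),
                                        subject = "subject", order = 4L) {
  precisionConnectome(bandEnvelope(ts, band, order = order),
                      shrinkage = match.arg(shrinkage),
                      subject = subject, modality = band$name)
}

#' Streamline-weighted average of a microstructural index
#'
#' Averages per-voxel index values along a tract, weighting each voxel by the
#' number of streamlines that pass through it, so that voxels unlikely to
#' belong to the tract contribute little.
#'
#' @param values per-voxel index values.
#' @param counts per-voxel streamline visitation counts (>= 1).
#' @return the weighted mean, guaranteed to lie in `[min(values),
#'   max(values)]`.
#' @export
weightedEdgeAverage <- function(values, counts) {
  if (!length(values) || length(values) != length(counts))
    stop("values and counts must be non-empty and of equal length")
  if (any(counts < 1))
    stop("visitation counts must be >= 1")
  sum(values * counts) / sum(counts)
}

#' Streamline-density edge weight
#'
#' Number of streamlines connecting two regions, divided by the average voxel
#' count of the two end-point regions of interest.
#'
#' @param count streamline count (>= 0).
#' @param sizeA,sizeB end-point region sizes in voxels (> 0).
#' @return the normalised streamline count; zero streamlines yield 0 and the
#'   edge is treated as missing downstream.
#' @export
nstreamsEdge <- function(count, sizeA, sizeB) {
  if (sizeA <= 0 || sizeB <= 0) stop("region sizes must be positive")
  if (count < 0) stop("streamline count must be non-negative")
  count / ((sizeA + sizeB) / 2)
}

#' Orientation dispersion index from Watson concentration
#'
#' ODI = 2/pi * atan(1/kappa): a monotone decreasing bijection from
#' concentration kappa in `[0, Inf)` onto `(0, 1]`, with kappa = 0 mapped to
#' 1 by continuous extension.
#'
#' @param kappa Watson concentration parameter(s), >= 0.
#' @return ODI value(s) in (0, 1].
#' @seealso [kappaFromOdi()]
#' @examples
#' odiFromKappa(1)    # 0.5
#' @export
odiFromKappa <- function(kappa) {
  if (any(kappa < 0)) stop("kappa must be non-negative")
  ifelse(kappa == 0, 1, 2 / pi * atan(1 / kappa))
}

#' Watson concentration from orientation dispersion
#'
#' Inverse of [odiFromKappa()]: kappa = 1 / tan(pi/2 * ODI).
#'
#' @param odi ODI value(s) in (0, 1].
#' @return kappa value(s) in `[0, Inf)`.
#' @export
kappaFromOdi <- function(odi) {
  if (any(odi <= 0 | odi > 1)) stop("ODI must lie in (0, 1]")
  ifelse(odi == 1, 0, 1 / tan(pi / 2 * odi))
}

#' Read/write regional time series as TSV
#'
#' Time-by-region table with a header of region names.
#'
#' @param path file path.
#' @param samplingRate sampling rate in Hz.
#' @rdname timeSeriesIO
#' @return `readTimeSeries`: a [RegionTimeSeries-class].
#' @export
readTimeSeries <- function(path, samplingRate) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE)
  regionTimeSeries(as.matrix(tab), samplingRate)
}

#' @param ts a [RegionTimeSeries-class].
#' @rdname timeSeriesIO
#' @export
writeTimeSeries <- function(ts, path) {
  utils::write.table(ts@data, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read/write streamline visitation records as JSON lines
#'
#' One JSON object per line with fields `edge` (two region labels), `values`,
#' `counts` and `streamlines`.
#'
#' @param path file path.
#' @rdname visitationIO
#' @return `readVisitation`: a list of visitation records.
#' @export
readVisitation <- function(path) {
  lines <- readLines(path)
  lapply(lines[nzchar(lines)], function(l) {
    rec <- jsonlite::fromJSON(l)
    rec$edge <- as.character(rec$edge)
    rec
  })
}

#' @param records list of visitation records.
#' @rdname visitationIO
#' @export
writeVisitation <- function(records, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (rec in records)
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  invisible(path)
}
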