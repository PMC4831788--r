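test_that("precision connectome inverts the sample covariance", {
  # orthonormal-column construction: sample covariance exactly the identity
  set.seed(2L)
  z <- matrix(rnorm(200L * 4L), 200L, 4L)
  z <- scale(z, center = TRUE, scale = FALSE) %*% solve(chol(cov(z)))
  colnames(z) <- c("lh_r01", "lh_r02", "rh_r01", "rh_r02")
  ts <- regionTimeSeries(z, samplingRate = 1)
  p <- precisionConnectome(ts, shrinkage = "none")
  expect_equal(unname(connValues(p)), diag(4L), tolerance = 1e-6)

  # bivariate: off-diagonal precision tends to -rho / (1 - rho^2)
  rho <- 0.6
  prec2 <- solve(matrix(c(1, rho, rho, 1), 2L))
  ts2 <- generateGaussianTimeseries(prec2, T = 20000L, seed = 4L)
  est <- connValues(precisionConnectome(ts2, shrinkage = "none"))
  expect_equal(est[1L, 2L], -rho / (1 - rho^2), tolerance = 0.05)
})

test_that("precision estimate recovers a known sparse precision", {
  # chain-graph precision on 10 regions
  n <- 10L
  prec <- diag(2, n)
  for (i in seq_len(n - 1L)) prec[i, i + 1L] <- prec[i + 1L, i] <- -0.8
  ts <- generateGaussianTimeseries(prec, T = 5000L, seed = 10L)
  est <- connValues(precisionConnectome(ts, shrinkage = "none"))
  expect_lt(max(abs(est - prec)), 0.1)
  # matches the direct inverse of the sample covariance (independent oracle)
  expect_equal(unname(est), unname(solve(cov(ts@data))), tolerance = 1e-8)
})

test_that("precision connectome is symmetric positive definite", {
  set.seed(21L)
  x <- matrix(rnorm(60L * 8L), 60L, 8L)
  colnames(x) <- syntheticAtlas(8L)@labels
  for (shr in c("ledoit-wolf", "none")) {
    p <- connValues(precisionConnectome(regionTimeSeries(x, 1), shrinkage = shr))
    expect_equal(p, t(p))
    expect_gt(min(eigen(p, symmetric = TRUE, only.values = TRUE)$values), 0)
  }
  # more regions than samples: raw inversion fails, shrinkage succeeds
  y <- matrix(rnorm(6L * 10L), 6L, 10L)
  colnames(y) <- syntheticAtlas(10L)@labels
  expect_error(precisionConnectome(regionTimeSeries(y, 1), shrinkage = "none"),
               "singular")
  pShr <- connValues(precisionConnectome(regionTimeSeries(y, 1)))
  expect_gt(min(eigen(pShr, symmetric = TRUE, only.values = TRUE)$values), 0)
})

test_that("band envelope recovers amplitude of in-band carriers", {
  fs <- 200
  tt <- seq_len(4000L) / fs
  A <- 2.5
  x <- cbind(A * sin(2 * pi * 10 * tt),     # inside the alpha band
             sin(2 * pi * 2 * tt))          # below it
  colnames(x) <- c("lh_r01", "rh_r01")
  ts <- regionTimeSeries(x, fs)
  env <- bandEnvelope(ts, bandDefinition("alpha"))
  interior <- 500L:3500L
  expect_true(all(env@data >= 0))
  expect_lt(max(abs(env@data[interior, 1L] - A)) / A, 0.05)
  expect_lt(max(env@data[interior, 2L]), 0.05 * A)   # stop-band rejection
  expect_error(bandEnvelope(ts, bandDefinition("hf", 80, 120)), "Nyquist")
})

test_that("band envelope tracks a slow amplitude modulator", {
  fs <- 200
  tt <- seq_len(8000L) / fs
  m <- 1 + 0.5 * sin(2 * pi * 0.3 * tt)     # slow positive modulator
  x <- cbind(m * sin(2 * pi * 10 * tt))
  colnames(x) <- "lh_r01"
  env <- bandEnvelope(regionTimeSeries(x, fs), bandDefinition("alpha"))
  interior <- 1000L:7000L
  expect_lt(max(abs(env@data[interior, 1L] - m[interior])), 0.1)
  # envelope commutes with positive amplitude scaling
  env3 <- bandEnvelope(regionTimeSeries(3 * x, fs), bandDefinition("alpha"))
  expect_equal(env3@data, 3 * env@data, tolerance = 1e-6)
})

test_that("envelope precision connectome is the composition of its stages", {
  osc <- generateBandOscillations(4L, bandDefinition("alpha"),
                                  envelopeCoupling = list(c(1L, 3L)),
                                  T = 6000L, samplingRate = 200, seed = 3L)
  band <- bandDefinition("alpha")
  direct <- envelopePrecisionConnectome(osc, band, shrinkage = "none")
  manual <- precisionConnectome(bandEnvelope(osc, band), shrinkage = "none",
                                modality = "alpha")
  expect_equal(connValues(direct), connValues(manual))
  expect_equal(modality(direct), "alpha")
})

test_that("coupled envelopes give the dominant negative precision entry", {
  osc <- generateBandOscillations(6L, bandDefinition("alpha"),
                                  envelopeCoupling = list(c(2L, 5L)),
                                  T = 10000L, samplingRate = 200,
                                  share = 0.7, seed = 8L)
  p <- connValues(envelopePrecisionConnectome(osc, bandDefinition("alpha")))
  off <- abs(p[upper.tri(p)])
  expect_lt(p[2L, 5L], 0)                    # shared driver -> negative precision
  expect_equal(max(off), abs(p[2L, 5L]))     # and largest in magnitude
})

test_that("independent regions give near-zero off-diagonal precision", {
  set.seed(12L)
  T <- 4000L
  x <- matrix(rnorm(T * 6L), T, 6L)
  colnames(x) <- syntheticAtlas(6L)@labels
  p <- connValues(precisionConnectome(regionTimeSeries(x, 1),
                                      shrinkage = "none"))
  # per-entry sampling SD is ~1/sqrt(T); 3.5 sigma allows for the 15
  # simultaneous off-diagonal entries
  expect_lt(max(abs(p[upper.tri(p)])), 3.5 / sqrt(T))
})

test_that("streamline-weighted averages behave like weighted means", {
  expect_equal(weightedEdgeAverage(c(0.5, 0.7), c(1, 3)), 0.65)
  expect_equal(weightedEdgeAverage(c(0.2, 0.4, 0.9), c(2, 2, 2)),
               mean(c(0.2, 0.4, 0.9)))
  expect_equal(weightedEdgeAverage(0.42, 1), 0.42)
  # invariance to uniform count rescaling, and range containment
  set.seed(6L)
  v <- runif(20L)
  k <- sample(1:9, 20L, replace = TRUE)
  expect_equal(weightedEdgeAverage(v, k), weightedEdgeAverage(v, 7 * k))
  expect_gte(weightedEdgeAverage(v, k), min(v))
  expect_lte(weightedEdgeAverage(v, k), max(v))
  expect_error(weightedEdgeAverage(numeric(0), numeric(0)), "non-empty")
})

test_that("streamline density normalises by mean end-point size", {
  expect_equal(nstreamsEdge(100, 40, 60), 2)
  expect_equal(nstreamsEdge(0, 40, 60), 0)
  expect_equal(nstreamsEdge(30, 15, 15), 2)
  expect_error(nstreamsEdge(10, 0, 5), "positive")
})

test_that("ODI-kappa relation is the arctan bijection", {
  expect_identical(odiFromKappa(1), 0.5)
  expect_equal(odiFromKappa(0.5), 2 / pi * atan(2))
  expect_identical(odiFromKappa(0), 1)       # continuous extension
  expect_lt(odiFromKappa(1e6), 1e-5)         # kappa -> Inf limit
  kappas <- c(0.01, 0.1, 0.5, 1, 2, 8, 32, 100)
  odis <- odiFromKappa(kappas)
  expect_true(all(diff(odis) < 0))           # strictly decreasing
  expect_true(all(odis > 0 & odis <= 1))
  expect_equal(kappaFromOdi(odis), kappas, tolerance = 1e-10)
  expect_error(odiFromKappa(-1), "non-negative")
})

test_that("time series and visitation records roundtrip through disk", {
  set.seed(14L)
  x <- matrix(rnorm(50L * 4L), 50L, 4L)
  colnames(x) <- syntheticAtlas(4L)@labels
  ts <- regionTimeSeries(x, 100)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeTimeSeries(ts, path)
  back <- readTimeSeries(path, 100)
  expect_equal(back@data, ts@data, tolerance = 1e-12)

  rec <- generateStreamlineVisitation(seed = 5L)
  jpath <- withr::local_tempfile(fileext = ".jsonl")
  writeVisitation(list(rec), jpath)
  back <- readVisitation(jpath)[[1L]]
  expect_equal(back$edge, rec$edge)
  expect_equal(back$values, rec$values, tolerance = 1e-12)
  expect_equal(back$counts, rec$counts)
})
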