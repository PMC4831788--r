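test_that("coupled panel generator is a pure function of config and seed", {
  cfg <- syntheticConfig(m = 12L, n = 10L, sX = 5L, sY = 5L, coupling = 2,
                         seed = 11L)
  p1 <- generateCoupledPanels(cfg)
  p2 <- generateCoupledPanels(cfg)
  expect_identical(panelValues(p1$X), panelValues(p2$X))
  expect_identical(panelValues(p1$Y), panelValues(p2$Y))
  expect_identical(p1$truth@supportX, p2$truth@supportX)
  # different seed, different draw
  p3 <- generateCoupledPanels(syntheticConfig(m = 12L, n = 10L, sX = 5L,
                                              sY = 5L, coupling = 2,
                                              seed = 12L))
  expect_false(identical(panelValues(p1$X), panelValues(p3$X)))
  # loadings are nonzero exactly on the supports, magnitude = coupling
  expect_equal(sort(names(p1$truth@loadingsX)), sort(p1$truth@supportX))
  expect_true(all(abs(p1$truth@loadingsX) == 2))
})

test_that("zero coupling yields panels independent of each other", {
  cfg <- syntheticConfig(m = 20L, n = 10L, sX = 5L, sY = 5L, coupling = 0,
                         seed = 3L)
  p <- generateCoupledPanels(cfg)
  X <- rowStandardize(panelValues(p$X))
  Y <- rowStandardize(panelValues(p$Y))
  dimnames(X) <- dimnames(Y) <- NULL
  scfg <- sccaConfig(cU = 2, cV = 2, weakness = 1)
  rho <- canonicalCor(sccaRank1(X, Y, scfg))
  set.seed(5L)
  null <- vapply(seq_len(200L), function(i)
    canonicalCor(sccaRank1(X, Y[, sample(ncol(Y))], scfg)), numeric(1L))
  pval <- (1 + sum(null >= rho)) / (1 + length(null))
  expect_gt(pval, 0.01)
})

test_that("strong coupling concentrates the leading singular vectors on-support", {
  # n=26 regions -> k=325 edges
  cfg <- syntheticConfig(m = 50L, n = 26L, sX = 10L, sY = 10L, coupling = 3,
                         seed = 19L)
  p <- generateCoupledPanels(cfg)
  X <- rowStandardize(panelValues(p$X))
  Y <- rowStandardize(panelValues(p$Y))
  sv <- svd(X %*% t(Y), nu = 1L, nv = 1L)
  topU <- rownames(X)[order(abs(sv$u[, 1L]), decreasing = TRUE)[1:10]]
  topV <- rownames(Y)[order(abs(sv$v[, 1L]), decreasing = TRUE)[1:10]]
  expect_gte(length(intersect(topU, p$truth@supportX)), 8L)
  expect_gte(length(intersect(topV, p$truth@supportY)), 8L)
})

test_that("population cross-covariance of the generator is rank one", {
  # with loadings a (on X) and b (on Y) sharing one latent factor,
  # cov(X, Y) = a b', a rank-1 matrix with norm |a||b| = coupling^2 sqrt(sX sY)
  cfg <- syntheticConfig(m = 4000L, n = 6L, sX = 4L, sY = 3L, coupling = 1.5,
                         seed = 23L)
  p <- generateCoupledPanels(cfg)
  cc <- tcrossprod(panelValues(p$X) - rowMeans(panelValues(p$X)),
                   panelValues(p$Y) - rowMeans(panelValues(p$Y))) / (cfg$m - 1)
  sv <- svd(cc)$d
  theory <- cfg$coupling^2 * sqrt(cfg$sX * cfg$sY)
  expect_equal(sv[1L], theory, tolerance = 0.1)
  expect_lt(sv[2L] / sv[1L], 0.15)    # remaining mass is sampling noise
})

test_that("connectome stacks devectorise panels with controlled missingness", {
  cfg <- syntheticConfig(m = 17L, n = 10L, sX = 5L, sY = 5L,
                         missingRate = 0, seed = 7L)
  p <- generateCoupledPanels(cfg)
  stacks <- generateConnectomeStacks(cfg, p)
  idx <- p$edgeIndex
  # no missingness: every edge retained, and values roundtrip
  expect_true(all(commonEdgeMask(stacks$structural, idx)))
  expect_equal(unname(vectorizeUpper(stacks$structural[[3L]], idx)),
               unname(panelValues(p$X)[, 3L]))
  expect_equal(unname(vectorizeUpper(stacks$functional[[9L]], idx)),
               unname(panelValues(p$Y)[, 9L]))

  # with missingness the per-edge retained fraction matches (1 - rate)^m
  cfg2 <- syntheticConfig(m = 17L, n = 40L, sX = 5L, sY = 5L,
                          missingRate = 0.05, seed = 9L)
  p2 <- generateCoupledPanels(cfg2)
  stacks2 <- generateConnectomeStacks(cfg2, p2)
  retained <- mean(commonEdgeMask(stacks2$structural, p2$edgeIndex))
  expect_lt(abs(retained - (1 - 0.05)^17), 0.05)
  # functional stacks stay complete
  expect_true(all(commonEdgeMask(stacks2$functional, p2$edgeIndex)))
})

test_that("interhemispheric knockout bias lowers inter-edge retention", {
  cfg <- syntheticConfig(m = 17L, n = 40L, sX = 5L, sY = 5L,
                         missingRate = 0.05, interOdds = 3, seed = 13L)
  p <- generateCoupledPanels(cfg)
  stacks <- generateConnectomeStacks(cfg, p)
  mask <- commonEdgeMask(stacks$structural, p$edgeIndex)
  hc <- hemiClass(p$edgeIndex)
  interRet <- mean(mask[hc == "inter"])
  intraRet <- mean(mask[hc != "inter"])
  expect_lt(interRet, intraRet)
})

test_that("gaussian series generator honours the requested precision", {
  # identity precision: sample covariance converges to the identity
  ts <- generateGaussianTimeseries(diag(10L), T = 10000L, seed = 2L)
  expect_lt(norm(cov(ts@data) - diag(10L), "F"), 0.2)
  # determinism
  ts2 <- generateGaussianTimeseries(diag(10L), T = 10000L, seed = 2L)
  expect_identical(ts@data, ts2@data)
  # non-SPD input rejected
  bad <- diag(3L)
  bad[1L, 1L] <- -1
  expect_error(generateGaussianTimeseries(bad, 10L), "positive definite")
})

test_that("band oscillation generator couples the envelopes it is told to", {
  band <- bandDefinition("alpha")
  osc <- generateBandOscillations(6L, band,
                                  envelopeCoupling = list(c(1L, 4L)),
                                  T = 10000L, samplingRate = 200,
                                  share = 0.6, seed = 17L)
  env <- bandEnvelope(osc, band)
  interior <- 500L:9500L
  e <- env@data[interior, ]
  expect_gt(cor(e[, 1L], e[, 4L]), 0.5)              # coupled pair
  # envelopes are slow, so single-pair correlations are noisy; uncoupled
  # pairs should be near zero on average
  others <- which(upper.tri(diag(6L)), arr.ind = TRUE)
  others <- others[!(others[, 1L] == 1L & others[, 2L] == 4L), ]
  offCor <- apply(others, 1L, function(ij) cor(e[, ij[1L]], e[, ij[2L]]))
  expect_lt(mean(abs(offCor)), 0.15)
  # carrier outside the analysed band leaves a near-zero envelope
  oscBeta <- generateBandOscillations(2L, bandDefinition("beta"),
                                      T = 4000L, samplingRate = 200,
                                      seed = 18L)
  envAlpha <- bandEnvelope(oscBeta, band)
  expect_lt(max(envAlpha@data[500L:3500L, ]), 0.1)
})

test_that("visitation generator respects its ranges and seed", {
  rec <- generateStreamlineVisitation(nVoxels = 30L, countRange = c(2L, 9L),
                                      valueRange = c(0.3, 0.4), seed = 4L)
  expect_length(rec$values, 30L)
  expect_true(all(rec$counts >= 2L & rec$counts <= 9L))
  expect_true(all(rec$values >= 0.3 & rec$values <= 0.4))
  expect_identical(rec,
                   generateStreamlineVisitation(nVoxels = 30L,
                                                countRange = c(2L, 9L),
                                                valueRange = c(0.3, 0.4),
                                                seed = 4L))
  # collapsed value range pins the weighted average
  recV <- generateStreamlineVisitation(valueRange = c(0.42, 0.42), seed = 1L)
  expect_equal(weightedEdgeAverage(recV$values, recV$counts), 0.42)
  # one dominant voxel pins it to that voxel's value
  expect_equal(weightedEdgeAverage(c(0.9, runif(5L)), c(1e6, rep(1, 5L))),
               0.9, tolerance = 1e-3)
})
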