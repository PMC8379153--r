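test_that("nearest-neighbor dedup counts each unordered pair once", {
  # 3 collinear clusters at 0, 28, 56: the mutual pair counts once
  expect_equal(sort(distances(nnDistances(cbind(c(0, 28, 56), 0)))), c(28, 28))

  # 2 clusters: exactly one distance
  expect_length(distances(nnDistances(cbind(c(0, 40), 0))), 1L)

  # 10 collinear clusters spaced 28: the 9 adjacent gaps
  d10 <- distances(nnDistances(cbind(28 * (0:9), 0)))
  expect_equal(sort(d10), rep(28, 9))

  expect_error(nnDistances(cbind(1, 1)), "at least 2")
})

test_that("dedup equals the exhaustive pair-enumeration oracle", {
  set.seed(14)
  for (rep in 1:40) {
    k <- sample(2:12, 1)
    p <- cbind(runif(k, 0, 300), runif(k, 0, 300))
    expect_equal(sort(distances(nnDistances(p))), oracle_nn_dedup(p),
                 tolerance = 1e-12)
  }
})

test_that("expansion rescaling divides distances and records the factor", {
  nnd <- nnDistances(cbind(c(0, 70), 0))
  eff <- applyExpansion(nnd, 2.5)
  expect_equal(distances(eff), 28)
  expect_equal(expansionFactor(eff), 2.5)
  expect_equal(distances(applyExpansion(nnd, 1)), distances(nnd))
  expect_error(applyExpansion(nnd, 0.8), "factor")
})

test_that("the first-peak fit recovers a known Gaussian to 0.3 nm", {
  set.seed(2)
  d <- rnorm(1e4, 28, 8)
  d <- d[d > 0]
  fit <- fitFirstPeak(d, 28)
  expect_true(fit@converged)
  expect_lt(abs(fit@mean - 28), 0.3)
  expect_lt(abs(fit@sigma - 8), 0.3)
})

test_that("degenerate and contaminated inputs are handled explicitly", {
  # identical distances: degenerate histogram, flagged not fitted
  fit <- fitFirstPeak(rep(28, 500), 28)
  expect_false(fit@converged)
  expect_match(fit@diagnostics$message, "degenerate|bins")

  # too few distances in the window
  expect_false(fitFirstPeak(rnorm(10, 28, 2), 28)@converged)

  # a second peak at twice the spacing does not drag the first-peak fit
  set.seed(6)
  d <- c(rnorm(8000, 28, 8), rnorm(2000, 56, 8))
  fit <- fitFirstPeak(d[d > 0], 28)
  expect_true(fit@converged)
  expect_lt(abs(fit@mean - 28), 0.5)
})

test_that("the distortion estimator implements the quadrature formula", {
  mk <- function(s) new("PeakFit", mean = 84, sigma = s, amplitude = 50,
                        fitWindow = c(42, 126), binWidth = 2, converged = TRUE,
                        diagnostics = list(message = "ok", nDistances = 100L))

  # equal widths: zero added distortion
  est0 <- estimateDistortion(mk(8), mk(8))
  expect_equal(est0@sigmaEmitter, 0)
  expect_true(est0@valid)

  # sigma 16 converts to ~37.7 nm FWHM, printing 38 at integer precision
  est16 <- estimateDistortion(mk(5), mk(sqrt(25 + 2 * 256)))
  expect_equal(est16@sigmaEmitter, 16, tolerance = 1e-12)
  expect_equal(est16@fwhmEmitter, 2 * sqrt(2 * log(2)) * 16, tolerance = 1e-12)
  expect_equal(round(est16@fwhmEmitter), 38)

  # narrower post than pre: flagged zero, never an imaginary number
  inv <- estimateDistortion(mk(8), mk(6))
  expect_false(inv@valid)
  expect_equal(inv@sigmaEmitter, 0)

  # unconverged inputs are an error, not a silent number
  bad <- new("PeakFit", mean = NA_real_, sigma = NA_real_, amplitude = NA_real_,
             fitWindow = c(42, 126), binWidth = 2, converged = FALSE,
             diagnostics = list())
  expect_error(estimateDistortion(bad, mk(8)), "converged")
})

test_that("FWHM / sigma is exactly 2 sqrt(2 ln 2) for every estimate", {
  mk <- function(s) new("PeakFit", mean = 84, sigma = s, amplitude = 50,
                        fitWindow = c(42, 126), binWidth = 2, converged = TRUE,
                        diagnostics = list(message = "ok", nDistances = 100L))
  for (sp in c(4, 6, 8)) {
    for (so in c(9, 14, 23)) {
      est <- estimateDistortion(mk(sp), mk(so))
      expect_equal(est@fwhmEmitter / max(est@sigmaEmitter, .Machine$double.xmin),
                   2 * sqrt(2 * log(2)), tolerance = 1e-12)
    }
  }
})

test_that("rescaling commutes with peak fitting", {
  set.seed(44)
  raw <- rnorm(5000, 70, 8)  # expanded-scale distances
  nnd <- new("NNDistanceSet", distances = raw[raw > 0],
             source = rep("obj:1-2", sum(raw > 0)), expansionFactor = 1)
  f <- 2.5
  a <- fitFirstPeak(applyExpansion(nnd, f), 28, binWidth = 1)
  b <- fitFirstPeak(nnd, f * 28, binWidth = 1 * f)
  expect_true(a@converged && b@converged)
  expect_equal(a@mean, b@mean / f, tolerance = 0.2)
})

test_that("multi-Gaussian projection fits resolve the designed patterns", {
  set.seed(10)
  # two rows 30 nm apart, sigma 3 each
  x2 <- c(rnorm(3000, 0, 3), rnorm(3000, 30, 3))
  pk2 <- fitMultiGaussian1d(x2, 2)
  expect_length(pk2, 2L)
  expect_true(all(vapply(pk2, function(p) p@converged, logical(1))))
  expect_lt(abs(diff(vapply(pk2, function(p) p@mean, numeric(1))) - 30), 0.5)
  expect_equal(vapply(pk2, function(p) p@sigma, numeric(1)), c(3, 3),
               tolerance = 0.2)

  # a single population behaves like the single-peak fit
  x1 <- rnorm(2000, 5, 4)
  pk1 <- fitMultiGaussian1d(x1, 1)
  expect_length(pk1, 1L)
  expect_lt(abs(pk1[[1]]@mean - 5), 0.4)

  # five equal peaks spaced 11 nm, sigma 2.5: adjacent gaps within 1 nm
  x5 <- as.vector(vapply(0:4, function(i) rnorm(2000, 11 * i, 2.5),
                         numeric(2000)))
  pk5 <- fitMultiGaussian1d(x5, 5)
  expect_length(pk5, 5L)
  gaps <- diff(vapply(pk5, function(p) p@mean, numeric(1)))
  expect_true(all(abs(gaps - 11) < 1))

  # asking for more peaks than maxima exist is flagged
  flat <- fitMultiGaussian1d(rnorm(500, 0, 1), 6)
  expect_false(flat[[1]]@converged)
})

test_that("merged-cluster diagnostics separate the two failure signatures", {
  d <- standardDesign("linear28")
  # clean regime: full labeling, no positional noise at all
  cfgClean <- simulationConfig(nObjects = 30, labelingEfficiency = 1,
                               intrinsicJitter = 0,
                               backgroundDensity = 0, seed = 3)
  sim <- simulateField(d, cfgClean, "pre")
  res <- analyzeLinearField(sim$localizations, 28, designSites = 10)
  expect_lt(res$diagnostic$fractionUnderCount, 0.05)
  expect_lt(res$diagnostic$fractionLongDistances, 0.05)

  # missing emitters alone create long distances but few merges
  cfgMiss <- simulationConfig(nObjects = 30, labelingEfficiency = 0.8,
                              backgroundDensity = 0, seed = 3)
  resM <- analyzeLinearField(simulateField(d, cfgMiss, "pre")$localizations,
                             28, designSites = 10)
  expect_gt(resM$diagnostic$fractionLongDistances, 0)

  # heavy gel distortion inflates the measured nearest-neighbor distances
  cfgGel <- simulationConfig(nObjects = 60, gelDistortion = 16, seed = 3)
  resG <- analyzeLinearField(simulateField(d, cfgGel, "post")$localizations,
                             28, designSites = 10)
  expect_gt(resG$diagnostic$fractionUnderCount, 0.5)
  if (!is.na(resG$diagnostic$meanDistanceInWindow) &&
      !is.na(res$diagnostic$meanDistanceInWindow)) {
    expect_gt(resG$diagnostic$meanDistanceInWindow,
              res$diagnostic$meanDistanceInWindow)
  }
})

test_that("fitted variance excess grows linearly with the applied distortion", {
  # The nearest-neighbor dedup keeps each chain's locally smaller gaps, which
  # narrows the fitted peak by a constant factor; the pipeline must agree
  # with a ground-truth oracle that applies the same dedup to the true site
  # positions, and the excess must stay linear in the squared distortion.
  d84 <- standardDesign("linear84")
  gels <- c(0, 5, 10, 16)
  pipe <- numeric(length(gels))
  orac <- numeric(length(gels))
  for (i in seq_along(gels)) {
    pd <- c(); od <- c()
    for (s in 1:3) {  # pool three replicate fields per distortion level
      cfg <- simulationConfig(nObjects = 150, gelDistortion = gels[i],
                              seed = 100 * i + s)
      sim <- simulateField(d84, cfg, "post")
      pd <- c(pd, distances(analyzeLinearField(sim$localizations, 84,
                                               minClusters = 3)$nnd))
      tr <- sim$truth
      od <- c(od, unlist(lapply(split(tr[tr$visible, ],
                                      tr$object_id[tr$visible]), function(o) {
        p <- cbind(o$x_true_nm, o$y_true_nm)
        if (nrow(p) < 2) return(NULL)
        oracle_nn_dedup(p)
      })))
    }
    pipe[i] <- fitFirstPeak(pd, 84)@sigma^2
    orac[i] <- fitFirstPeak(od, 84)@sigma^2
  }
  # the pipeline tracks the ground-truth oracle across the distortion range
  expect_equal(pipe, orac, tolerance = 0.15)
  # the variance excess is linear in sigma_g^2 ...
  expect_gt(summary(stats::lm(pipe ~ I(gels^2)))$r.squared, 0.95)
  # ... with the pipeline slope matching the truth-level slope; both sit at
  # 2 c^2 where c < 1 is the narrowing from the nearest-neighbor dedup
  slope <- function(v) {
    unname(stats::coef(stats::lm(I(v - v[1]) ~ 0 + I(gels^2))))
  }
  expect_equal(slope(pipe) / slope(orac), 1, tolerance = 0.15)
  expect_gt(slope(pipe), 1.2)
  expect_lt(slope(pipe), 2.2)
})
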