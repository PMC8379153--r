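test_that("identical design, config, condition and seed reproduce the table exactly", {
  d <- standardDesign("linear28")
  cfg <- simulationConfig(nObjects = 10, seed = 42)
  a <- simulateField(d, cfg, "pre")
  b <- simulateField(d, cfg, "pre")
  expect_identical(coords(a$localizations), coords(b$localizations))
  expect_identical(frames(a$localizations), frames(b$localizations))
  expect_identical(a$truth, b$truth)

  fa <- tempfile(fileext = ".csv"); fb <- tempfile(fileext = ".csv")
  writeLocalizations(a$localizations, fa)
  writeLocalizations(b$localizations, fb)
  expect_identical(readLines(fa), readLines(fb))
})

test_that("one ground-truth record exists per designed site, independent of visibility", {
  d <- standardDesign("linear84")
  cfg <- simulationConfig(nObjects = 25, labelingEfficiency = 0.5, seed = 3)
  sim <- simulateField(d, cfg, "pre")
  expect_equal(nrow(sim$truth), 25L * 4L)
  expect_equal(as.integer(table(sim$truth$object_id)), rep(4L, 25))
  expect_true(mean(sim$truth$visible) < 1)
})

test_that("degenerate probabilities behave exactly", {
  d <- standardDesign("linear28")
  # full labeling, no background, forced minimum blinking count
  cfg <- simulationConfig(nObjects = 5, labelingEfficiency = 1,
                          backgroundDensity = 0, locsPerEmitterMean = 0.01,
                          minLocsPerEmitter = 5, seed = 7)
  sim <- simulateField(d, cfg, "pre")
  expect_true(all(sim$truth$visible))
  # Poisson(0.01) is essentially always 0, so every emitter emits the floor
  expect_equal(length(sim$localizations), 5L * 10L * 5L)
})

test_that("expansion scales ground-truth pairwise distances exactly", {
  d <- standardDesign("linear28")
  base <- simulationConfig(nObjects = 6, intrinsicJitter = 0, gelDistortion = 0,
                           backgroundDensity = 0, seed = 11)
  exp25 <- base; exp25@expansionFactor <- 2.5
  t1 <- simulateField(d, base, "pre")$truth
  t2 <- simulateField(d, exp25, "pre")$truth
  p1 <- cbind(t1$x_true_nm, t1$y_true_nm)
  p2 <- cbind(t2$x_true_nm, t2$y_true_nm)
  expect_equal(as.numeric(stats::dist(p2)), 2.5 * as.numeric(stats::dist(p1)),
               tolerance = 1e-12)
})

test_that("pre/post displacement contrast matches the configured gel sigma", {
  d <- standardDesign("linear84")
  cfg <- simulationConfig(nObjects = 2500, gelDistortion = 16,
                          locsPerEmitterMean = 0.01, minLocsPerEmitter = 1,
                          backgroundDensity = 0, seed = 5)
  pre <- simulateField(d, cfg, "pre")$truth
  post <- simulateField(d, cfg, "post")$truth
  # same seed: pre and post share placement/jitter, differ by the gel vector
  dx <- post$x_true_nm - pre$x_true_nm
  dy <- post$y_true_nm - pre$y_true_nm
  expect_gte(length(dx), 1e4)
  empVar <- stats::var(c(dx, dy))
  expect_lt(abs(empVar - 16^2) / 16^2, 0.05)
  expect_true(all(pre$dx_gel_nm == 0))
  expect_equal(post$dx_gel_nm, dx)
})

test_that("missing emitters create nearest-neighbor distances at spacing multiples", {
  d <- standardDesign("linear28")
  cfg <- simulationConfig(nObjects = 60, labelingEfficiency = 0.8,
                          intrinsicJitter = 0, backgroundDensity = 0, seed = 9)
  tr <- simulateField(d, cfg, "pre")$truth
  gaps <- unlist(lapply(split(tr[tr$visible, ], tr$object_id[tr$visible]),
                        function(o) {
    p <- cbind(o$x_true_nm, o$y_true_nm)
    if (nrow(p) < 2) return(NULL)
    sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))
  }))
  expect_true(any(abs(gaps - 56) < 1e-6))
  expect_true(any(abs(gaps - 84) < 1e-6))
})

test_that("configuration invariants are enforced", {
  expect_error(simulationConfig(labelingEfficiency = 0), "labelingEfficiency")
  expect_error(simulationConfig(labelingEfficiency = 1.2), "labelingEfficiency")
  expect_error(simulationConfig(localizationPrecision = -1), "sigma")
  expect_error(simulationConfig(expansionFactor = 0.5), "expansionFactor")
  expect_error(simulationConfig(fieldSize = c(-1, 90)), "fieldSize")
})
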