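test_that("blurred rendering preserves mass and peak positions", {
  p <- clusteringParams(blurSigma = 4, renderPixel = 2)

  # single localization: maximum at its pixel
  tab <- localizationTable(50, 50)
  img <- renderBlurred(tab, p, bounds = c(0, 100, 0, 100))
  ix <- which(img@pixels == max(img@pixels), arr.ind = TRUE)
  expect_equal(unname(ix[1, ]), c(26, 26))  # pixel containing (50, 50)

  # kernel normalization: total intensity = n within 1% for interior points
  set.seed(3)
  xy <- matrix(runif(400, 40, 160), ncol = 2)
  img <- renderBlurred(loc_table(xy), p, bounds = c(0, 200, 0, 200))
  expect_lt(abs(sum(img@pixels) - 200) / 200, 0.01)

  # two localizations 40 nm apart at blur sigma 4: two distinct maxima
  tab2 <- localizationTable(c(80, 120), c(100, 100))
  img2 <- renderBlurred(tab2, p, bounds = c(40, 160, 60, 140))
  mx <- localMaxima(img2, minDistance = 7, threshold = 0.2)
  expect_equal(nrow(mx), 2L)
  expect_equal(sort(mx[, 1]), c(80, 120), tolerance = 0.05)

  expect_error(renderBlurred(tab, p, bounds = c(10, 10, 0, 100)), "degenerate")
})

test_that("maxima-seeded K-means resolves spacings DBSCAN cannot", {
  # tightly packed localizations: a single cluster at the point
  set.seed(5)
  tight <- loc_table(make_cloud(c(10, 10), 80, 0.5))
  res <- maximaSeededKmeans(tight, clusteringParams())
  expect_equal(nrow(centroids(res)), 1L)
  expect_equal(centroids(res)[1, ], c(10, 10), tolerance = 0.3,
               ignore_attr = TRUE)

  # five emitters spaced 11 nm on a line, sigma 3 clouds
  set.seed(17)
  centersTrue <- cbind(11 * (0:4), 0)
  xy <- do.call(rbind, lapply(1:5, function(i) make_cloud(centersTrue[i, ], 100, 3)))
  tab <- loc_table(xy)
  km <- maximaSeededKmeans(tab, clusteringParams())
  expect_equal(nrow(centroids(km)), 5L)
  err <- sqrt(rowSums((centroids(km) - centersTrue)^2))
  expect_lt(max(err), 2)

  # while DBSCAN at eps 12 joins them into fewer clusters
  db <- clusterDbscan(tab, clusteringParams(eps = 12, minPts = 5))
  expect_lt(nrow(centroids(db)), 5L)
})

test_that("converged K-means is a fixed point of nearest-center assignment", {
  set.seed(23)
  xy <- do.call(rbind, lapply(0:4, function(i) make_cloud(c(11 * i, 0), 100, 3)))
  tab <- loc_table(xy)
  km <- maximaSeededKmeans(tab, clusteringParams())
  cent <- centroids(km)
  # brute-force nearest-center assignment
  d2 <- outer(rowSums(xy^2), rep(1, nrow(cent))) - 2 * xy %*% t(cent) +
    outer(rep(1, nrow(xy)), rowSums(cent^2))
  nearest <- max.col(-d2, ties.method = "first")
  for (k in seq_len(nrow(cent))) {
    got <- sort(membership(km)[[k]])
    # identify which final cluster this centroid corresponds to
    want <- which(nearest == which.min(colSums((t(cent) - cent[k, ])^2)))
    expect_equal(got, want)
    # and the centroids agree with an independent Lloyd run from the same seeds
  }
  # cross-check against stats::kmeans started from the converged centers:
  # a fixed point should not move
  ref <- stats::kmeans(xy, centers = cent, iter.max = 50, algorithm = "Lloyd")
  ord <- order(ref$centers[, 1])
  expect_equal(unname(ref$centers[ord, , drop = FALSE]), unname(cent),
               tolerance = 1e-6)
})

test_that("the K-means objective never increases across iterations", {
  set.seed(31)
  xy <- do.call(rbind, lapply(0:3, function(i) make_cloud(c(12 * i, 5 * (i %% 2)), 80, 3)))
  km <- maximaSeededKmeans(loc_table(xy), clusteringParams())
  obj <- attr(km, "objective")
  expect_gt(length(obj), 1L)
  expect_true(all(diff(obj) <= 1e-9))
})
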