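make_cluster_set <- function(p) {
  new("EmitterClusterSet", centroids = p,
      membership = as.list(seq_len(nrow(p))),
      nLocalizations = rep(1L, nrow(p)))
}

test_that("single-linkage grouping follows chains up to the radius", {
  # ten collinear clusters 28 nm apart: one candidate
  p <- cbind(28 * (0:9), 0)
  g <- groupClusters(make_cluster_set(p), 100)
  expect_length(g, 1L)
  expect_equal(nrow(centroids(g[[1]])), 10L)

  # two such objects 2 um apart: two candidates
  p2 <- rbind(p, cbind(28 * (0:9), 2000))
  g2 <- groupClusters(make_cluster_set(p2), 100)
  expect_length(g2, 2L)

  # chain break: {0, 90} and {200} at radius 100
  p3 <- cbind(c(0, 90, 200), 0)
  g3 <- groupClusters(make_cluster_set(p3), 100)
  sizes <- sort(vapply(g3, function(s) nrow(centroids(s)), numeric(1)))
  expect_equal(sizes, c(1, 2))
})

test_that("straightness is the rotation-invariant TLS R-squared", {
  # exactly collinear at arbitrary orientation: R^2 = 1
  for (th in c(0, pi / 7, pi / 2, 2.1)) {
    p <- cbind(28 * (0:4), 0) %*% t(rot2(th))
    expect_equal(as.numeric(straightness(p)), 1, tolerance = 1e-12)
  }

  # corners + center of a square: isotropic scatter, far below 0.9
  sq <- rbind(c(0, 0), c(100, 0), c(0, 100), c(100, 100), c(50, 50))
  expect_lt(as.numeric(straightness(sq)), 0.6)

  # noisy 45-degree line matches the SVD reference to 1e-9
  set.seed(12)
  along <- seq(0, 250, length.out = 8)
  p <- cbind(along, rnorm(8, 0, 5)) %*% t(rot2(pi / 4))
  r2 <- straightness(p)
  expect_gt(as.numeric(r2), 0.9)
  expect_equal(as.numeric(r2), oracle_straightness(p), tolerance = 1e-9)

  expect_error(straightness(p[1:2, ]), "at least 3")
  expect_error(straightness(matrix(5, 4, 2)), "identical")
})

test_that("object selection applies the cluster-count and straightness rules", {
  four <- make_cluster_set(cbind(28 * (0:3), 0))          # R^2 = 1, 4 clusters
  six <- make_cluster_set(cbind(28 * (0:5), c(0, 2, -2, 1, 0, -1)))
  sel <- selectLinearObjects(list(four, six), minClusters = 5, r2Min = 0.9)
  expect_length(sel, 1L)
  expect_equal(nrow(centroids(sel[[1]])), 6L)
  expect_gt(sel[[1]]@straightness, 0.9)

  # rows: 2 clusters rejected, 5 collinear accepted
  two <- make_cluster_set(cbind(c(0, 11), 0))
  five <- make_cluster_set(cbind(11 * (0:4), 0))
  rows <- selectRows(list(two, five))
  expect_length(rows, 1L)
  expect_equal(rows[[1]]@kind, "rectangular_row")
})

test_that("selection is monotone in both thresholds", {
  set.seed(77)
  cands <- lapply(1:40, function(i) {
    n <- sample(3:8, 1)
    make_cluster_set(cbind(28 * seq_len(n), rnorm(n, 0, sample(c(1, 8, 20), 1))))
  })
  nAcc <- function(mc, r2) length(selectLinearObjects(cands, mc, r2))
  for (mc in 3:6) expect_gte(nAcc(mc, 0.9), nAcc(mc + 1, 0.9))
  for (r2 in c(0.5, 0.7, 0.9)) expect_gte(nAcc(3, r2), nAcc(3, r2 + 0.05))
})

test_that("ROI selection applies the strict density rule", {
  expect_length(selectRois(localizationTable(numeric(0), numeric(0), integer(0))), 0L)

  # 31 localizations inside one window: exactly one ROI with all 31
  set.seed(4)
  tab31 <- localizationTable(runif(31, 500, 900), runif(31, 500, 900))
  rois <- selectRois(tab31)
  expect_length(rois, 1L)
  expect_equal(length(rois[[1]]), 31L)

  # exactly 30 localizations: "more than 30" is strict, no ROI
  tab30 <- tab31[1:30]
  expect_length(selectRois(tab30), 0L)
})

test_that("two-row fitting recovers exact geometry and is rotation invariant", {
  k <- 8
  base <- rbind(cbind(11 * (1:k), 0), cbind(11 * (1:k), 30))
  pts <- base[rep(seq_len(nrow(base)), each = 5), ]
  fit <- fitTwoRows(loc_table(pts))
  expect_equal(fit@rowSpacing, 30, tolerance = 1e-9)
  expect_equal(as.integer(table(fit@assignments)), c(40L, 40L))

  for (th in c(0.3, 1.2, pi / 2)) {
    rotated <- pts %*% t(rot2(th))
    fitR <- fitTwoRows(loc_table(rotated))
    expect_equal(fitR@rowSpacing, 30, tolerance = 1e-9)
  }

  # translation invariance
  fitT <- fitTwoRows(loc_table(sweep(pts, 2, c(5e4, -3e4), `+`)))
  expect_equal(fitT@rowSpacing, 30, tolerance = 1e-9)

  # a single row cannot be split into two
  one_row <- loc_table(cbind(11 * (1:8), 0)[rep(1:8, each = 5), ])
  expect_error(fitTwoRows(one_row), "degenerate|empty")
})

test_that("two-row fitting recovers the design spacing under realistic noise", {
  set.seed(21)
  spacings <- replicate(50, {
    th <- runif(1, 0, 2 * pi)
    base <- rbind(cbind(11 * (1:8), 0), cbind(11 * (1:8), 30))
    sites <- (base + matrix(rnorm(32, 0, 1.5), 16, 2)) %*% t(rot2(th))
    pts <- do.call(rbind, lapply(seq_len(16), function(i) {
      make_cloud(sites[i, ], 30, 3)
    }))
    fitTwoRows(loc_table(pts))@rowSpacing
  })
  expect_lt(abs(mean(spacings) - 30), 1)
})

test_that("axis projection behaves as a 1D shadow", {
  p <- cbind(seq(0, 100, 10), 0)
  expect_true(all(abs(projectOntoAxis(p, c(0, 1))) < 1e-12))

  # rectangular ROI projected perpendicular to the rows is bimodal
  base <- rbind(cbind(11 * (1:8), 0), cbind(11 * (1:8), 30))
  pts <- base[rep(1:16, each = 20), ] + matrix(rnorm(640, 0, 1), ncol = 2)
  perp <- projectOntoAxis(pts, c(0, 1))
  km <- stats::kmeans(perp, centers = c(min(perp), max(perp)))
  expect_equal(abs(diff(sort(km$centers))), 30, tolerance = 0.5)

  expect_error(projectOntoAxis(p, c(0, 0)), "nonzero")
})

test_that("geometry outputs are invariant under rigid motion", {
  set.seed(31)
  p <- cbind(28 * (0:6), rnorm(7, 0, 3))
  nn0 <- sort(distances(nnDistances(p)))
  r20 <- as.numeric(straightness(p))
  for (i in 1:5) {
    q <- sweep(p %*% t(rot2(runif(1, 0, 2 * pi))), 2, runif(2, -1e5, 1e5), `+`)
    expect_equal(sort(distances(nnDistances(q))), nn0, tolerance = 1e-9)
    expect_equal(as.numeric(straightness(q)), r20, tolerance = 1e-9)
  }
})
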