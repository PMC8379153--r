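# Independent reference implementations used to cross-check the package.
# These deliberately take the slow, obvious route (full distance matrices,
# explicit enumeration) and share no code with the implementations they test.

# O(n^2) reference DBSCAN: full distance matrix, explicit neighbor lists,
# scan in ascending row order, border points keep the first cluster that
# reaches them. Labels: 0 = noise, >0 = cluster id in discovery order.
oracle_dbscan <- function(xy, eps, minPts) {
  n <- nrow(xy)
  D <- as.matrix(stats::dist(xy))
  nbrs <- lapply(seq_len(n), function(i) which(D[i, ] <= eps))
  core <- lengths(nbrs) >= minPts
  labels <- rep(NA_integer_, n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (!is.na(labels[i])) next
    if (!core[i]) { labels[i] <- 0L; next }
    cid <- cid + 1L
    labels[i] <- cid
    queue <- setdiff(nbrs[[i]], i)
    while (length(queue)) {
      q <- queue[1]
      queue <- queue[-1]
      if (!is.na(labels[q])) {
        if (labels[q] == 0L) labels[q] <- cid  # border point
        next
      }
      labels[q] <- cid
      if (core[q]) queue <- c(queue, nbrs[[q]])
    }
  }
  labels
}

# canonical form of a clustering: list of sorted member-index vectors,
# ordered by their smallest member
canon_membership <- function(memb) {
  m <- lapply(memb, sort)
  m[order(vapply(m, min, integer(1)))]
}

canon_from_labels <- function(labels) {
  canon_membership(unname(split(seq_along(labels), labels)[as.character(
    sort(unique(labels[labels > 0L])))]))
}

# exhaustive nearest-neighbor dedup oracle: the set of unordered pairs
# {i, argmin_j d(i, j)}, smallest-index tie break, one distance per pair
oracle_nn_dedup <- function(p) {
  k <- nrow(p)
  D <- as.matrix(stats::dist(p))
  diag(D) <- Inf
  pairs <- unique(t(vapply(seq_len(k), function(i) {
    j <- which.min(D[i, ])
    c(min(i, j), max(i, j))
  }, integer(2))))
  sort(D[pairs])
}

# straightness oracle via singular value decomposition
oracle_straightness <- function(p) {
  s <- svd(sweep(p, 2, colMeans(p)))$d
  1 - s[2]^2 / sum(s^2)
}

rot2 <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
}

# Gaussian localization cloud around a center
make_cloud <- function(center, n, sigma) {
  cbind(center[1] + rnorm(n, 0, sigma), center[2] + rnorm(n, 0, sigma))
}

# random DBSCAN test instance: a few Gaussian blobs plus uniform noise
random_instance <- function(maxN = 500) {
  k <- sample(1:8, 1)
  centers <- matrix(runif(2 * k, 0, 300), k, 2)
  pts <- do.call(rbind, lapply(seq_len(k), function(i) {
    make_cloud(centers[i, ], sample(5:60, 1), runif(1, 2, 15))
  }))
  noise <- matrix(runif(2 * sample(5:40, 1), -20, 320), ncol = 2)
  pts <- rbind(pts, noise)
  pts[seq_len(min(nrow(pts), maxN)), , drop = FALSE]
}

loc_table <- function(xy) localizationTable(xy[, 1], xy[, 2])
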