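#' ROI selection parameters
#'
#' Defaults implement the density rule used for rectangular origami: keep
#' regions holding strictly more than 30 localizations per 4 square
#' micrometers.
#'
#' @param minLocalizations strict lower count per window (default 30).
#' @param roiArea window area in um^2 (default 4, i.e. 2 x 2 um windows).
#' @param groupingRadius single-linkage radius for cluster grouping, nm
#'   (default 100: above the largest design gap of 84 nm, far below
#'   inter-object distances in a sparse field).
#' @return a validated [RoiSelectionParams].
#' @export
roiSelectionParams <- function(minLocalizations = 30, roiArea = 4,
                               groupingRadius = 100) {
  new("RoiSelectionParams", minLocalizations = minLocalizations,
      roiArea = roiArea, groupingRadius = groupingRadius)
}

# connected components of an undirected adjacency (list of integer neighbor
# vectors); returns integer component labels
.components <- function(adj) {
  n <- length(adj)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s]) next
    cur <- cur + 1L
    stack <- s
    while (length(stack)) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (comp[v]) next
      comp[v] <- cur
      stack <- c(stack, adj[[v]][comp[adj[[v]]] == 0L])
    }
  }
  comp
}

#' Group emitter clusters into candidate origami objects
#'
#' Single-linkage grouping: two clusters belong to the same candidate object
#' iff a chain of clusters connects them with consecutive centroid distances
#' at most `groupingRadius`.
#'
#' @param clusters an [EmitterClusterSet].
#' @param groupingRadius linkage radius, nm (> 0).
#' @return a list of [EmitterClusterSet] candidates (singletons included),
#'   ordered by their first centroid.
#' @export
groupClusters <- function(clusters, groupingRadius = 100) {
  stopifnot(is(clusters, "EmitterClusterSet"))
  if (groupingRadius <= 0) stop("groupingRadius must be > 0")
  cent <- centroids(clusters)
  k <- nrow(cent)
  if (k == 0L) return(list())
  d <- as.matrix(stats::dist(cent))
  adj <- lapply(seq_len(k), function(i) which(d[i, ] <= groupingRadius & seq_len(k) != i))
  comp <- .components(adj)
  lapply(seq_len(max(comp)), function(g) {
    ix <- which(comp == g)
    new("EmitterClusterSet",
        centroids = cent[ix, , drop = FALSE],
        membership = clusters@membership[ix],
        nLocalizations = clusters@nLocalizations[ix])
  })
}

.as_centroid_matrix <- function(x) {
  if (is(x, "EmitterClusterSet")) return(centroids(x))
  if (is(x, "OrigamiObject")) return(centroids(x))
  if (is.matrix(x)) return(x)
  stop("expected an EmitterClusterSet, OrigamiObject, or matrix of centroids")
}

# principal axis (unit vector, sign fixed to positive x, then positive y)
# and eigenvalues of the centroid scatter
.principal_axis <- function(p) {
  ctr <- sweep(p, 2, colMeans(p))
  ev <- eigen(crossprod(ctr) / nrow(p), symmetric = TRUE)
  ax <- ev$vectors[, 1]
  if (ax[1] < 0 || (ax[1] == 0 && ax[2] < 0)) ax <- -ax
  list(axis = ax, values = ev$values)
}

#' Straightness of a cluster chain (total-least-squares R-squared)
#'
#' Fits the principal axis through the cluster centroids and returns
#' `1 - (perpendicular residual sum of squares) / (total scatter)`, which is
#' rotation-invariant (unlike y-on-x regression, which would spuriously
#' reject vertically oriented objects). Exactly collinear centroids give 1.
#'
#' @param x an [EmitterClusterSet], [OrigamiObject], or centroid matrix with
#'   at least 3 rows.
#' @return R-squared in \[0, 1\], with the unit principal axis attached as
#'   attribute `"axis"`.
#' @export
straightness <- function(x) {
  p <- .as_centroid_matrix(x)
  if (nrow(p) < 3L) stop("straightness needs at least 3 clusters")
  pa <- .principal_axis(p)
  tot <- sum(pa$values)
  if (tot <= 0) stop("straightness undefined: all centroids identical")
  r2 <- 1 - pa$values[2] / tot
  attr(r2, "axis") <- pa$axis
  r2
}

#' Select straight origami objects
#'
#' Keeps candidates with at least `minClusters` clusters whose centroids form
#' a straight line (total-least-squares R-squared strictly above `r2Min`).
#'
#' @param candidates list of [EmitterClusterSet] (from [groupClusters()]).
#' @param minClusters minimum cluster count (default 5, the linear-origami
#'   rule; use 3 for rectangular rows and sparse 4-site designs).
#' @param r2Min straightness threshold (default 0.9).
#' @param kind object kind recorded on the result.
#' @return list of accepted [OrigamiObject]s, with the selection rate
#'   (accepted / candidates) attached as attribute `"selectionRate"`.
#' @export
selectLinearObjects <- function(candidates, minClusters = 5, r2Min = 0.9,
                                kind = "linear") {
  accepted <- list()
  for (cand in candidates) {
    k <- nrow(centroids(cand))
    if (k < minClusters || k < 3L) next
    r2 <- straightness(cand)
    if (r2 > r2Min) {
      accepted[[length(accepted) + 1L]] <-
        new("OrigamiObject", clusters = cand, straightness = as.numeric(r2),
            axis = attr(r2, "axis"), kind = kind)
    }
  }
  attr(accepted, "selectionRate") <-
    if (length(candidates)) length(accepted) / length(candidates) else NA_real_
  accepted
}

#' Select rows of a rectangular origami
#'
#' Same rule as [selectLinearObjects()] with the rectangular-row default of
#' at least 3 clusters in a straight line.
#'
#' @param rowClusters list of [EmitterClusterSet], one per candidate row.
#' @param minClusters minimum cluster count (default 3).
#' @param r2Min straightness threshold (default 0.9).
#' @return list of accepted [OrigamiObject]s with `kind = "rectangular_row"`.
#' @export
selectRows <- function(rowClusters, minClusters = 3, r2Min = 0.9) {
  selectLinearObjects(rowClusters, minClusters = minClusters, r2Min = r2Min,
                      kind = "rectangular_row")
}

#' Select dense regions of interest
#'
#' Tiles the field with square windows of area `roiArea` um^2 on a grid whose
#' step is half the window side, keeps windows containing strictly more than
#' `minLocalizations` localizations, merges overlapping kept windows, and
#' returns each merged region's localizations as one ROI.
#'
#' @param table a [LocalizationTable].
#' @param params a [RoiSelectionParams].
#' @return list of [LocalizationTable] ROIs (possibly empty). Each ROI
#'   carries its source row indices as attribute `"indices"`.
#' @export
selectRois <- function(table, params = roiSelectionParams()) {
  stopifnot(is(table, "LocalizationTable"))
  validObject(params)
  xy <- coords(table)
  if (nrow(xy) == 0L) return(list())
  side <- sqrt(params@roiArea) * 1000  # nm
  step <- side / 2

  # half-step cells; a window is a 2x2 block of cells
  cx <- as.integer(floor((xy[, 1] - min(xy[, 1])) / step))
  cy <- as.integer(floor((xy[, 2] - min(xy[, 2])) / step))
  ncx <- max(cx) + 1L; ncy <- max(cy) + 1L
  cellCount <- matrix(0L, ncx + 1L, ncy + 1L)  # pad so 2x2 sums are in range
  idx <- cbind(cx + 1L, cy + 1L)
  for (r in seq_len(nrow(idx))) {
    cellCount[idx[r, 1], idx[r, 2]] <- cellCount[idx[r, 1], idx[r, 2]] + 1L
  }
  winCount <- cellCount[seq_len(ncx), seq_len(ncy), drop = FALSE] +
    cellCount[seq_len(ncx) + 1L, seq_len(ncy), drop = FALSE] +
    cellCount[seq_len(ncx), seq_len(ncy) + 1L, drop = FALSE] +
    cellCount[seq_len(ncx) + 1L, seq_len(ncy) + 1L, drop = FALSE]
  kept <- which(winCount > params@minLocalizations, arr.ind = TRUE)
  if (!nrow(kept)) return(list())

  # windows overlap iff their grid indices differ by <= 1 in both axes
  adj <- lapply(seq_len(nrow(kept)), function(i) {
    which(abs(kept[, 1] - kept[i, 1]) <= 1L & abs(kept[, 2] - kept[i, 2]) <= 1L &
            seq_len(nrow(kept)) != i)
  })
  comp <- .components(adj)

  # a localization belongs to a window iff its cell is one of the window's 2x2
  winOfCell <- function(wx, wy) (cx >= wx - 1L) & (cx <= wx) & (cy >= wy - 1L) & (cy <= wy)
  lapply(seq_len(max(comp)), function(g) {
    wix <- which(comp == g)
    inRoi <- rep(FALSE, nrow(xy))
    for (w in wix) {
      inRoi <- inRoi | winOfCell(kept[w, 1], kept[w, 2])
    }
    roi <- table[which(inRoi)]
    attr(roi, "indices") <- which(inRoi)
    roi
  })
}

#' Fit two parallel rows to a rectangular-origami ROI
#'
#' Estimates the common row direction and splits localizations into the two
#' rows. The initial direction is the ROI's principal axis; localizations are
#' split by 1D 2-means on the perpendicular coordinate; the direction is then
#' re-estimated as the principal axis of the within-row-centered
#' localizations and the split repeated until stable. The refinement step
#' matters: the whole-ROI principal axis is tilted by uneven site occupancy
#' between the rows, which biases the recovered spacing low by ~1 nm.
#'
#' @param roi a [LocalizationTable] holding one rectangular origami.
#' @param minPts minimum localizations per row (default 5); the ROI must hold
#'   at least `2 * minPts`.
#' @param maxIter direction-refinement iterations (default 10).
#' @return a [TwoRowFit].
#' @export
fitTwoRows <- function(roi, minPts = 5, maxIter = 10L) {
  stopifnot(is(roi, "LocalizationTable"))
  xy <- coords(roi)
  if (nrow(xy) < 2 * minPts) stop("ROI has too few localizations for a two-row fit")
  ctr <- sweep(xy, 2, colMeans(xy))
  axis <- .principal_axis(xy)$axis
  split <- NULL
  for (it in seq_len(maxIter)) {
    perp <- drop(ctr %*% c(-axis[2], axis[1]))
    cen <- stats::quantile(perp, c(0.25, 0.75), names = FALSE)
    if (cen[1] == cen[2]) cen <- range(perp)
    for (ll in 1:100) {
      a <- abs(perp - cen[1]) <= abs(perp - cen[2])
      if (!any(a) || all(a)) break
      newCen <- c(mean(perp[a]), mean(perp[!a]))
      if (max(abs(newCen - cen)) < 1e-6) { cen <- newCen; break }
      cen <- newCen
    }
    if (!any(a) || all(a)) stop("degenerate ROI: one row is empty after the split")
    newSplit <- a
    # re-estimate the direction with the row offsets removed
    centered <- ctr
    centered[a, ] <- sweep(ctr[a, , drop = FALSE], 2, colMeans(ctr[a, , drop = FALSE]))
    centered[!a, ] <- sweep(ctr[!a, , drop = FALSE], 2, colMeans(ctr[!a, , drop = FALSE]))
    newAxis <- .principal_axis(centered)$axis
    done <- !is.null(split) && identical(newSplit, split) &&
      sum(abs(newAxis - axis)) < 1e-12
    axis <- newAxis
    split <- newSplit
    if (done) break
  }
  perp <- drop(ctr %*% c(-axis[2], axis[1]))
  off <- c(mean(perp[split]), mean(perp[!split]))
  rowLab <- ifelse(split, 1L, 2L)
  if (off[1] > off[2]) {  # deterministic: row 1 has the smaller offset
    off <- rev(off)
    rowLab <- 3L - rowLab
  }
  new("TwoRowFit", commonDirection = axis, rowOffsets = off,
      rowSpacing = abs(off[2] - off[1]), assignments = rowLab)
}

#' Project points onto an axis
#'
#' Signed scalar projections of the points about their centroid onto a unit
#' direction; used for 1D multi-Gaussian fitting of row profiles.
#'
#' @param points numeric matrix (n x 2) or [LocalizationTable].
#' @param direction length-2 direction vector (normalized internally; the
#'   zero vector is an error).
#' @return numeric vector of projections, nm.
#' @export
projectOntoAxis <- function(points, direction) {
  if (is(points, "LocalizationTable")) points <- coords(points)
  nrm <- sqrt(sum(direction^2))
  if (!is.finite(nrm) || nrm == 0) stop("direction must be a nonzero vector")
  u <- direction / nrm
  ctr <- sweep(points, 2, colMeans(points))
  drop(ctr %*% u)
}
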