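#' Nearest-neighbor emitter distances within origami objects
#'
#' For each cluster, the Euclidean distance to its nearest neighboring
#' cluster within the same object. Each unordered pair is counted once: a
#' mutual nearest-neighbor pair contributes a single distance.
#'
#' @param x an [OrigamiObject], a centroid matrix, or a list of either (the
#'   distances are pooled; duplicates are only removed within an object).
#' @param ... unused.
#' @return an [NNDistanceSet] with `expansionFactor = 1`.
#' @name nnDistances
NULL

.nn_pairs <- function(p, label) {
  k <- nrow(p)
  if (k < 2L) stop("nearest-neighbor distances need at least 2 clusters")
  d <- as.matrix(stats::dist(p))
  diag(d) <- Inf
  nn <- apply(d, 1, which.min)  # smallest index wins ties (deterministic)
  pairs <- cbind(pmin(seq_len(k), nn), pmax(seq_len(k), nn))
  keep <- !duplicated(pairs)
  pairs <- pairs[keep, , drop = FALSE]
  list(distances = d[pairs],
       source = sprintf("%s:%d-%d", label, pairs[, 1], pairs[, 2]))
}

#' @rdname nnDistances
setMethod("nnDistances", "OrigamiObject", function(x, ...) {
  res <- .nn_pairs(centroids(x), "obj")
  new("NNDistanceSet", distances = res$distances, source = res$source,
      expansionFactor = 1)
})

#' @rdname nnDistances
setMethod("nnDistances", "matrix", function(x, ...) {
  res <- .nn_pairs(x, "obj")
  new("NNDistanceSet", distances = res$distances, source = res$source,
      expansionFactor = 1)
})

#' @rdname nnDistances
setMethod("nnDistances", "list", function(x, ...) {
  out <- lapply(seq_along(x), function(i) {
    .nn_pairs(.as_centroid_matrix(x[[i]]), sprintf("obj%d", i))
  })
  new("NNDistanceSet",
      distances = unlist(lapply(out, `[[`, "distances")) %||% numeric(0),
      source = unlist(lapply(out, `[[`, "source")) %||% character(0),
      expansionFactor = 1)
})

#' Rescale post-expansion distances to effective (pre-expansion) distances
#'
#' Distances measured in an expanded gel are divided by the expansion factor,
#' determined experimentally from the physical gel size, to give effective
#' distances comparable with unexpanded samples.
#'
#' @param nnd an [NNDistanceSet].
#' @param factor expansion factor (>= 1).
#' @return a new [NNDistanceSet] with the factor recorded.
#' @export
applyExpansion <- function(nnd, factor) {
  stopifnot(is(nnd, "NNDistanceSet"))
  if (!is.numeric(factor) || length(factor) != 1L || factor < 1) {
    stop("expansion factor must be a single number >= 1")
  }
  new("NNDistanceSet", distances = nnd@distances / factor,
      source = nnd@source, expansionFactor = nnd@expansionFactor * factor)
}

.gauss <- function(x, A, mu, sigma) A * exp(-(x - mu)^2 / (2 * sigma^2))

.failed_fit <- function(window, binWidth, msg, n) {
  new("PeakFit", mean = NA_real_, sigma = NA_real_, amplitude = NA_real_,
      fitWindow = window, binWidth = binWidth, converged = FALSE,
      diagnostics = list(message = msg, nDistances = n))
}

#' Fit a Gaussian to the first nearest-neighbor distance peak
#'
#' Histograms the distances at `binWidth` and fits
#' `A * exp(-(d - mu)^2 / (2 sigma^2))` to the bin centers/counts inside the
#' window `windowFactors * expectedSpacing` by unweighted least squares
#' (Levenberg-Marquardt), starting from `mu = expectedSpacing`,
#' `sigma = 0.3 * expectedSpacing`, `A` = tallest bin in the window. The
#' window keeps higher-order peaks (missing-emitter multiples of the design
#' spacing) out of the fit.
#'
#' @param nnd an [NNDistanceSet] or numeric vector of distances, nm.
#' @param expectedSpacing design spacing, nm.
#' @param binWidth histogram bin width, nm (default 2).
#' @param windowFactors window as multiples of `expectedSpacing`
#'   (default `c(0.5, 1.5)`).
#' @param minDistances minimum number of distances inside the window
#'   (default 30).
#' @return a [PeakFit]; failures (too few distances, degenerate histogram,
#'   optimizer failure, mean outside window) return `converged = FALSE` with
#'   diagnostics, never a silent number.
#' @export
fitFirstPeak <- function(nnd, expectedSpacing, binWidth = 2,
                         windowFactors = c(0.5, 1.5), minDistances = 30) {
  d <- if (is(nnd, "NNDistanceSet")) distances(nnd) else as.numeric(nnd)
  if (expectedSpacing <= 0) stop("expectedSpacing must be positive")
  window <- windowFactors * expectedSpacing
  nWin <- sum(d >= window[1] & d <= window[2])
  if (nWin < minDistances) {
    return(.failed_fit(window, binWidth,
                       sprintf("only %d distances in the fit window (need %d)",
                               nWin, minDistances), nWin))
  }
  breaks <- seq(0, max(d) + binWidth, by = binWidth)
  h <- graphics::hist(d, breaks = breaks, plot = FALSE)
  inWin <- h$mids >= window[1] & h$mids <= window[2]
  xs <- h$mids[inWin]
  ys <- h$counts[inWin]
  if (sum(ys > 0) < 4L) {
    return(.failed_fit(window, binWidth,
                       "degenerate histogram: fewer than 4 occupied bins", nWin))
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ A * exp(-(x - mu)^2 / (2 * sigma^2)),
      data = data.frame(x = xs, y = ys),
      start = list(A = max(ys), mu = expectedSpacing,
                   sigma = 0.3 * expectedSpacing),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(.failed_fit(window, binWidth, conditionMessage(fit), nWin))
  }
  cf <- stats::coef(fit)
  mu <- unname(cf["mu"]); sg <- abs(unname(cf["sigma"]))
  if (!is.finite(mu) || !is.finite(sg) || sg <= 0 ||
      mu <= window[1] || mu >= window[2]) {
    return(.failed_fit(window, binWidth,
                       "fitted peak outside the window or degenerate sigma", nWin))
  }
  new("PeakFit", mean = mu, sigma = sg, amplitude = unname(cf["A"]),
      fitWindow = window, binWidth = binWidth, converged = TRUE,
      diagnostics = list(message = "ok", nDistances = nWin))
}

#' Per-emitter gel distortion from pre/post peak widths
#'
#' The fitted first-peak width contains intrinsic structural variation plus
#' (after denaturation) gel-introduced per-emitter displacement. Each of the
#' two emitters in a distance receives an independent displacement whose
#' component along the inter-emitter axis is Gaussian, so independent
#' per-emitter errors add in quadrature in the pairwise distance:
#' `sigma_post^2 = sigma_pre^2 + 2 * sigma_emitter^2` (transverse
#' second-order terms are negligible when the spacing is much larger than
#' the distortion, which is why the sparse 84-nm design is used). Hence
#' `sigma_emitter = sqrt((sigma_post^2 - sigma_pre^2) / 2)` and
#' `FWHM = 2 sqrt(2 ln 2) * sigma_emitter`.
#'
#' @param fitPre converged [PeakFit] before denaturation.
#' @param fitPost converged [PeakFit] after denaturation.
#' @return a [DistortionEstimate]; when `sigma_post < sigma_pre` (possible by
#'   sampling noise at small true distortion) the estimate is zero and
#'   flagged `valid = FALSE` rather than clamped silently.
#' @export
estimateDistortion <- function(fitPre, fitPost) {
  stopifnot(is(fitPre, "PeakFit"), is(fitPost, "PeakFit"))
  if (!fitPre@converged || !fitPost@converged) {
    stop("estimateDistortion requires two converged peak fits")
  }
  excess <- fitPost@sigma^2 - fitPre@sigma^2
  if (excess < 0) {
    se <- 0; ok <- FALSE
  } else {
    se <- sqrt(excess / 2); ok <- TRUE
  }
  new("DistortionEstimate", sigmaPre = fitPre@sigma, sigmaPost = fitPost@sigma,
      sigmaEmitter = se, fwhmEmitter = 2 * sqrt(2 * log(2)) * se, valid = ok)
}

#' Fit a sum of Gaussians to a 1D projection
#'
#' Histograms the projected coordinates and fits a sum of `nPeaks` Gaussians
#' by unweighted least squares, with means initialized at the `nPeaks`
#' highest local maxima of the histogram (picked greedily in order of
#' decreasing count, skipping candidates closer than `minSeparation` to an
#' already-picked one, so count noise inside one peak cannot seed two
#' Gaussians), common initial sigma of half the median gap between the
#' initial means, and amplitudes at the local-maximum counts.
#'
#' @param projected numeric vector of 1D coordinates, nm (e.g. from
#'   [projectOntoAxis()]).
#' @param nPeaks number of Gaussians (>= 1).
#' @param binWidth histogram bin width, nm (default 1).
#' @param minPointsPerPeak minimum points per expected peak (default 20).
#' @param minSeparation minimum distance between initial peak positions, nm
#'   (default `3 * binWidth`).
#' @return list of [PeakFit], sorted by mean. If fewer local maxima than
#'   `nPeaks` are found or the optimizer fails, a single unconverged
#'   [PeakFit] is returned (in a list) with diagnostics.
#' @export
fitMultiGaussian1d <- function(projected, nPeaks, binWidth = 1,
                               minPointsPerPeak = 20,
                               minSeparation = 3 * binWidth) {
  if (nPeaks < 1) stop("nPeaks must be >= 1")
  x <- as.numeric(projected)
  window <- range(x)
  if (length(x) < nPeaks * minPointsPerPeak) {
    return(list(.failed_fit(window, binWidth, "too few points per peak", length(x))))
  }
  breaks <- seq(min(x) - binWidth, max(x) + binWidth, by = binWidth)
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)
  cnt <- h$counts
  nb <- length(cnt)
  isMax <- cnt > 0
  if (nb > 1) {
    isMax <- isMax & cnt >= c(-Inf, cnt[-nb]) & cnt >= c(cnt[-1], -Inf)
  }
  cand <- which(isMax)
  cand <- cand[order(-cnt[cand], cand)]
  picked <- integer(0)
  for (i in cand) {
    if (length(picked) == nPeaks) break
    if (!length(picked) ||
        min(abs(h$mids[i] - h$mids[picked])) >= minSeparation) {
      picked <- c(picked, i)
    }
  }
  if (length(picked) < nPeaks) {
    return(list(.failed_fit(window, binWidth,
                            sprintf("found %d separated local maxima, need %d",
                                    length(picked), nPeaks), length(x))))
  }
  mu0 <- sort(h$mids[picked])
  a0 <- cnt[match(mu0, h$mids)]
  s0 <- if (nPeaks > 1) max(binWidth, stats::median(diff(mu0)) / 2) else stats::sd(x)

  form <- paste0("y ~ ", paste(sprintf("A%d * exp(-(x - mu%d)^2 / (2 * s%d^2))",
                                       seq_len(nPeaks), seq_len(nPeaks),
                                       seq_len(nPeaks)), collapse = " + "))
  start <- c(as.list(stats::setNames(a0, paste0("A", seq_len(nPeaks)))),
             as.list(stats::setNames(mu0, paste0("mu", seq_len(nPeaks)))),
             as.list(stats::setNames(rep(s0, nPeaks), paste0("s", seq_len(nPeaks)))))
  fit <- tryCatch(
    minpack.lm::nlsLM(stats::as.formula(form),
                      data = data.frame(x = h$mids, y = cnt),
                      start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(list(.failed_fit(window, binWidth, conditionMessage(fit), length(x))))
  }
  cf <- stats::coef(fit)
  peaks <- lapply(seq_len(nPeaks), function(i) {
    new("PeakFit",
        mean = unname(cf[paste0("mu", i)]),
        sigma = abs(unname(cf[paste0("s", i)])),
        amplitude = unname(cf[paste0("A", i)]),
        fitWindow = window, binWidth = binWidth, converged = TRUE,
        diagnostics = list(message = "ok", nDistances = length(x)))
  })
  peaks[order(vapply(peaks, function(p) p@mean, numeric(1)))]
}

#' Diagnostics for erroneously merged clusters
#'
#' When distortion pushes neighboring emitters close together, their
#' localization clouds can be misread as a single cluster. That removes the
#' short true spacing from the histogram and places the merged centroid
#' farther from its flanking neighbors, inflating the measured
#' nearest-neighbor distances. This reports the two signatures: the fraction
#' of selected objects with fewer clusters than designed sites, and the
#' fraction of distances beyond 1.5x the design spacing.
#'
#' @param objects list of [OrigamiObject].
#' @param expectedSpacing design spacing, nm.
#' @param designSites number of labeling sites in the design.
#' @return list with `fractionUnderCount`, `fractionLongDistances`,
#'   `nObjects`, `nDistances`, and `meanDistanceInWindow`.
#' @export
mergedClusterDiagnostic <- function(objects, expectedSpacing, designSites) {
  nObj <- length(objects)
  if (!nObj) {
    return(list(fractionUnderCount = NA_real_, fractionLongDistances = NA_real_,
                nObjects = 0L, nDistances = 0L, meanDistanceInWindow = NA_real_))
  }
  counts <- vapply(objects, function(o) nrow(centroids(o)), numeric(1))
  d <- distances(nnDistances(objects))
  inWin <- d >= 0.5 * expectedSpacing & d <= 1.5 * expectedSpacing
  list(fractionUnderCount = mean(counts < designSites),
       fractionLongDistances = mean(d > 1.5 * expectedSpacing),
       nObjects = nObj, nDistances = length(d),
       meanDistanceInWindow = if (any(inWin)) mean(d[inWin]) else NA_real_)
}
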