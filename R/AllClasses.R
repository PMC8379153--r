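#' @import methods
NULL

.unit_tol <- 1e-8

#' OrigamiDesign: labeling-site layout of a nanoruler
#'
#' Site positions of a DNA-origami nanoruler in its local (unrotated) frame,
#' in nanometers. Linear designs place all sites on one line; rectangular
#' designs place them on exactly two parallel lines.
#'
#' @slot name single character label (e.g. `"linear28"`).
#' @slot sitePositions numeric matrix, one row per labeling site, columns x/y (nm).
#' @slot kind `"linear"` or `"rectangular"`.
#' @export
setClass("OrigamiDesign",
  representation(name = "character", sitePositions = "matrix", kind = "character"))

setValidity("OrigamiDesign", function(object) {
  p <- object@sitePositions
  if (!is.numeric(p) || ncol(p) != 2L) return("sitePositions must be an n x 2 numeric matrix")
  if (nrow(p) < 2L) return("a design needs at least 2 sites")
  if (!object@kind %in% c("linear", "rectangular")) return("kind must be 'linear' or 'rectangular'")
  if (any(!is.finite(p))) return("site positions must be finite")
  ctr <- sweep(p, 2, colMeans(p))
  ev <- eigen(crossprod(ctr), symmetric = TRUE)
  if (object@kind == "linear") {
    if (ev$values[2] > .unit_tol * max(ev$values[1], 1)) {
      return("linear design sites must be exactly collinear")
    }
  } else {
    # perpendicular offsets must take exactly two values
    perp <- drop(ctr %*% ev$vectors[, 2])
    if (length(unique(round(perp, 6))) != 2L) {
      return("rectangular design sites must lie on exactly two parallel lines")
    }
  }
  TRUE
})

#' SimulationConfig: generative parameters for a synthetic STORM field
#'
#' All lengths are nanometers except `fieldSize` (micrometers). See
#' [simulationConfig()] for the documented defaults.
#'
#' @slot nObjects number of origami objects placed in the field.
#' @slot fieldSize width/height of the field, micrometers (length-2).
#' @slot labelingEfficiency per-site probability that a dye is present.
#' @slot locsPerEmitterMean Poisson mean of localizations per visible emitter.
#' @slot minLocsPerEmitter lower floor on localizations per visible emitter.
#' @slot localizationPrecision per-coordinate sigma (nm) of each localization
#'   about its emitter.
#' @slot intrinsicJitter per-coordinate sigma (nm) of per-site structural
#'   displacement, present in every condition.
#' @slot gelDistortion per-coordinate sigma (nm) of per-site displacement
#'   applied only in the `"post"` condition.
#' @slot expansionFactor isotropic scale factor about the field origin (>= 1).
#' @slot backgroundDensity background localizations per square micrometer.
#' @slot nFrames number of camera frames localizations are attributed to.
#' @slot seed integer seed making the simulation reproducible.
#' @export
setClass("SimulationConfig",
  representation(
    nObjects = "numeric", fieldSize = "numeric", labelingEfficiency = "numeric",
    locsPerEmitterMean = "numeric", minLocsPerEmitter = "numeric",
    localizationPrecision = "numeric", intrinsicJitter = "numeric",
    gelDistortion = "numeric", expansionFactor = "numeric",
    backgroundDensity = "numeric", nFrames = "numeric", seed = "numeric"))

setValidity("SimulationConfig", function(object) {
  if (object@nObjects < 0) return("nObjects must be >= 0")
  if (length(object@fieldSize) != 2L || any(object@fieldSize <= 0)) {
    return("fieldSize must be two positive values (um)")
  }
  if (object@labelingEfficiency <= 0 || object@labelingEfficiency > 1) {
    return("labelingEfficiency must be in (0, 1]")
  }
  sds <- c(object@localizationPrecision, object@intrinsicJitter, object@gelDistortion)
  if (any(sds < 0)) return("all sigma parameters must be >= 0")
  if (object@expansionFactor < 1) return("expansionFactor must be >= 1")
  if (object@backgroundDensity < 0) return("backgroundDensity must be >= 0")
  if (object@nFrames < 1) return("nFrames must be >= 1")
  if (object@minLocsPerEmitter < 1) return("minLocsPerEmitter must be >= 1")
  TRUE
})

#' LocalizationTable: molecule-list input to the pipeline
#'
#' One row per localization: lateral position in nanometers plus the camera
#' frame it was detected in. Extra columns of an input file are carried along
#' untouched in `extra`.
#'
#' @slot coords numeric matrix (n x 2) of x/y positions, nm.
#' @slot frame integer vector of frame indices (>= 1).
#' @slot extra data.frame of opaque extra columns (possibly zero columns).
#' @export
setClass("LocalizationTable",
  representation(coords = "matrix", frame = "integer", extra = "data.frame"))

setValidity("LocalizationTable", function(object) {
  if (ncol(object@coords) != 2L) return("coords must have two columns")
  if (any(!is.finite(object@coords))) return("coordinates must be finite")
  if (length(object@frame) != nrow(object@coords)) return("frame length must match coords")
  if (length(object@frame) && any(object@frame < 1L)) return("frame indices must be >= 1")
  if (nrow(object@extra) && nrow(object@extra) != nrow(object@coords)) {
    return("extra rows must match coords")
  }
  TRUE
})

#' ClusteringParams: parameters of the emitter-clustering stage
#'
#' @slot eps DBSCAN neighborhood radius, nm.
#' @slot minPts DBSCAN core threshold (point itself included) and the minimum
#'   cluster size kept by either clustering method.
#' @slot blurSigma Gaussian blur sigma (nm) for the maxima-seeding image.
#' @slot maximaMinDistance minimum separation (nm) between accepted local maxima.
#' @slot maximaThreshold intensity cut for maxima, as a fraction of the image max.
#' @slot renderPixel pixel size (nm) of the binned image used for blurring.
#' @export
setClass("ClusteringParams",
  representation(eps = "numeric", minPts = "numeric", blurSigma = "numeric",
                 maximaMinDistance = "numeric", maximaThreshold = "numeric",
                 renderPixel = "numeric"))

setValidity("ClusteringParams", function(object) {
  if (object@eps <= 0) return("eps must be > 0")
  if (object@minPts < 1) return("minPts must be >= 1")
  if (object@blurSigma <= 0) return("blurSigma must be > 0")
  if (object@maximaThreshold <= 0 || object@maximaThreshold >= 1) {
    return("maximaThreshold must be in (0, 1)")
  }
  if (object@maximaMinDistance < 0) return("maximaMinDistance must be >= 0")
  if (object@renderPixel <= 0) return("renderPixel must be > 0")
  TRUE
})

#' EmitterClusterSet: clusters of localizations, one per emitter
#'
#' Result of [clusterDbscan()] or [maximaSeededKmeans()]. Each cluster's
#' centroid is the arithmetic mean of its member localizations; membership
#' indices refer to rows of the source [LocalizationTable].
#'
#' @slot centroids numeric matrix (k x 2), nm.
#' @slot membership list of integer vectors of member row indices.
#' @slot nLocalizations integer vector of cluster sizes.
#' @export
setClass("EmitterClusterSet",
  representation(centroids = "matrix", membership = "list",
                 nLocalizations = "integer"))

setValidity("EmitterClusterSet", function(object) {
  k <- nrow(object@centroids)
  if (ncol(object@centroids) != 2L && k > 0) return("centroids must have two columns")
  if (length(object@membership) != k) return("membership length must equal cluster count")
  if (length(object@nLocalizations) != k) return("nLocalizations length must equal cluster count")
  if (k && any(object@nLocalizations != lengths(object@membership))) {
    return("nLocalizations must equal membership sizes")
  }
  TRUE
})

#' OrigamiObject: a selected group of emitter clusters
#'
#' @slot clusters the member [EmitterClusterSet].
#' @slot straightness total-least-squares R-squared of the cluster centroids.
#' @slot axis unit vector of the principal direction.
#' @slot kind `"linear"` or `"rectangular_row"`.
#' @export
setClass("OrigamiObject",
  representation(clusters = "EmitterClusterSet", straightness = "numeric",
                 axis = "numeric", kind = "character"))

setValidity("OrigamiObject", function(object) {
  if (nrow(object@clusters@centroids) < 2L) return("an object needs >= 2 clusters")
  if (!object@kind %in% c("linear", "rectangular_row")) {
    return("kind must be 'linear' or 'rectangular_row'")
  }
  if (length(object@axis) != 2L) return("axis must be length 2")
  TRUE
})

#' RoiSelectionParams: density rule for rectangular-origami regions of interest
#'
#' @slot minLocalizations a window is kept when it holds strictly more than
#'   this many localizations.
#' @slot roiArea window area in square micrometers (window side = sqrt(roiArea)).
#' @slot groupingRadius single-linkage radius (nm) used when grouping clusters
#'   into objects.
#' @export
setClass("RoiSelectionParams",
  representation(minLocalizations = "numeric", roiArea = "numeric",
                 groupingRadius = "numeric"))

setValidity("RoiSelectionParams", function(object) {
  if (object@minLocalizations <= 0 || object@roiArea <= 0 || object@groupingRadius <= 0) {
    return("all parameters must be positive")
  }
  TRUE
})

#' TwoRowFit: two parallel lines fitted to a rectangular-origami ROI
#'
#' @slot commonDirection unit vector shared by the two rows.
#' @slot rowOffsets perpendicular intercepts of the two rows, nm.
#' @slot rowSpacing absolute offset difference, nm.
#' @slot assignments integer row label (1 or 2) per localization.
#' @export
setClass("TwoRowFit",
  representation(commonDirection = "numeric", rowOffsets = "numeric",
                 rowSpacing = "numeric", assignments = "integer"))

setValidity("TwoRowFit", function(object) {
  if (length(object@commonDirection) != 2L) return("commonDirection must be length 2")
  if (abs(sqrt(sum(object@commonDirection^2)) - 1) > 1e-6) {
    return("commonDirection must be unit length")
  }
  if (length(object@rowOffsets) != 2L) return("rowOffsets must be length 2")
  if (object@rowSpacing < 0) return("rowSpacing must be >= 0")
  if (!all(object@assignments %in% c(1L, 2L))) return("assignments must be 1 or 2")
  TRUE
})

#' NNDistanceSet: deduplicated nearest-neighbor emitter distances
#'
#' Distances are stored after division by `expansionFactor` ("effective
#' distances") whenever the factor differs from 1.
#'
#' @slot distances numeric vector of distances, nm.
#' @slot source character identifier of the originating object/pair per distance.
#' @slot expansionFactor divisor already applied to the distances.
#' @export
setClass("NNDistanceSet",
  representation(distances = "numeric", source = "character",
                 expansionFactor = "numeric"))

setValidity("NNDistanceSet", function(object) {
  if (length(object@distances) && any(object@distances <= 0)) {
    return("all distances must be > 0")
  }
  if (length(object@source) != length(object@distances)) {
    return("source must parallel distances")
  }
  if (object@expansionFactor < 1) return("expansionFactor must be >= 1")
  TRUE
})

#' PeakFit: Gaussian fitted to a histogram peak
#'
#' @slot mean fitted peak position, nm.
#' @slot sigma fitted standard deviation, nm.
#' @slot amplitude fitted peak height, counts.
#' @slot fitWindow lower/upper bounds (nm) of the bins used.
#' @slot binWidth histogram bin width, nm.
#' @slot converged whether the optimizer succeeded and the mean lies inside the
#'   window.
#' @slot diagnostics list with `nDistances`, `message` and similar fit notes.
#' @export
setClass("PeakFit",
  representation(mean = "numeric", sigma = "numeric", amplitude = "numeric",
                 fitWindow = "numeric", binWidth = "numeric",
                 converged = "logical", diagnostics = "list"))

setValidity("PeakFit", function(object) {
  if (length(object@fitWindow) != 2L) return("fitWindow must be length 2")
  if (object@converged) {
    if (object@sigma <= 0) return("sigma must be > 0 for a converged fit")
    if (object@mean <= object@fitWindow[1] || object@mean >= object@fitWindow[2]) {
      return("a converged mean must lie inside the fit window")
    }
  }
  TRUE
})

#' DistortionEstimate: per-emitter positional error from pre/post peak widths
#'
#' @slot sigmaPre first-peak sigma before denaturation, nm.
#' @slot sigmaPost first-peak sigma after denaturation, nm.
#' @slot sigmaEmitter per-emitter, per-axis distortion sigma, nm.
#' @slot fwhmEmitter `2 sqrt(2 log 2)` times `sigmaEmitter`, nm.
#' @slot valid FALSE when `sigmaPost < sigmaPre` (flagged zero, not clamped
#'   silently).
#' @export
setClass("DistortionEstimate",
  representation(sigmaPre = "numeric", sigmaPost = "numeric",
                 sigmaEmitter = "numeric", fwhmEmitter = "numeric",
                 valid = "logical"))

setValidity("DistortionEstimate", function(object) {
  if (object@valid && object@sigmaEmitter < 0) return("sigmaEmitter must be >= 0 when valid")
  if (abs(object@fwhmEmitter - 2 * sqrt(2 * log(2)) * object@sigmaEmitter) >
      1e-9 * max(1, object@fwhmEmitter)) {
    return("fwhmEmitter must equal 2*sqrt(2*log 2)*sigmaEmitter")
  }
  TRUE
})

#' RenderParams: STORM rendering convention
#'
#' @slot spotSigma sigma (nm) of the rendered 2D Gaussian per localization.
#' @slot pixelSize rendered pixel size, nm.
#' @slot cameraPixel camera pixel size in sample space, nm (metadata only).
#' @export
setClass("RenderParams",
  representation(spotSigma = "numeric", pixelSize = "numeric",
                 cameraPixel = "numeric"))

setValidity("RenderParams", function(object) {
  if (object@spotSigma <= 0) return("spotSigma must be > 0")
  if (object@pixelSize <= 0) return("pixelSize must be > 0")
  TRUE
})

#' StormImage: rendered intensity image with its geometry
#'
#' @slot pixels numeric matrix; rows index x pixels, columns y pixels.
#' @slot origin nm coordinates of the lower-left corner of pixel (1, 1).
#' @slot pixelSize pixel edge length, nm.
#' @export
setClass("StormImage",
  representation(pixels = "matrix", origin = "numeric", pixelSize = "numeric"))

setValidity("StormImage", function(object) {
  if (length(object@origin) != 2L) return("origin must be length 2")
  if (object@pixelSize <= 0) return("pixelSize must be > 0")
  TRUE
})
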