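#' @rdname accessors
setMethod("coords", "LocalizationTable", function(object) object@coords)

#' @rdname accessors
setMethod("frames", "LocalizationTable", function(object) object@frame)

#' @rdname accessors
setMethod("centroids", "EmitterClusterSet", function(object) object@centroids)

#' @rdname accessors
setMethod("centroids", "OrigamiObject", function(object) object@clusters@centroids)

#' @rdname accessors
setMethod("clusterSizes", "EmitterClusterSet", function(object) object@nLocalizations)

#' @rdname accessors
setMethod("clusterSizes", "OrigamiObject", function(object) object@clusters@nLocalizations)

#' @rdname accessors
setMethod("membership", "EmitterClusterSet", function(object) object@membership)

#' @rdname accessors
setMethod("distances", "NNDistanceSet", function(object) object@distances)

#' @rdname accessors
setMethod("expansionFactor", "NNDistanceSet", function(object) object@expansionFactor)

#' Number of localizations in a table
#' @param x a [LocalizationTable].
#' @export
setMethod("length", "LocalizationTable", function(x) nrow(x@coords))

#' Subset a localization table by row index
#' @param x a [LocalizationTable].
#' @param i integer or logical row index.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "LocalizationTable", function(x, i, j, ..., drop = FALSE) {
  new("LocalizationTable",
      coords = x@coords[i, , drop = FALSE],
      frame = x@frame[i],
      extra = x@extra[i, , drop = FALSE])
})

#' Convert a localization table to a data.frame
#' @param x a [LocalizationTable].
#' @param ... unused.
#' @export
setMethod("as.data.frame", "LocalizationTable", function(x, ...) {
  df <- data.frame(x_nm = x@coords[, 1], y_nm = x@coords[, 2], frame = x@frame)
  if (ncol(x@extra)) df <- cbind(df, x@extra)
  df
})

setMethod("show", "LocalizationTable", function(object) {
  cat("LocalizationTable with", nrow(object@coords), "localizations\n")
  if (nrow(object@coords)) {
    rx <- range(object@coords[, 1]); ry <- range(object@coords[, 2])
    cat(sprintf("  x: [%.1f, %.1f] nm  y: [%.1f, %.1f] nm  frames: %d..%d\n",
                rx[1], rx[2], ry[1], ry[2], min(object@frame), max(object@frame)))
  }
  if (ncol(object@extra)) {
    cat("  extra columns:", paste(names(object@extra), collapse = ", "), "\n")
  }
})

setMethod("show", "OrigamiDesign", function(object) {
  cat(sprintf("OrigamiDesign '%s' (%s): %d sites\n",
              object@name, object@kind, nrow(object@sitePositions)))
})

setMethod("show", "EmitterClusterSet", function(object) {
  cat("EmitterClusterSet with", nrow(object@centroids), "clusters")
  if (nrow(object@centroids)) {
    cat(sprintf(" (sizes %d..%d)", min(object@nLocalizations), max(object@nLocalizations)))
  }
  cat("\n")
})

setMethod("show", "OrigamiObject", function(object) {
  cat(sprintf("OrigamiObject (%s): %d clusters, straightness R^2 = %.4f\n",
              object@kind, nrow(object@clusters@centroids), object@straightness))
})

setMethod("show", "NNDistanceSet", function(object) {
  cat(sprintf("NNDistanceSet: %d distances", length(object@distances)))
  if (length(object@distances)) {
    cat(sprintf(", median %.1f nm", stats::median(object@distances)))
  }
  if (object@expansionFactor != 1) {
    cat(sprintf(" (effective, expansion factor %.2f applied)", object@expansionFactor))
  }
  cat("\n")
})

setMethod("show", "PeakFit", function(object) {
  if (object@converged) {
    cat(sprintf("PeakFit: mean %.2f nm, sigma %.2f nm (window %.1f-%.1f nm)\n",
                object@mean, object@sigma, object@fitWindow[1], object@fitWindow[2]))
  } else {
    cat("PeakFit: not converged —", object@diagnostics$message %||% "no details", "\n")
  }
})

setMethod("show", "DistortionEstimate", function(object) {
  cat(sprintf("DistortionEstimate: sigma %.1f nm (FWHM %.1f nm), pre %.2f / post %.2f nm%s\n",
              object@sigmaEmitter, object@fwhmEmitter, object@sigmaPre, object@sigmaPost,
              if (object@valid) "" else " [flagged: post < pre]"))
})

setMethod("show", "TwoRowFit", function(object) {
  cat(sprintf("TwoRowFit: row spacing %.2f nm, direction (%.3f, %.3f)\n",
              object@rowSpacing, object@commonDirection[1], object@commonDirection[2]))
})

setMethod("show", "StormImage", function(object) {
  cat(sprintf("StormImage: %d x %d pixels of %.1f nm, total intensity %.1f\n",
              nrow(object@pixels), ncol(object@pixels), object@pixelSize,
              sum(object@pixels)))
})

`%||%` <- function(a, b) if (is.null(a)) b else a
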