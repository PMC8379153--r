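#' Construct a nanoruler labeling-site design
#'
#' Builds the site layout of a DNA-origami nanoruler in its local frame.
#' Linear designs place `nSites` sites at `(i * spacing, 0)`; rectangular
#' designs place two rows of `nSites` at `(i * spacing, 0)` and
#' `(i * spacing, rowSpacing)`.
#'
#' @param kind `"linear"` or `"rectangular"`.
#' @param spacing within-row site spacing, nm (> 0).
#' @param nSites sites per row (>= 2).
#' @param rowSpacing distance between the two rows, nm; required for (and only
#'   for) rectangular designs.
#' @param name optional label; defaults to e.g. `"linear28"`.
#' @return an [OrigamiDesign].
#' @examples
#' makeDesign("linear", 28, 10)        # ten sites spanning 252 nm
#' makeDesign("rectangular", 11, 8, rowSpacing = 30)
#' @export
makeDesign <- function(kind = c("linear", "rectangular"), spacing, nSites,
                       rowSpacing = NULL, name = NULL) {
  kind <- match.arg(kind)
  if (!is.numeric(spacing) || spacing <= 0) stop("spacing must be positive")
  if (!is.numeric(nSites) || nSites < 2 || nSites != round(nSites)) {
    stop("nSites must be an integer >= 2")
  }
  if (kind == "rectangular") {
    if (is.null(rowSpacing) || rowSpacing <= 0) {
      stop("rowSpacing is required (and must be positive) for rectangular designs")
    }
  } else if (!is.null(rowSpacing)) {
    stop("rowSpacing only applies to rectangular designs")
  }
  xs <- (seq_len(nSites) - 1) * spacing
  pos <- if (kind == "linear") {
    cbind(x = xs, y = rep(0, nSites))
  } else {
    rbind(cbind(x = xs, y = rep(0, nSites)),
          cbind(x = xs, y = rep(rowSpacing, nSites)))
  }
  if (is.null(name)) name <- paste0(substr(kind, 1, 4), round(spacing))
  new("OrigamiDesign", name = name, sitePositions = pos, kind = kind)
}

#' Standard nanoruler designs used throughout the package
#'
#' * `"linear28"`: 10 collinear sites, 28-nm spacing (252-nm span).
#' * `"linear84"`: 4 collinear sites, 84-nm spacing (same 252-nm span; the
#'   sparse variant used for distortion estimation, where nearest-neighbor
#'   peaks stay well separated even under heavy distortion).
#' * `"rect11"`: two rows 30 nm apart, 8 sites per row at 11-nm spacing.
#'
#' @param name one of `"linear28"`, `"linear84"`, `"rect11"`.
#' @return an [OrigamiDesign].
#' @export
standardDesign <- function(name = c("linear28", "linear84", "rect11")) {
  name <- match.arg(name)
  switch(name,
    linear28 = makeDesign("linear", 28, 10, name = "linear28"),
    linear84 = makeDesign("linear", 84, 4, name = "linear84"),
    rect11   = makeDesign("rectangular", 11, 8, rowSpacing = 30, name = "rect11"))
}
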