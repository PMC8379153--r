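#' Rendering parameters
#'
#' The super-resolution rendering convention: each localization is drawn as
#' an isotropic 2D Gaussian of sigma `spotSigma` (8 nm by default, matching
#' the common molecule-list rendering radius). `cameraPixel` (153 nm in
#' sample space for the source instrument) is carried as metadata only.
#'
#' @param spotSigma rendered spot sigma, nm (default 8).
#' @param pixelSize rendered pixel size, nm (default 2).
#' @param cameraPixel camera pixel size in sample space, nm (default 153).
#' @return a validated [RenderParams].
#' @export
renderParams <- function(spotSigma = 8, pixelSize = 2, cameraPixel = 153) {
  new("RenderParams", spotSigma = spotSigma, pixelSize = pixelSize,
      cameraPixel = cameraPixel)
}

#' Render a STORM image from molecular coordinates
#'
#' Sums an isotropic 2D Gaussian of sigma `spotSigma`, truncated at 4 sigma
#' and normalized to unit mass in pixel units, at every localization
#' position on a pixel grid. Total intensity therefore equals the number of
#' localizations up to boundary truncation, i.e. intensity is proportional
#' to localization density.
#'
#' @param table a [LocalizationTable].
#' @param params a [RenderParams].
#' @param bounds `c(xmin, xmax, ymin, ymax)` nm, or `NULL` for the data
#'   extent padded by `4 * spotSigma`.
#' @return a [StormImage]. An empty table with explicit bounds renders an
#'   all-zero image.
#' @export
renderStorm <- function(table, params = renderParams(), bounds = NULL) {
  stopifnot(is(table, "LocalizationTable"))
  validObject(params)
  xy <- coords(table)
  bounds <- .resolve_bounds(xy, bounds, 4 * params@spotSigma)
  px <- params@pixelSize
  nx <- max(1L, as.integer(ceiling((bounds[2] - bounds[1]) / px)))
  ny <- max(1L, as.integer(ceiling((bounds[4] - bounds[3]) / px)))
  if (as.double(nx) * ny > 4e7) {
    stop("rendering grid would exceed 4e7 pixels; pass tighter bounds or a larger pixel")
  }
  img <- matrix(0, nx, ny)
  if (nrow(xy) == 0L) {
    return(new("StormImage", pixels = img, origin = c(bounds[1], bounds[3]),
               pixelSize = px))
  }
  half <- as.integer(ceiling(4 * params@spotSigma / px))
  s2 <- 2 * params@spotSigma^2
  # pixel-center coordinate helpers
  cxAt <- function(i) bounds[1] + (i - 0.5) * px
  cyAt <- function(j) bounds[3] + (j - 0.5) * px
  for (r in seq_len(nrow(xy))) {
    i0 <- as.integer(floor((xy[r, 1] - bounds[1]) / px)) + 1L
    j0 <- as.integer(floor((xy[r, 2] - bounds[3]) / px)) + 1L
    xi <- max(1L, i0 - half):min(nx, i0 + half)
    yj <- max(1L, j0 - half):min(ny, j0 + half)
    gx <- exp(-(cxAt(xi) - xy[r, 1])^2 / s2)
    gy <- exp(-(cyAt(yj) - xy[r, 2])^2 / s2)
    spot <- outer(gx, gy)
    img[xi, yj] <- img[xi, yj] + spot * (px^2 / (2 * pi * params@spotSigma^2))
  }
  new("StormImage", pixels = img, origin = c(bounds[1], bounds[3]),
      pixelSize = px)
}
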