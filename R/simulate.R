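#' Simulation configuration with documented defaults
#'
#' The defaults emulate the no-gel reference regime of the nanoruler
#' experiments: a sparse ~90 x 90 um field, ~15,000 frames, Cy5-like blinking
#' with on average 30 localizations per dye, and per-localization precision
#' tight enough (sigma 2.5 nm per coordinate) that DBSCAN at eps = 12 nm
#' resolves 28-nm site spacings while per-cluster centroids localize each dye
#' to well under a nanometer. Intrinsic per-site jitter (sigma 3 nm per
#' coordinate) models structural heterogeneity present in every condition;
#' `gelDistortion` models the additional random per-site displacement that
#' gel embedding plus denaturation can introduce (applied only when
#' [simulateField()] is run with `condition = "post"`).
#'
#' @param nObjects origami objects per field (default 100).
#' @param fieldSize field width/height in micrometers (default `c(90, 90)`).
#' @param labelingEfficiency per-site dye incorporation probability (default 0.85).
#' @param locsPerEmitterMean Poisson mean localizations per visible dye (default 30).
#' @param minLocsPerEmitter floor on localizations per visible dye (default 5,
#'   so every simulated emitter is detectable at `minPts = 5`).
#' @param localizationPrecision per-coordinate sigma of a localization about
#'   its dye, nm (default 2.5).
#' @param intrinsicJitter per-coordinate sigma of per-site structural
#'   displacement, nm (default 3).
#' @param gelDistortion per-coordinate sigma of post-denaturation per-site
#'   displacement, nm (default 0).
#' @param expansionFactor isotropic scale about the field origin (default 1;
#'   expanded gels in the source experiments reached 2.2-2.5).
#' @param backgroundDensity spurious localizations per square micrometer of
#'   the (scaled) field (default 0.05).
#' @param nFrames camera frames (default 15000).
#' @param seed integer seed (default 1).
#' @return a validated [SimulationConfig].
#' @export
simulationConfig <- function(nObjects = 100, fieldSize = c(90, 90),
                             labelingEfficiency = 0.85,
                             locsPerEmitterMean = 30, minLocsPerEmitter = 5,
                             localizationPrecision = 2.5, intrinsicJitter = 3,
                             gelDistortion = 0, expansionFactor = 1,
                             backgroundDensity = 0.05, nFrames = 15000,
                             seed = 1) {
  if (length(fieldSize) == 1L) fieldSize <- rep(fieldSize, 2)
  new("SimulationConfig",
      nObjects = nObjects, fieldSize = as.numeric(fieldSize),
      labelingEfficiency = labelingEfficiency,
      locsPerEmitterMean = locsPerEmitterMean,
      minLocsPerEmitter = minLocsPerEmitter,
      localizationPrecision = localizationPrecision,
      intrinsicJitter = intrinsicJitter, gelDistortion = gelDistortion,
      expansionFactor = expansionFactor, backgroundDensity = backgroundDensity,
      nFrames = nFrames, seed = seed)
}

#' Build a localization table from vectors
#'
#' @param x,y coordinates in nm.
#' @param frame frame indices (recycled if length 1; defaults to 1).
#' @param extra optional data.frame of extra columns carried along untouched.
#' @return a [LocalizationTable].
#' @export
localizationTable <- function(x, y, frame = 1L, extra = NULL) {
  n <- length(x)
  if (length(frame) == 1L) frame <- rep(frame, n)
  if (is.null(extra)) extra <- data.frame(row.names = seq_len(n))
  new("LocalizationTable",
      coords = cbind(x_nm = as.numeric(x), y_nm = as.numeric(y)),
      frame = as.integer(frame), extra = extra)
}

# rotation matrix for angle theta (rad)
.rot <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
}

# run expr with a private RNG stream seeded by `seed`, restoring global state
.with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Simulate a STORM field of nanoruler objects
#'
#' Places `nObjects` copies of `design` uniformly at random position and
#' orientation in the field (with rejection so that no two objects' padded
#' bounding circles overlap), marks each labeling site visible with
#' probability `labelingEfficiency`, displaces every site by intrinsic
#' Gaussian jitter and — in the `"post"` condition only — by an additional
#' iid Gaussian gel displacement, scales all positions isotropically by
#' `expansionFactor` about the field origin, and emits
#' `max(minLocsPerEmitter, Poisson(locsPerEmitterMean))` localizations per
#' visible site with iid Gaussian noise of sigma `localizationPrecision` per
#' coordinate. Background localizations are added as a uniform spatial
#' Poisson process. Frames are drawn uniformly from `1..nFrames`.
#'
#' The gel displacement stream is drawn in both conditions (and merely not
#' applied in `"pre"`), so a pre/post pair simulated with the same seed shares
#' placements, visibility, jitter and blinking, and differs exactly by the
#' per-site gel displacement.
#'
#' @param design an [OrigamiDesign].
#' @param config a [SimulationConfig].
#' @param condition `"pre"` (before denaturation; no gel displacement) or
#'   `"post"` (gel displacement applied).
#' @return a list with `localizations` (a [LocalizationTable]) and `truth`
#'   (a data.frame with one row per designed site:
#'   `object_id, site_index, x_true_nm, y_true_nm, visible, dx_gel_nm,
#'   dy_gel_nm`; true positions are in the final, scaled coordinates).
#' @export
simulateField <- function(design, config = simulationConfig(),
                          condition = c("pre", "post")) {
  condition <- match.arg(condition)
  stopifnot(is(design, "OrigamiDesign"), is(config, "SimulationConfig"))
  validObject(design); validObject(config)

  .with_seed(config@seed, {
    nObj <- as.integer(config@nObjects)
    sites0 <- design@sitePositions
    nSites <- nrow(sites0)
    ctr0 <- colMeans(sites0)
    boundR <- sqrt(max(rowSums(sweep(sites0, 2, ctr0)^2)))
    fieldNm <- config@fieldSize * 1000
    pad <- 300  # nm of clearance beyond the bounding circles

    # -- placements (rejection sampling, deterministic given the seed) --
    centers <- matrix(NA_real_, nObj, 2)
    thetas <- numeric(nObj)
    for (i in seq_len(nObj)) {
      ok <- FALSE
      for (attempt in 1:10000) {
        cand <- c(stats::runif(1, boundR, fieldNm[1] - boundR),
                  stats::runif(1, boundR, fieldNm[2] - boundR))
        th <- stats::runif(1, 0, 2 * pi)
        if (i == 1L) { ok <- TRUE } else {
          prev <- centers[seq_len(i - 1L), , drop = FALSE]
          dmin <- sqrt(min(rowSums(sweep(prev, 2, cand)^2)))
          ok <- dmin > 2 * boundR + pad
        }
        if (ok) { centers[i, ] <- cand; thetas[i] <- th; break }
      }
      if (!ok) stop("could not place all objects without overlap; field too crowded")
    }

    # -- per-site truth --
    truth <- vector("list", nObj)
    locsList <- vector("list", nObj)
    for (i in seq_len(nObj)) {
      placed <- sites0 %*% t(.rot(thetas[i]))
      placed <- sweep(placed, 2, centers[i, ], `+`)
      visible <- stats::runif(nSites) < config@labelingEfficiency
      jit <- matrix(stats::rnorm(2 * nSites, 0, config@intrinsicJitter), nSites, 2)
      gel <- matrix(stats::rnorm(2 * nSites, 0, config@gelDistortion), nSites, 2)
      applied <- if (condition == "post") gel else matrix(0, nSites, 2)
      pos <- (placed + jit + applied) * config@expansionFactor

      truth[[i]] <- data.frame(
        object_id = i, site_index = seq_len(nSites),
        x_true_nm = pos[, 1], y_true_nm = pos[, 2],
        visible = visible,
        dx_gel_nm = applied[, 1], dy_gel_nm = applied[, 2])

      if (any(visible)) {
        vpos <- pos[visible, , drop = FALSE]
        counts <- pmax(config@minLocsPerEmitter,
                       stats::rpois(nrow(vpos), config@locsPerEmitterMean))
        rep_idx <- rep(seq_len(nrow(vpos)), counts)
        ntot <- sum(counts)
        locsList[[i]] <- cbind(
          vpos[rep_idx, 1] + stats::rnorm(ntot, 0, config@localizationPrecision),
          vpos[rep_idx, 2] + stats::rnorm(ntot, 0, config@localizationPrecision))
      } else {
        locsList[[i]] <- matrix(numeric(0), 0, 2)
      }
    }

    # -- background --
    scaledField <- fieldNm * config@expansionFactor
    areaUm2 <- prod(scaledField / 1000)
    nBg <- stats::rpois(1, config@backgroundDensity * areaUm2)
    bg <- cbind(stats::runif(nBg, 0, scaledField[1]),
                stats::runif(nBg, 0, scaledField[2]))

    allLocs <- do.call(rbind, c(locsList, list(bg)))
    n <- nrow(allLocs)
    frame <- if (n) sample.int(as.integer(config@nFrames), n, replace = TRUE) else integer(0)

    truthDf <- do.call(rbind, truth)
    if (is.null(truthDf)) {
      truthDf <- data.frame(object_id = integer(0), site_index = integer(0),
                            x_true_nm = numeric(0), y_true_nm = numeric(0),
                            visible = logical(0), dx_gel_nm = numeric(0),
                            dy_gel_nm = numeric(0))
    }
    attr(truthDf, "placements") <- data.frame(
      object_id = seq_len(nObj),
      cx_nm = centers[, 1], cy_nm = centers[, 2], theta_rad = thetas)
    list(localizations = localizationTable(allLocs[, 1], allLocs[, 2], frame),
         truth = truthDf)
  })
}
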