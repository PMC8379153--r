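#' Linear-origami analysis: localizations to first-peak fit
#'
#' Runs the linear-nanoruler branch on one field: DBSCAN clustering,
#' single-linkage grouping into candidate objects, straightness selection,
#' deduplicated nearest-neighbor distances, optional expansion rescaling,
#' and the first-peak Gaussian fit.
#'
#' @param locs a [LocalizationTable].
#' @param expectedSpacing design spacing, nm (pre-expansion units).
#' @param params a [ClusteringParams].
#' @param groupingRadius single-linkage radius, nm, applied in the data
#'   coordinates; `NULL` (default) uses `max(100, 2 * expectedSpacing) *
#'   expansionFactor`, which stays above the design gap plus realistic
#'   distortion tails while remaining far below inter-object distances.
#' @param minClusters,r2Min selection rule (defaults 5 and 0.9).
#' @param expansionFactor divisor applied to the measured distances
#'   (default 1).
#' @param binWidth histogram bin width for the peak fit, nm.
#' @param designSites designed site count (for the merged-cluster
#'   diagnostic); `NA` skips the diagnostic.
#' @return list with `clusters`, `objects`, `selectionRate`, `nnd` (effective
#'   distances), `fit` (a [PeakFit]) and `diagnostic`.
#' @export
analyzeLinearField <- function(locs, expectedSpacing,
                               params = clusteringParams(),
                               groupingRadius = NULL, minClusters = 5,
                               r2Min = 0.9, expansionFactor = 1,
                               binWidth = 2, designSites = NA) {
  if (is.null(groupingRadius)) {
    groupingRadius <- max(100, 2 * expectedSpacing) * expansionFactor
  }
  clusters <- clusterDbscan(locs, params)
  candidates <- groupClusters(clusters, groupingRadius)
  objects <- selectLinearObjects(candidates, minClusters = minClusters,
                                 r2Min = r2Min)
  nnd <- nnDistances(objects)
  if (expansionFactor != 1) nnd <- applyExpansion(nnd, expansionFactor)
  fit <- fitFirstPeak(nnd, expectedSpacing, binWidth = binWidth)
  diag <- if (is.na(designSites)) NULL else {
    mergedClusterDiagnostic(objects, expectedSpacing * expansionFactor,
                            designSites)
  }
  list(clusters = clusters, objects = objects,
       selectionRate = attr(objects, "selectionRate"),
       nnd = nnd, fit = fit, diagnostic = diag)
}

#' Rectangular-origami analysis: ROIs, rows, and the within-row peak
#'
#' Runs the rectangular-nanoruler branch: density-based ROI selection,
#' two-parallel-row fitting per ROI, local-maxima-seeded K-means per row,
#' row selection (>= 3 collinear clusters), within-row nearest-neighbor
#' distances, optional expansion rescaling, and the first-peak fit at the
#' within-row spacing.
#'
#' @param locs a [LocalizationTable].
#' @param expectedSpacing within-row design spacing, nm (pre-expansion).
#' @param rowSpacing design row separation, nm (pre-expansion); only reported
#'   back, not used for fitting.
#' @param params a [ClusteringParams].
#' @param roiParams a [RoiSelectionParams].
#' @param minClusters,r2Min row selection rule (defaults 3 and 0.9).
#' @param expansionFactor divisor applied to measured distances (default 1).
#' @param binWidth peak-fit bin width, nm (default 1).
#' @param minRoiLocalizations skip ROIs with fewer localizations
#'   (default 2 * minPts).
#' @return list with `rois`, `rowFits` (list of [TwoRowFit]), `rowSpacings`
#'   (effective nm, one per fitted ROI), `rows` (accepted row
#'   [OrigamiObject]s), `nnd`, and `fit`.
#' @export
analyzeRectField <- function(locs, expectedSpacing = 11, rowSpacing = 30,
                             params = clusteringParams(),
                             roiParams = roiSelectionParams(),
                             minClusters = 3, r2Min = 0.9,
                             expansionFactor = 1, binWidth = 1,
                             minRoiLocalizations = NULL) {
  if (is.null(minRoiLocalizations)) minRoiLocalizations <- 2 * params@minPts
  rois <- selectRois(locs, roiParams)
  rowFits <- list()
  rowSets <- list()
  # ROI windows are micrometers wide while an origami spans ~100 nm, so a
  # stray background localization inside the window would wreck the
  # principal-axis fit; isolate the dominant dense blob first with a coarse
  # DBSCAN whose radius bridges the two rows but not the background.
  blobParams <- clusteringParams(eps = 1.5 * rowSpacing * expansionFactor,
                                 minPts = params@minPts)
  for (roi in rois) {
    if (length(roi) < minRoiLocalizations) next
    blobs <- clusterDbscan(roi, blobParams)
    if (!nrow(centroids(blobs))) next
    roi <- roi[membership(blobs)[[which.max(clusterSizes(blobs))]]]
    if (length(roi) < minRoiLocalizations) next
    fit2 <- tryCatch(fitTwoRows(roi, minPts = params@minPts),
                     error = function(e) NULL)
    if (is.null(fit2)) next
    rowFits[[length(rowFits) + 1L]] <- fit2
    for (rowId in 1:2) {
      sub <- roi[which(fit2@assignments == rowId)]
      if (length(sub) < params@minPts) next
      cl <- maximaSeededKmeans(sub, params)
      if (nrow(centroids(cl))) rowSets[[length(rowSets) + 1L]] <- cl
    }
  }
  rows <- selectRows(rowSets, minClusters = minClusters, r2Min = r2Min)
  nnd <- nnDistances(rows)
  if (expansionFactor != 1) nnd <- applyExpansion(nnd, expansionFactor)
  fit <- fitFirstPeak(nnd, expectedSpacing, binWidth = binWidth)
  list(rois = rois, rowFits = rowFits,
       rowSpacings = vapply(rowFits, function(f) f@rowSpacing, numeric(1)) /
         expansionFactor,
       rows = rows, nnd = nnd, fit = fit)
}

.known_config_keys <- c(
  "design", "condition", "simulate", "inputPathPre", "inputPathPost",
  "outDir", "expansionFactor", "seed", "binWidth", "groupingRadius",
  "minClusters", "r2Min", "simulation", "clustering", "roi")

#' Pipeline configuration
#'
#' Assembles (and validates) the configuration consumed by [runPipeline()].
#' Every field has a default; unknown keys are rejected.
#'
#' @param design `"linear28"`, `"linear84"` or `"rect11"`.
#' @param condition `"pre"`, `"post"`, or `"both"` (simulate both conditions
#'   and estimate the gel distortion from their peak fits).
#' @param simulate when TRUE (default) the field is simulated; otherwise
#'   `inputPathPre` (and `inputPathPost` for `condition = "both"`) must name
#'   molecule-list CSVs.
#' @param inputPathPre,inputPathPost input CSVs when `simulate = FALSE`.
#' @param outDir output directory, or `NULL` to write nothing.
#' @param expansionFactor divisor applied to measured distances (default 1).
#' @param seed simulation seed.
#' @param binWidth peak-fit bin width, nm; default 2 (1 for `rect11`).
#' @param groupingRadius cluster-to-object linkage radius, nm, or `NULL`
#'   for the spacing-scaled default of [analyzeLinearField()].
#' @param minClusters selection threshold; default 5 for `linear28`, 3 for
#'   `linear84` (a 4-site design cannot hold 5 clusters) and for rows.
#' @param r2Min straightness threshold (default 0.9).
#' @param simulation named list of [simulationConfig()] overrides.
#' @param clustering named list of [clusteringParams()] overrides.
#' @param roi named list of [roiSelectionParams()] overrides.
#' @return a validated configuration list of class `"nanorulerConfig"`.
#' @export
pipelineConfig <- function(design = "linear28", condition = "pre",
                           simulate = TRUE, inputPathPre = NULL,
                           inputPathPost = NULL, outDir = NULL,
                           expansionFactor = 1, seed = 1, binWidth = NULL,
                           groupingRadius = NULL, minClusters = NULL,
                           r2Min = 0.9, simulation = list(),
                           clustering = list(), roi = list()) {
  design <- match.arg(design, c("linear28", "linear84", "rect11"))
  condition <- match.arg(condition, c("pre", "post", "both"))
  if (is.null(binWidth)) binWidth <- if (design == "rect11") 1 else 2
  if (is.null(minClusters)) minClusters <- if (design == "linear28") 5 else 3
  cfg <- list(design = design, condition = condition, simulate = simulate,
              inputPathPre = inputPathPre, inputPathPost = inputPathPost,
              outDir = outDir, expansionFactor = expansionFactor, seed = seed,
              binWidth = binWidth, groupingRadius = groupingRadius,
              minClusters = minClusters, r2Min = r2Min,
              simulation = simulation, clustering = clustering, roi = roi)
  class(cfg) <- "nanorulerConfig"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' Fields mirror [pipelineConfig()]; unknown keys are an error.
#'
#' @param path YAML file.
#' @return configuration list, as from [pipelineConfig()].
#' @export
readPipelineConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  unknown <- setdiff(names(raw), .known_config_keys)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  do.call(pipelineConfig, raw)
}

.design_spacing <- function(design) {
  p <- design@sitePositions
  if (design@kind == "linear") {
    sort(unique(round(diff(p[, 1]), 9)))[1]
  } else {
    xs <- sort(unique(p[, 1]))
    xs[2] - xs[1]
  }
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

.run_one_condition <- function(cfg, condition, design, simCfg, clustParams,
                               roiParams, outDir, log) {
  locs <- if (cfg$simulate) {
    sim <- .stage("simulate", simulateField(design, simCfg, condition))
    if (!is.null(outDir)) {
      writeLocalizations(sim$localizations,
                         file.path(outDir, sprintf("localizations_%s.csv", condition)))
      writeGroundTruth(sim$truth,
                       file.path(outDir, sprintf("ground_truth_%s.csv", condition)))
    }
    sim$localizations
  } else {
    path <- if (condition == "post") cfg$inputPathPost else cfg$inputPathPre
    if (is.null(path)) stop("no input path configured for condition ", condition)
    .stage("read", readLocalizations(path))
  }
  log(sprintf("condition %s: %d localizations", condition, length(locs)))

  spacing <- .design_spacing(design)
  if (design@kind == "linear") {
    res <- .stage("analyze-linear", analyzeLinearField(
      locs, spacing, params = clustParams,
      groupingRadius = if (is.null(cfg$groupingRadius)) NULL else
        cfg$groupingRadius * cfg$expansionFactor,
      minClusters = cfg$minClusters, r2Min = cfg$r2Min,
      expansionFactor = cfg$expansionFactor, binWidth = cfg$binWidth,
      designSites = nrow(design@sitePositions)))
    if (!is.null(outDir)) {
      cent <- centroids(res$clusters)
      utils::write.csv(
        data.frame(cluster_id = seq_len(nrow(cent)),
                   x_nm = cent[, 1], y_nm = cent[, 2],
                   n_locs = clusterSizes(res$clusters)),
        file.path(outDir, sprintf("clusters_%s.csv", condition)),
        row.names = FALSE, quote = FALSE)
      utils::write.csv(
        data.frame(object_id = seq_along(res$objects),
                   n_clusters = vapply(res$objects,
                                       function(o) nrow(centroids(o)), numeric(1)),
                   r2 = vapply(res$objects,
                               function(o) o@straightness, numeric(1))),
        file.path(outDir, sprintf("objects_%s.csv", condition)),
        row.names = FALSE, quote = FALSE)
      utils::write.csv(data.frame(distance_nm = distances(res$nnd)),
                       file.path(outDir, sprintf("distances_%s.csv", condition)),
                       row.names = FALSE, quote = FALSE)
    }
  } else {
    res <- .stage("analyze-rect", analyzeRectField(
      locs, spacing, params = clustParams, roiParams = roiParams,
      minClusters = cfg$minClusters, r2Min = cfg$r2Min,
      expansionFactor = cfg$expansionFactor, binWidth = cfg$binWidth))
    if (!is.null(outDir)) {
      utils::write.csv(
        data.frame(roi_id = seq_along(res$rowSpacings),
                   row_spacing_nm = res$rowSpacings),
        file.path(outDir, sprintf("rows_%s.csv", condition)),
        row.names = FALSE, quote = FALSE)
      utils::write.csv(data.frame(distance_nm = distances(res$nnd)),
                       file.path(outDir, sprintf("distances_%s.csv", condition)),
                       row.names = FALSE, quote = FALSE)
    }
  }
  res
}

.fit_summary <- function(fit) {
  list(converged = fit@converged,
       mean_nm = if (fit@converged) fit@mean else NA,
       sigma_nm = if (fit@converged) fit@sigma else NA,
       n_distances = fit@diagnostics$nDistances)
}

#' Run the full nanoruler pipeline
#'
#' Composes simulation (or input reading), clustering, object/row selection,
#' nearest-neighbor statistics, peak fitting and — for `condition = "both"`
#' — the pre/post distortion estimate, writing intermediate CSVs, a JSON
#' summary and a run log when `outDir` is set. Re-running the same
#' configuration reproduces identical outputs.
#'
#' @param cfg configuration from [pipelineConfig()] or [readPipelineConfig()].
#' @return the summary list, invisibly: per-condition fit results plus, for
#'   `condition = "both"`, the distortion block.
#' @export
runPipeline <- function(cfg = pipelineConfig()) {
  stopifnot(inherits(cfg, "nanorulerConfig"))
  outDir <- cfg$outDir
  if (!is.null(outDir) && !dir.exists(outDir)) {
    dir.create(outDir, recursive = TRUE)
  }
  logLines <- character(0)
  log <- function(msg) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), msg)
    message(line)
    logLines <<- c(logLines, line)
  }
  design <- standardDesign(cfg$design)
  simCfg <- do.call(simulationConfig, c(cfg$simulation, list(seed = cfg$seed)))
  if (!("expansionFactor" %in% names(cfg$simulation)) &&
      cfg$expansionFactor != 1 && cfg$simulate) {
    simCfg@expansionFactor <- cfg$expansionFactor
  }
  clustParams <- do.call(clusteringParams, cfg$clustering)
  roiParams <- do.call(roiSelectionParams, cfg$roi)
  log(sprintf("design %s (%s), condition %s, seed %d, expansion factor %.2f",
              cfg$design, design@kind, cfg$condition, cfg$seed,
              cfg$expansionFactor))

  conditions <- if (cfg$condition == "both") c("pre", "post") else cfg$condition
  results <- list()
  for (cond in conditions) {
    results[[cond]] <- .run_one_condition(cfg, cond, design, simCfg,
                                          clustParams, roiParams, outDir, log)
  }

  summary <- list(
    package_version = as.character(utils::packageVersion("nanoruler")),
    design = cfg$design, condition = cfg$condition, seed = cfg$seed,
    expansion_factor = cfg$expansionFactor,
    parameters = list(eps = clustParams@eps, min_pts = clustParams@minPts,
                      min_clusters = cfg$minClusters, r2_min = cfg$r2Min,
                      bin_width = cfg$binWidth,
                      grouping_radius = cfg$groupingRadius %||% "auto"))
  for (cond in conditions) {
    summary[[cond]] <- .fit_summary(results[[cond]]$fit)
    if (!is.null(results[[cond]]$rowSpacings) &&
        length(results[[cond]]$rowSpacings)) {
      summary[[cond]]$mean_row_spacing_nm <- mean(results[[cond]]$rowSpacings)
    }
    if (!is.null(results[[cond]]$diagnostic)) {
      summary[[cond]]$merged_fraction <-
        results[[cond]]$diagnostic$fractionUnderCount
    }
  }
  if (cfg$condition == "both") {
    if (results$pre$fit@converged && results$post$fit@converged) {
      est <- estimateDistortion(results$pre$fit, results$post$fit)
      summary$distortion <- list(
        sigma_pre_nm = est@sigmaPre, sigma_post_nm = est@sigmaPost,
        sigma_emitter_nm = est@sigmaEmitter, fwhm_emitter_nm = est@fwhmEmitter,
        valid = est@valid)
    } else {
      summary$distortion <- list(valid = FALSE,
                                 message = "one or both peak fits failed")
    }
  }
  if (!is.null(outDir)) {
    jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE)
    writeLines(logLines, file.path(outDir, "run.log"))
  }
  invisible(summary)
}
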