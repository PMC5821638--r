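#' @include AllClasses.R AllGenerics.R modelTree.R errorBudget.R
NULL

#' Keep-mask from residual screening against a reference fit
#'
#' Plots whose residuals (observed minus predicted, from a single fit on
#' the un-noised mean response) exceed \code{k} residual standard
#' deviations are flagged for exclusion — the guard against plots that
#' changed (fire, clearing) between the field and remote-sensing
#' acquisitions.
#'
#' @param observed,predicted AGB vectors of equal length (t/ha).
#' @param k SD multiplier; default 2.
#' @return Logical keep-mask: \code{TRUE} where \code{|r| <= k * SD(r)}.
#'   With zero residual SD everything is kept.
#' @export
#' @examples
#' residualOutlierMask(c(1, 2, 30), c(1.1, 2, 3))
residualOutlierMask <- function(observed, predicted, k = 2) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 3,
            k > 0)
  r <- observed - predicted
  s <- sd(r)
  if (!is.finite(s) || s == 0) return(rep(TRUE, length(r)))
  abs(r) <= k * s
}

## Flatten a named list of rasters into an npix x p matrix (column-major
## pixel order).
layersToMatrix <- function(layers, names = NULL) {
  if (is.matrix(layers)) return(layers)
  if (!is.null(names)) layers <- layers[names]
  out <- vapply(layers, as.vector, numeric(length(layers[[1]])))
  colnames(out) <- names(layers)
  out
}

#' Fit-and-predict over a Monte-Carlo realization set
#'
#' For each realization \code{r} a model tree is fitted on the training
#' predictors against row \code{r} of the realization set and applied to
#' the full target grid; the \code{n} predicted maps are stacked. Negative
#' predictions are clamped to zero. Training rows with missing predictors
#' are dropped (with a message); target pixels with missing predictors are
#' \code{NA}.
#'
#' @param realizations a \code{\linkS4class{RealizationSet}} (or an
#'   \code{n x m} matrix of response realizations).
#' @param trainPredictors \code{m x p} matrix of predictors at the training
#'   units, aligned with the realization columns.
#' @param targetPredictors named list of predictor rasters (matrices), or
#'   an \code{npix x p} matrix; names must match \code{trainPredictors}.
#' @param dims target raster dimensions \code{c(rows, cols)}; taken from
#'   the raster list when omitted.
#' @param scenario provenance label.
#' @param ... model-tree options passed to \code{\link{modelTree}}
#'   (\code{minLeafSize}, \code{maxDepth}, \code{smoothing},
#'   \code{nCommittees}, \code{extrapolationCap}).
#' @return A \code{\linkS4class{PredictionStack}}.
#' @export
mcFitPredict <- function(realizations, trainPredictors, targetPredictors,
                         dims = NULL, scenario = "unlabelled", ...) {
  values <- if (is(realizations, "RealizationSet"))
    realizations@values else as.matrix(realizations)
  n <- nrow(values)
  if (n < 2) stop("need at least 2 realizations")
  trainPredictors <- as.matrix(trainPredictors)
  if (ncol(values) != nrow(trainPredictors))
    stop("realization columns must align with training predictor rows")
  if (!is.matrix(targetPredictors)) {
    if (is.null(dims)) dims <- dim(targetPredictors[[1]])
    targetPredictors <- layersToMatrix(targetPredictors,
                                       colnames(trainPredictors))
  } else if (is.null(dims)) {
    dims <- c(nrow(targetPredictors), 1L)
  }
  keep <- rowSums(!is.finite(trainPredictors)) == 0
  if (!all(keep)) {
    message(sum(!keep), " training row(s) dropped for missing predictors")
    trainPredictors <- trainPredictors[keep, , drop = FALSE]
    values <- values[, keep, drop = FALSE]
  }
  targetOK <- rowSums(!is.finite(targetPredictors)) == 0
  stack <- array(NA_real_, c(dims[1], dims[2], n))
  tgt <- targetPredictors[targetOK, , drop = FALSE]
  for (r in seq_len(n)) {
    fit <- modelTree(trainPredictors, values[r, ], ...)
    map <- rep(NA_real_, prod(dims))
    map[targetOK] <- pmax(0, predict(fit, tgt))
    stack[, , r] <- map
  }
  new("PredictionStack", values = stack,
      provenance = list(scenario = scenario, learner = list(...),
                        nTrain = nrow(trainPredictors)))
}

## (q97.5 - q2.5)/2 over matrix rows, linear-interpolation quantiles;
## rows containing NA give NA.
rowCI95 <- function(m) {
  ok <- rowSums(is.na(m)) == 0
  out <- rep(NA_real_, nrow(m))
  if (any(ok)) {
    q <- apply(m[ok, , drop = FALSE], 1, quantile,
               probs = c(0.025, 0.975), names = FALSE, type = 7)
    out[ok] <- (q[2, ] - q[1, ]) / 2
  }
  out
}

#' @rdname ci95
#' @export
setMethod("ci95", "PredictionStack", function(stack, ...) {
  d <- dim(stack@values)
  if (d[3] < 2) stop("need at least 2 realizations")
  matrix(rowCI95(matrix(stack@values, d[1] * d[2], d[3])), d[1], d[2])
})

#' @rdname ci95
#' @export
setMethod("ci95", "matrix", function(stack, ...) {
  if (nrow(stack) < 2) stop("need at least 2 realizations")
  rowCI95(t(stack))
})

#' @rdname ci95
#' @export
setMethod("ci95", "RealizationSet", function(stack, ...) {
  ci95(stack@values)
})

surfaceFromPixels <- function(mu, half, meanGuard, d) {
  rel <- 100 * half / mu
  rel[!is.finite(rel) | mu < meanGuard] <- NA_real_
  new("UncertaintySurface",
      meanAGB = matrix(mu, d[1], d[2]),
      ci95Halfwidth = matrix(half, d[1], d[2]),
      relUncertainty = matrix(rel, d[1], d[2]))
}

#' @rdname relativeUncertainty
#' @export
setMethod("relativeUncertainty", "PredictionStack",
          function(stack, meanGuard = 1, ...) {
  d <- dim(stack@values)
  if (d[3] < 2) stop("need at least 2 realizations")
  m <- matrix(stack@values, d[1] * d[2], d[3])
  surfaceFromPixels(rowMeans(m), rowCI95(m), meanGuard, d[1:2])
})

#' @rdname relativeUncertainty
#' @export
setMethod("relativeUncertainty", "matrix",
          function(stack, meanGuard = 1, ...) {
  if (nrow(stack) < 2) stop("need at least 2 realizations")
  m <- t(stack)
  surfaceFromPixels(rowMeans(m), rowCI95(m), meanGuard,
                    c(nrow(m), 1L))
})

#' Screen reference pixels by relative uncertainty
#'
#' Keep-mask of pixels whose relative uncertainty is strictly below the
#' threshold (default 50\%); undefined (\code{NA}) pixels are excluded.
#' Used between the upscaling stages to stop high LiDAR-AGB uncertainties
#' from propagating into the wall-to-wall map.
#'
#' @param surface an \code{\linkS4class{UncertaintySurface}} (or a numeric
#'   matrix/vector of relative uncertainties in \%).
#' @param threshold percent; default 50.
#' @return Logical mask of the surface's shape.
#' @export
uncertaintyScreen <- function(surface, threshold = 50) {
  stopifnot(threshold > 0)
  rel <- if (is(surface, "UncertaintySurface"))
    surface@relUncertainty else surface
  !is.na(rel) & rel < threshold
}

#' Forest mask from a tree-cover layer
#'
#' Forest is tree cover strictly greater than the threshold (default 10\%,
#' the FAO forest definition used for masking biomass maps).
#'
#' @param treeCover tree-cover raster in percent, values in \code{[0, 100]}.
#' @param threshold percent; default 10.
#' @return Logical mask.
#' @export
forestMask <- function(treeCover, threshold = 10) {
  if (any(treeCover < 0, na.rm = TRUE) || any(treeCover > 100, na.rm = TRUE))
    stop("'treeCover' must lie in [0, 100]")
  !is.na(treeCover) & treeCover > threshold
}

#' Total aboveground carbon of an AGB map
#'
#' Sums AGB over non-\code{NA} pixels, converts area and applies the
#' biomass-to-carbon factor (default 0.48).
#'
#' @param agb AGB raster (t/ha).
#' @param pixelArea pixel area (ha); default 1.
#' @param factor carbon fraction of dry biomass, in \code{(0, 1]}; default
#'   0.48.
#' @return Total carbon (t C).
#' @export
#' @examples
#' totalCarbon(matrix(100, 1, 1))  # 48
totalCarbon <- function(agb, pixelArea = 1, factor = 0.48) {
  stopifnot(factor > 0, factor <= 1, pixelArea > 0)
  s <- sum(agb, na.rm = TRUE)
  s * pixelArea * factor
}

## Pixels covered by the circular 1 ha plot footprint (56.42 m radius).
footprintPixels <- function(x, y, pixelSize, nr, nc, radius = 56.42) {
  rows <- yToRow(max(y - radius, pixelSize / 2), pixelSize):
          yToRow(min(y + radius, nr * pixelSize - pixelSize / 2), pixelSize)
  cols <- xToCol(max(x - radius, pixelSize / 2), pixelSize):
          xToCol(min(x + radius, nc * pixelSize - pixelSize / 2), pixelSize)
  expand.grid(row = rows, col = cols)
}

plotsOnStrips <- function(plots, mask, pixelSize) {
  vapply(seq_len(nrow(plots)), function(i) {
    fp <- footprintPixels(plots$x[i], plots$y[i], pixelSize,
                          nrow(mask), ncol(mask))
    all(mask[cbind(fp$row, fp$col)])
  }, logical(1))
}

#' Run an upscaling scenario on a synthetic scene
#'
#' Three scenarios reproduce the study design:
#' \describe{
#'   \item{\code{nfi_direct}}{plot AGB (calibration fraction of a
#'     stratified split) is noised with the field-error budget and each
#'     realization is upscaled to the satellite layers in one stage.}
#'   \item{\code{lidar_two_stage}}{plots fully inside the LiDAR strips are
#'     screened for residual outliers (2 residual SDs against a reference
#'     fit), noised, upscaled to the LiDAR metrics along the strips
#'     (stage 1), and each stage-1 realization map then calibrates the
#'     satellite layers using all strip pixels as training (stage 2):
#'     realization \code{r} of stage 2 consumes realization \code{r} of
#'     stage 1, so stage-1 model error propagates.}
#'   \item{\code{lidar_two_stage_screened}}{as above, but only strip pixels
#'     whose stage-1 relative uncertainty is below \code{screenThreshold}
#'     train stage 2.}
#' }
#' Plots on slopes steeper than \code{slopeMax} never enter any training
#' set, and the final surfaces are masked to forest (tree cover >
#' \code{forestThreshold}).
#'
#' @param scene a \code{\linkS4class{SyntheticScene}}.
#' @param scenario one of \code{"nfi_direct"}, \code{"lidar_two_stage"},
#'   \code{"lidar_two_stage_screened"}.
#' @param n Monte-Carlo realizations; default 100.
#' @param epsField relative field error in percent or an
#'   \code{\linkS4class{ErrorBudget}}; default \code{errorBudget()}
#'   (about 17\%).
#' @param seed master seed for the realization draws and the calibration
#'   split; default 1.
#' @param slopeMax slope exclusion threshold (degrees); default 15.
#' @param forestThreshold tree-cover threshold (\%); default 10.
#' @param screenThreshold stage-1 uncertainty screen (\%); default 50.
#' @param calFraction calibration fraction of the stratified split used by
#'   \code{nfi_direct}; default 0.67.
#' @param meanGuard guard on the ensemble mean (t/ha); default 1.
#' @param treeConfig list of \code{\link{modelTree}} options.
#' @return \code{list(surface, stack, report)}: the forest-masked
#'   \code{\linkS4class{UncertaintySurface}}, the prediction stack, and a
#'   report of counts at every filter step (plus the stage-1 surface for
#'   the two-stage scenarios).
#' @export
runScenario <- function(scene,
                        scenario = c("nfi_direct", "lidar_two_stage",
                                     "lidar_two_stage_screened"),
                        n = 100, epsField = errorBudget(), seed = 1,
                        slopeMax = 15, forestThreshold = 10,
                        screenThreshold = 50, calFraction = 0.67,
                        meanGuard = 1, treeConfig = list()) {
  scenario <- match.arg(scenario)
  stopifnot(is(scene, "SyntheticScene"))
  cfg <- scene@config
  plots <- scene@plots
  report <- list(scenario = scenario, n_realizations = n, seed = seed,
                 n_plots_total = nrow(plots))
  plots <- plots[plots$slope_deg <= slopeMax, , drop = FALSE]
  report$n_plots_after_slope <- nrow(plots)
  satLayers <- scene@predictorLayers
  satTarget <- layersToMatrix(satLayers)
  d <- dim(scene@trueAGB)

  fitStack <- function(rs, trainX, target, label) {
    do.call(mcFitPredict,
            c(list(realizations = rs, trainPredictors = trainX,
                   targetPredictors = target, dims = d, scenario = label),
              treeConfig))
  }

  if (scenario == "nfi_direct") {
    split <- stratifiedSplit(plots, seed = deriveSeed(seed, "calsplit"),
                             calFraction = calFraction)
    cal <- split$cal
    report$n_calibration_plots <- nrow(cal)
    report$n_validation_plots <- nrow(split$val)
    rs <- generateRealizations(cal$agb_plot, epsField, n = n,
                               masterSeed = deriveSeed(seed, "nfi"))
    trainX <- satTarget[(cal$col - 1L) * d[1] + cal$row, , drop = FALSE]
    stack <- fitStack(rs, trainX, satTarget, "NFI-direct")
  } else {
    onStrip <- plotsOnStrips(plots, scene@stripMask, cfg@pixelSize)
    strip <- plots[onStrip, , drop = FALSE]
    report$n_plots_on_strips <- nrow(strip)
    if (nrow(strip) == 0) stop("no plots lie on the LiDAR strips")
    lidarAll <- layersToMatrix(scene@lidarMetrics)
    stripIdx <- which(as.vector(scene@stripMask))
    plotIdx <- (strip$col - 1L) * d[1] + strip$row
    lidarAtPlots <- lidarAll[plotIdx, , drop = FALSE]
    # residual screen against a single fit on the un-noised mean response
    refFit <- do.call(modelTree, c(list(X = lidarAtPlots,
                                        y = strip$agb_plot), treeConfig))
    keep <- residualOutlierMask(strip$agb_plot,
                                predict(refFit, lidarAtPlots), k = 2)
    report$n_plots_outlier_excluded <- sum(!keep)
    strip <- strip[keep, , drop = FALSE]
    report$n_plots_stage1 <- nrow(strip)
    rs <- generateRealizations(strip$agb_plot, epsField, n = n,
                               masterSeed = deriveSeed(seed, "lidar"))
    lidarTrain <- lidarAll[(strip$col - 1L) * d[1] + strip$row, ,
                           drop = FALSE]
    stage1 <- fitStack(rs, lidarTrain, lidarAll, "LiDAR-stage1")
    stage1Surf <- relativeUncertainty(stage1, meanGuard = meanGuard)
    report$n_strip_pixels <- length(stripIdx)
    trainIdx <- stripIdx
    if (scenario == "lidar_two_stage_screened") {
      ok <- uncertaintyScreen(stage1Surf, threshold = screenThreshold)
      trainIdx <- intersect(stripIdx, which(as.vector(ok)))
      report$n_strip_pixels_screened <- length(trainIdx)
      if (length(trainIdx) == 0) stop("uncertainty screen removed all pixels")
    }
    s1mat <- matrix(stage1@values, d[1] * d[2], n)
    stage2Responses <- t(s1mat[trainIdx, , drop = FALSE])
    stack <- fitStack(stage2Responses, satTarget[trainIdx, , drop = FALSE],
                      satTarget,
                      if (scenario == "lidar_two_stage") "LiDAR-stage2"
                      else "LiDAR-stage2-screened")
    report$stage1_surface <- stage1Surf
  }

  surf <- relativeUncertainty(stack, meanGuard = meanGuard)
  forest <- forestMask(satLayers$tree_cover, forestThreshold)
  report$n_forest_pixels <- sum(forest)
  mask <- function(m) { m[!forest] <- NA_real_; m }
  surf <- new("UncertaintySurface", meanAGB = mask(surf@meanAGB),
              ci95Halfwidth = mask(surf@ci95Halfwidth),
              relUncertainty = mask(surf@relUncertainty))
  report$total_agc_tC <- totalCarbon(surf@meanAGB,
                                     pixelArea = (cfg@pixelSize / 100)^2)
  report$mean_rel_uncertainty_pct <-
    mean(surf@relUncertainty[is.finite(surf@relUncertainty)])
  list(surface = surf, stack = stack, report = report)
}

#' Write scenario outputs as plain-text rasters plus a JSON report
#'
#' @param result list from \code{\link{runScenario}}.
#' @param dir output directory.
#' @return \code{dir}, invisibly.
#' @export
writeScenario <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wl <- function(m, name)
    utils::write.table(m, file.path(dir, paste0(name, ".tsv")),
                       row.names = FALSE, col.names = FALSE)
  wl(result$surface@meanAGB, "agb_mean")
  wl(result$surface@ci95Halfwidth, "agb_ci95")
  wl(result$surface@relUncertainty, "agb_uncert")
  rep <- result$report
  rep$stage1_surface <- NULL
  jsonlite::write_json(rep, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
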