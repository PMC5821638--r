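#' SceneConfig: parameters of a synthetic forest scene
#'
#' Describes the statistical structure of a synthetic study area: the true
#' AGB random field, the inventory-plot network (1 ha plots of four 0.04 ha
#' sub-plots on a regular grid), partial-coverage LiDAR strips, and the
#' SAR/optical/terrain predictor layers. All lengths are metres, areas
#' hectares, AGB in t/ha.
#'
#' @slot gridRows,gridCols raster dimensions in pixels.
#' @slot pixelSize pixel edge length (m); 100 m gives 1-ha pixels.
#' @slot agbMean,agbSD,agbMax target mean, SD and ceiling of the true AGB
#'   field (t/ha).
#' @slot correlationLength e-folding correlation length of the AGB field (m).
#' @slot plotSpacing spacing of the regular plot grid (m).
#' @slot subplotsPerPlot number of sub-plots per plot (4 in national
#'   inventories of this design).
#' @slot subplotArea area of one sub-plot (ha).
#' @slot subplotNoisePct relative measurement error per sub-plot AGB (%).
#' @slot geolocationSD SD of Gaussian plot-centre geolocation jitter (m).
#' @slot lidarStripWidth width of each LiDAR strip (pixels).
#' @slot lidarCoverageFraction fraction of scene columns covered by strips.
#' @slot nLidarMetrics number of synthetic plot-aggregated LiDAR metrics.
#' @slot lidarNoiseSD additive metric noise, as a fraction of each metric's
#'   noise-free SD.
#' @slot sarParams named list with elements \code{HH}, \code{HV} (each
#'   \code{list(A, B, alpha)}: dB offset, dB dynamic range, 1/(t/ha) rate)
#'   and \code{looks} (gamma-speckle shape L).
#' @slot opticalParams named list of per-band saturation constants (see
#'   \code{\link{simulateSatellite}}).
#' @slot seed master integer seed; all layers derive child seeds from it.
#' @seealso \code{\link{sceneConfig}}, \code{\link{simulateScene}}
#' @export
setClass("SceneConfig", representation(
  gridRows = "integer", gridCols = "integer", pixelSize = "numeric",
  agbMean = "numeric", agbSD = "numeric", agbMax = "numeric",
  correlationLength = "numeric", plotSpacing = "numeric",
  subplotsPerPlot = "integer", subplotArea = "numeric",
  subplotNoisePct = "numeric", geolocationSD = "numeric",
  lidarStripWidth = "integer", lidarCoverageFraction = "numeric",
  nLidarMetrics = "integer", lidarNoiseSD = "numeric",
  sarParams = "list", opticalParams = "list", seed = "integer"))

setValidity("SceneConfig", function(object) {
  msg <- character()
  pos <- c(gridRows = object@gridRows, gridCols = object@gridCols,
           pixelSize = object@pixelSize, agbMean = object@agbMean,
           correlationLength = object@correlationLength,
           plotSpacing = object@plotSpacing,
           subplotsPerPlot = object@subplotsPerPlot,
           subplotArea = object@subplotArea,
           lidarStripWidth = object@lidarStripWidth,
           nLidarMetrics = object@nLidarMetrics)
  bad <- names(pos)[!is.finite(pos) | pos <= 0]
  if (length(bad)) msg <- c(msg, paste0("must be > 0: ",
                                        paste(bad, collapse = ", ")))
  if (object@agbSD < 0) msg <- c(msg, "agbSD must be >= 0")
  if (object@agbMax < object@agbMean)
    msg <- c(msg, "agbMax must be >= agbMean")
  if (object@lidarCoverageFraction < 0 || object@lidarCoverageFraction > 1)
    msg <- c(msg, "lidarCoverageFraction must be in [0, 1]")
  if (object@geolocationSD < 0) msg <- c(msg, "geolocationSD must be >= 0")
  if (object@subplotNoisePct < 0) msg <- c(msg, "subplotNoisePct must be >= 0")
  if (object@plotSpacing < object@pixelSize)
    msg <- c(msg, "plotSpacing must be >= pixelSize")
  if (!all(c("HH", "HV", "looks") %in% names(object@sarParams)))
    msg <- c(msg, "sarParams must contain HH, HV and looks")
  else if (object@sarParams$looks <= 0)
    msg <- c(msg, "sarParams$looks must be > 0")
  if (length(msg)) msg else TRUE
})

#' SyntheticScene: a generated study area
#'
#' Holds the true AGB raster, the predictor layers (SAR backscatter in dB,
#' optical reflectances, NDVI, tree cover, terrain), the plot-aggregated
#' LiDAR metrics (defined only inside the strip mask, \code{NA} elsewhere),
#' the strip mask and the simulated inventory-plot table. All rasters are
#' numeric matrices on one planar grid; \code{NA} is nodata.
#'
#' @slot trueAGB true AGB raster (t/ha).
#' @slot predictorLayers named list of rasters: \code{HH}, \code{HV} (dB),
#'   \code{red}, \code{nir}, \code{swir1}, \code{swir2} (reflectance),
#'   \code{ndvi}, \code{tree_cover} (%), \code{altitude} (m),
#'   \code{slope} (degrees).
#' @slot lidarMetrics named list of metric rasters, \code{NA} off-strip.
#' @slot stripMask logical raster, \code{TRUE} inside LiDAR strips.
#' @slot plots data.frame with columns \code{plot_id}, \code{x}, \code{y},
#'   \code{row}, \code{col}, \code{agb_sub1..agb_subK}, \code{agb_plot},
#'   \code{agb_true}, \code{slope_deg}.
#' @slot config the \code{\linkS4class{SceneConfig}} that generated the scene.
#' @export
setClass("SyntheticScene", representation(
  trueAGB = "matrix", predictorLayers = "list", lidarMetrics = "list",
  stripMask = "matrix", plots = "data.frame", config = "SceneConfig"))

setValidity("SyntheticScene", function(object) {
  msg <- character()
  d <- dim(object@trueAGB)
  allLayers <- c(object@predictorLayers, object@lidarMetrics,
                 list(strip = object@stripMask))
  for (nm in names(allLayers)) {
    if (!identical(dim(allLayers[[nm]]), d))
      msg <- c(msg, paste0("layer '", nm, "' is not on the scene grid"))
  }
  if (any(object@trueAGB < 0, na.rm = TRUE))
    msg <- c(msg, "trueAGB must be >= 0 everywhere")
  tc <- object@predictorLayers[["tree_cover"]]
  if (!is.null(tc) && (any(tc < 0, na.rm = TRUE) || any(tc > 100, na.rm = TRUE)))
    msg <- c(msg, "tree_cover must lie in [0, 100]")
  if (length(object@lidarMetrics)) {
    off <- !object@stripMask
    for (nm in names(object@lidarMetrics)) {
      if (any(is.finite(object@lidarMetrics[[nm]][off])))
        msg <- c(msg, paste0("lidar metric '", nm,
                             "' has data outside the strip mask"))
    }
  }
  if (length(msg)) msg else TRUE
})

#' ErrorBudget: relative error components of field-estimated AGB
#'
#' The total relative error of plot-level AGB is the root sum of squares of
#' independent measurement, allometric-model and sampling components,
#' all expressed in percent.
#'
#' @slot measurementPct,allometryPct,samplingPct component errors (%).
#' @slot totalPct root-sum-square total (%).
#' @seealso \code{\link{errorBudget}}, \code{\link{composeError}}
#' @export
setClass("ErrorBudget", representation(
  measurementPct = "numeric", allometryPct = "numeric",
  samplingPct = "numeric", totalPct = "numeric"))

setValidity("ErrorBudget", function(object) {
  comp <- c(object@measurementPct, object@allometryPct, object@samplingPct)
  if (any(comp < 0)) return("error components must be >= 0")
  if (abs(object@totalPct - sqrt(sum(comp^2))) > 1e-8)
    return("totalPct must equal the root sum of squares of the components")
  TRUE
})

#' RealizationSet: Monte-Carlo noisy copies of a reference AGB vector
#'
#' Row \code{r} holds realization \code{r} of the reference values:
#' \code{base * (1 + eps/100 * X)} with standard-normal \code{X}, clipped at
#' zero. Each realization is reproducible in isolation from
#' \code{(masterSeed, r)}.
#'
#' @slot values \code{n x m} matrix of AGB realizations (t/ha).
#' @slot base reference AGB vector of length \code{m} (t/ha).
#' @slot epsFieldPct relative field error used (%).
#' @slot masterSeed integer master seed.
#' @seealso \code{\link{generateRealizations}}
#' @export
setClass("RealizationSet", representation(
  values = "matrix", base = "numeric", epsFieldPct = "numeric",
  masterSeed = "integer"))

setValidity("RealizationSet", function(object) {
  msg <- character()
  if (ncol(object@values) != length(object@base))
    msg <- c(msg, "ncol(values) must match length(base)")
  if (any(object@values < 0, na.rm = TRUE))
    msg <- c(msg, "realization values must be >= 0 (clipped)")
  if (object@epsFieldPct < 0) msg <- c(msg, "epsFieldPct must be >= 0")
  if (length(msg)) msg else TRUE
})

#' ModelTree: rule-based piecewise-linear regressor
#'
#' A model tree grown by recursive binary splitting on the SD-reduction
#' criterion, with a multivariate linear model at every node, pruning of
#' subtrees that do not beat their node's linear model, recursive smoothing
#' of leaf predictions through ancestor models, and clamping of predictions
#' to the training response range (plus a small extrapolation margin).
#' Committee members, if requested, are fitted on residual-adjusted
#' responses and averaged.
#'
#' @slot committees list of fitted trees (length \code{nCommittees}); each
#'   tree is a recursive list of nodes (split variable, threshold, linear
#'   coefficients, training size).
#' @slot predictorNames column names the model was trained on.
#' @slot yRange numeric length-2 training response range.
#' @slot config list echoing the training configuration.
#' @seealso \code{\link{modelTree}}, \code{\link{predict,ModelTree-method}}
#' @export
setClass("ModelTree", representation(
  committees = "list", predictorNames = "character", yRange = "numeric",
  config = "list"))

#' PredictionStack: ensemble of predicted AGB rasters
#'
#' \code{n} co-registered AGB maps (t/ha), one per Monte-Carlo realization,
#' stored as a \code{rows x cols x n} array with \code{NA} nodata. The
#' stack is the source of the mean, CI95 and relative-uncertainty surfaces.
#'
#' @slot values 3-D array (rows, cols, realizations).
#' @slot provenance list: scenario label, learner config, seeds.
#' @seealso \code{\link{mcFitPredict}}, \code{\link{ci95}},
#'   \code{\link{relativeUncertainty}}
#' @export
setClass("PredictionStack", representation(
  values = "array", provenance = "list"))

setValidity("PredictionStack", function(object) {
  if (length(dim(object@values)) != 3L)
    return("values must be a rows x cols x n array")
  if (dim(object@values)[3] < 1L) return("stack must hold >= 1 realization")
  TRUE
})

#' UncertaintySurface: per-pixel mean, CI95 half-width and uncertainty
#'
#' @slot meanAGB ensemble-mean AGB raster (t/ha).
#' @slot ci95Halfwidth raster of half the distance between the empirical
#'   97.5th and 2.5th percentiles (t/ha).
#' @slot relUncertainty raster of 100 * CI95 / mean (%), \code{NA} where the
#'   ensemble mean falls below the guard.
#' @seealso \code{\link{relativeUncertainty}}
#' @export
setClass("UncertaintySurface", representation(
  meanAGB = "matrix", ci95Halfwidth = "matrix", relUncertainty = "matrix"))

setValidity("UncertaintySurface", function(object) {
  msg <- character()
  if (!identical(dim(object@meanAGB), dim(object@ci95Halfwidth)) ||
      !identical(dim(object@meanAGB), dim(object@relUncertainty)))
    msg <- c(msg, "all surfaces must share one grid")
  if (any(object@ci95Halfwidth < 0, na.rm = TRUE))
    msg <- c(msg, "ci95Halfwidth must be >= 0")
  if (any(object@relUncertainty < 0, na.rm = TRUE))
    msg <- c(msg, "relUncertainty must be >= 0 where defined")
  if (length(msg)) msg else TRUE
})
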