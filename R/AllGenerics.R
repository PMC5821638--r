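#' @include AllClasses.R
NULL

#' Accessors for scene and ensemble objects
#'
#' @param object a package object.
#' @name accessors
#' @aliases trueAGB predictorLayers lidarMetrics stripMask scenePlots
#'   sceneConfig realizationValues stackValues nRealizations meanSurface
#'   ci95Surface uncertaintySurface
NULL

#' @rdname accessors
#' @export
setGeneric("trueAGB", function(object) standardGeneric("trueAGB"))
#' @rdname accessors
#' @export
setGeneric("predictorLayers",
           function(object) standardGeneric("predictorLayers"))
#' @rdname accessors
#' @export
setGeneric("lidarMetrics", function(object) standardGeneric("lidarMetrics"))
#' @rdname accessors
#' @export
setGeneric("stripMask", function(object) standardGeneric("stripMask"))
#' @rdname accessors
#' @export
setGeneric("scenePlots", function(object) standardGeneric("scenePlots"))
#' @rdname accessors
#' @export
setGeneric("sceneConfig", function(object, ...) standardGeneric("sceneConfig"))
#' @rdname accessors
#' @export
setGeneric("realizationValues",
           function(object) standardGeneric("realizationValues"))
#' @rdname accessors
#' @export
setGeneric("stackValues", function(object) standardGeneric("stackValues"))
#' @rdname accessors
#' @export
setGeneric("nRealizations", function(object) standardGeneric("nRealizations"))
#' @rdname accessors
#' @export
setGeneric("meanSurface", function(object) standardGeneric("meanSurface"))
#' @rdname accessors
#' @export
setGeneric("ci95Surface", function(object) standardGeneric("ci95Surface"))
#' @rdname accessors
#' @export
setGeneric("uncertaintySurface",
           function(object) standardGeneric("uncertaintySurface"))

#' Per-pixel 95\% confidence-interval half-width of a prediction ensemble
#'
#' @param stack a \code{\linkS4class{PredictionStack}} (or an
#'   \code{n x m} matrix of realizations in rows).
#' @param ... passed to methods.
#' @return Raster (matrix) of CI95 half-widths, \code{(q97.5 - q2.5) / 2},
#'   computed with linear-interpolation empirical quantiles.
#' @export
setGeneric("ci95", function(stack, ...) standardGeneric("ci95"))

#' Per-pixel relative uncertainty of a prediction ensemble
#'
#' @param stack a \code{\linkS4class{PredictionStack}} (or \code{n x m}
#'   matrix).
#' @param meanGuard pixels with ensemble mean below this (t/ha) get
#'   \code{NA} relative uncertainty; guards against division blow-up at
#'   near-zero biomass. Default 1 t/ha.
#' @param ... passed to methods.
#' @return An \code{\linkS4class{UncertaintySurface}}.
#' @export
setGeneric("relativeUncertainty",
           function(stack, meanGuard = 1, ...)
             standardGeneric("relativeUncertainty"))

## ---- accessor methods ----

#' @rdname accessors
#' @export
setMethod("trueAGB", "SyntheticScene", function(object) object@trueAGB)
#' @rdname accessors
#' @export
setMethod("predictorLayers", "SyntheticScene",
          function(object) object@predictorLayers)
#' @rdname accessors
#' @export
setMethod("lidarMetrics", "SyntheticScene",
          function(object) object@lidarMetrics)
#' @rdname accessors
#' @export
setMethod("stripMask", "SyntheticScene", function(object) object@stripMask)
#' @rdname accessors
#' @export
setMethod("scenePlots", "SyntheticScene", function(object) object@plots)
#' @rdname accessors
#' @export
setMethod("sceneConfig", "SyntheticScene", function(object, ...) object@config)
#' @rdname accessors
#' @export
setMethod("realizationValues", "RealizationSet",
          function(object) object@values)
#' @rdname accessors
#' @export
setMethod("nRealizations", "RealizationSet",
          function(object) nrow(object@values))
#' @rdname accessors
#' @export
setMethod("stackValues", "PredictionStack", function(object) object@values)
#' @rdname accessors
#' @export
setMethod("nRealizations", "PredictionStack",
          function(object) dim(object@values)[3])
#' @rdname accessors
#' @export
setMethod("meanSurface", "UncertaintySurface", function(object) object@meanAGB)
#' @rdname accessors
#' @export
setMethod("ci95Surface", "UncertaintySurface",
          function(object) object@ci95Halfwidth)
#' @rdname accessors
#' @export
setMethod("uncertaintySurface", "UncertaintySurface",
          function(object) object@relUncertainty)

## ---- show methods ----

setMethod("show", "SceneConfig", function(object) {
  cat(sprintf("SceneConfig: %d x %d px @ %g m (%.1f x %.1f km)\n",
              object@gridRows, object@gridCols, object@pixelSize,
              object@gridRows * object@pixelSize / 1000,
              object@gridCols * object@pixelSize / 1000))
  cat(sprintf("  AGB field: mean %g, SD %g, max %g t/ha; corr. length %g m\n",
              object@agbMean, object@agbSD, object@agbMax,
              object@correlationLength))
  cat(sprintf("  plots: spacing %g m, %d x %g ha sub-plots, noise %g%%\n",
              object@plotSpacing, object@subplotsPerPlot, object@subplotArea,
              object@subplotNoisePct))
  cat(sprintf("  LiDAR: %d metrics, strip width %d px, coverage %.0f%%\n",
              object@nLidarMetrics, object@lidarStripWidth,
              100 * object@lidarCoverageFraction))
  cat(sprintf("  seed: %d\n", object@seed))
})

setMethod("show", "SyntheticScene", function(object) {
  cat(sprintf("SyntheticScene: %d x %d px, %d predictor layers, %d LiDAR metrics\n",
              nrow(object@trueAGB), ncol(object@trueAGB),
              length(object@predictorLayers), length(object@lidarMetrics)))
  cat(sprintf("  true AGB: mean %.1f, SD %.1f, max %.1f t/ha\n",
              mean(object@trueAGB), sd(as.vector(object@trueAGB)),
              max(object@trueAGB)))
  cat(sprintf("  strips cover %.1f%% of pixels; %d plots\n",
              100 * mean(object@stripMask), nrow(object@plots)))
})

setMethod("show", "ErrorBudget", function(object) {
  cat(sprintf(
    "ErrorBudget: measurement %.1f%% + allometry %.1f%% + sampling %.1f%% (RSS) = %.2f%%\n",
    object@measurementPct, object@allometryPct, object@samplingPct,
    object@totalPct))
})

setMethod("show", "RealizationSet", function(object) {
  cat(sprintf("RealizationSet: %d realizations x %d values, eps_field %.1f%%, seed %d\n",
              nrow(object@values), ncol(object@values), object@epsFieldPct,
              object@masterSeed))
})

setMethod("show", "ModelTree", function(object) {
  nl <- vapply(object@committees, countLeaves, integer(1))
  cat(sprintf("ModelTree: %d committee(s), %s leaves, %d predictors\n",
              length(object@committees), paste(nl, collapse = "/"),
              length(object@predictorNames)))
  cat(sprintf("  response range [%.2f, %.2f], smoothing %s\n",
              object@yRange[1], object@yRange[2],
              if (isTRUE(object@config$smoothing)) "on" else "off"))
})

setMethod("show", "PredictionStack", function(object) {
  d <- dim(object@values)
  cat(sprintf("PredictionStack: %d x %d px, %d realizations (%s)\n",
              d[1], d[2], d[3],
              if (is.null(object@provenance$scenario)) "unlabelled"
              else object@provenance$scenario))
})

setMethod("show", "UncertaintySurface", function(object) {
  cat(sprintf("UncertaintySurface: %d x %d px\n",
              nrow(object@meanAGB), ncol(object@meanAGB)))
  ok <- is.finite(object@relUncertainty)
  if (any(ok))
    cat(sprintf("  mean AGB %.1f t/ha; mean relative uncertainty %.1f%% over %d px\n",
                mean(object@meanAGB[is.finite(object@meanAGB)]),
                mean(object@relUncertainty[ok]), sum(ok)))
})
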