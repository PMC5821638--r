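#' @include AllClasses.R utils.R sarTools.R
NULL

#' Construct a scene configuration
#'
#' Defaults describe the study conditions the package's simulations assume:
#' a 20 x 20 km scene of 1-ha pixels whose true AGB field has mean 45 t/ha,
#' SD 35 t/ha and a 160 t/ha ceiling; a regular network of 1-ha plots (four
#' 0.04 ha sub-plots each) at 700 m spacing with 10 m geolocation jitter
#' and 10% per-sub-plot measurement noise; narrow LiDAR strips (4 pixels,
#' a 400 m swath) covering 6% of the scene with 12 plot-aggregated metrics
#' whose individual correlation with AGB is about 0.8; dual-pol L-band
#' backscatter saturating around 100 t/ha with 4-look gamma speckle; and
#' optical reflectances, tree cover and terrain derived from the same
#' field. Plots fully inside the strips are then a small minority of the
#' network, and the strip pixels greatly outnumber them, mirroring the
#' relative data volumes of a national inventory, an airborne campaign and
#' a wall-to-wall satellite mosaic.
#'
#' @param gridRows,gridCols raster dimensions (pixels); default 200 x 200.
#' @param pixelSize pixel edge (m); default 100 (1-ha pixels).
#' @param agbMean,agbSD,agbMax AGB field targets (t/ha); defaults 45/35/160.
#' @param correlationLength AGB correlation length (m); default 2000.
#' @param plotSpacing plot-grid spacing (m); default 700.
#' @param subplotsPerPlot,subplotArea sub-plot design; defaults 4 and 0.04 ha.
#' @param subplotNoisePct per-sub-plot relative measurement noise (%);
#'   default 10.
#' @param geolocationSD plot-centre jitter SD (m); default 10.
#' @param lidarStripWidth strip width (pixels); default 4 (a 400 m
#'   airborne-LiDAR swath at the default pixel size).
#' @param lidarCoverageFraction fraction of columns under strips; default
#'   0.06 (strips sample a small share of the scene, as airborne
#'   campaigns do).
#' @param nLidarMetrics number of synthetic LiDAR metrics; default 12.
#' @param lidarNoiseSD metric noise as a fraction of the noise-free metric
#'   SD; default 0.8 (per-metric correlation with AGB around 0.75-0.85,
#'   the regime of real plot-aggregated canopy metrics).
#' @param sarParams,opticalParams see \code{\linkS4class{SceneConfig}};
#'   \code{NULL} takes the defaults described above.
#' @param seed master seed; default 1.
#' @return A validated \code{\linkS4class{SceneConfig}}.
#' @export
#' @examples
#' SceneConfig(gridRows = 50, gridCols = 50, seed = 7)
SceneConfig <- function(gridRows = 200, gridCols = 200, pixelSize = 100,
                        agbMean = 45, agbSD = 35, agbMax = 160,
                        correlationLength = 2000, plotSpacing = 700,
                        subplotsPerPlot = 4, subplotArea = 0.04,
                        subplotNoisePct = 10, geolocationSD = 10,
                        lidarStripWidth = 4, lidarCoverageFraction = 0.06,
                        nLidarMetrics = 12, lidarNoiseSD = 0.8,
                        sarParams = NULL, opticalParams = NULL, seed = 1) {
  if (is.null(sarParams)) {
    sarParams <- list(
      HH = list(A = -14, B = 6, alpha = 0.03),
      HV = list(A = -22, B = 10, alpha = 0.04),
      looks = 4)
  }
  if (is.null(opticalParams)) {
    opticalParams <- list(
      red   = list(b0 = 0.10, bsat = 0.030, k = 0.030, noiseSD = 0.004),
      nir   = list(b0 = 0.20, bsat = 0.320, k = 0.025, noiseSD = 0.008),
      swir1 = list(b0 = 0.25, bsat = 0.100, k = 0.030, noiseSD = 0.008),
      swir2 = list(b0 = 0.20, bsat = 0.060, k = 0.030, noiseSD = 0.006),
      treeCover = list(mid = 30, scale = 12),
      terrain = list(altitudeBase = 1000, altitudeSD = 120,
                     correlationLength = 3000))
  }
  new("SceneConfig",
      gridRows = as.integer(gridRows), gridCols = as.integer(gridCols),
      pixelSize = pixelSize, agbMean = agbMean, agbSD = agbSD,
      agbMax = agbMax, correlationLength = correlationLength,
      plotSpacing = plotSpacing, subplotsPerPlot = as.integer(subplotsPerPlot),
      subplotArea = subplotArea, subplotNoisePct = subplotNoisePct,
      geolocationSD = geolocationSD,
      lidarStripWidth = as.integer(lidarStripWidth),
      lidarCoverageFraction = lidarCoverageFraction,
      nLidarMetrics = as.integer(nLidarMetrics), lidarNoiseSD = lidarNoiseSD,
      sarParams = sarParams, opticalParams = opticalParams,
      seed = as.integer(seed))
}

#' Simulate the true AGB field of a scene
#'
#' A Gaussian random field with exponential covariance (spectral synthesis)
#' is affinely rescaled to the configured mean and SD and clipped to
#' \code{[0, agbMax]}. With \code{agbSD = 0} the field is constant
#' \code{agbMean}.
#'
#' @param config a \code{\linkS4class{SceneConfig}}.
#' @return AGB matrix (t/ha).
#' @export
simulateTrueAGB <- function(config) {
  validObject(config)
  if (config@agbSD == 0) {
    return(matrix(config@agbMean, config@gridRows, config@gridCols))
  }
  z <- gaussianRandomField(config@gridRows, config@gridCols,
                           config@correlationLength / config@pixelSize,
                           deriveSeed(config@seed, "true_agb"))
  pmin(pmax(config@agbMean + config@agbSD * z, 0), config@agbMax)
}

## Altitude from an independent random field; slope (degrees) from its
## central-difference gradient.
simulateTerrain <- function(config) {
  tp <- config@opticalParams$terrain
  z <- gaussianRandomField(config@gridRows, config@gridCols,
                           tp$correlationLength / config@pixelSize,
                           deriveSeed(config@seed, "terrain"))
  altitude <- tp$altitudeBase + tp$altitudeSD * z
  nr <- nrow(altitude); nc <- ncol(altitude)
  pad <- function(i, n) pmin(pmax(i, 1L), n)
  dzdr <- (altitude[pad(2:(nr + 1), nr), ] -
           altitude[pad(0:(nr - 1), nr), ]) / (2 * config@pixelSize)
  dzdc <- (altitude[, pad(2:(nc + 1), nc)] -
           altitude[, pad(0:(nc - 1), nc)]) / (2 * config@pixelSize)
  slope <- atan(sqrt(dzdr^2 + dzdc^2)) * 180 / pi
  list(altitude = altitude, slope = slope)
}

#' Simulate the inventory-plot network
#'
#' Plots sit on a regular grid of spacing \code{plotSpacing}, with Gaussian
#' geolocation jitter of the plot centre. Each plot samples
#' \code{subplotsPerPlot} sub-plot AGB values from the true field at the
#' sub-plot pixel, each with independent relative measurement noise; the
#' plot AGB is the sub-plot mean (the per-hectare extrapolation of the
#' sub-plot sample). Slope is read at the plot-centre pixel.
#'
#' @param scene a \code{\linkS4class{SyntheticScene}}, or a list with
#'   elements \code{trueAGB} and \code{slope} matrices.
#' @param config a \code{\linkS4class{SceneConfig}}.
#' @return data.frame with one row per plot (see
#'   \code{\linkS4class{SyntheticScene}}).
#' @export
simulatePlots <- function(scene, config) {
  if (is(scene, "SyntheticScene")) {
    agb <- scene@trueAGB
    slope <- scene@predictorLayers$slope
  } else {
    agb <- scene$trueAGB
    slope <- scene$slope
  }
  if (is.null(agb)) stop("true AGB field required before plot simulation")
  if (config@plotSpacing < config@pixelSize)
    stop("'plotSpacing' must be at least one pixel")
  ps <- config@pixelSize
  extX <- ncol(agb) * ps
  extY <- nrow(agb) * ps
  cx <- seq(config@plotSpacing / 2, extX, by = config@plotSpacing)
  cy <- seq(config@plotSpacing / 2, extY, by = config@plotSpacing)
  centers <- expand.grid(y = cy, x = cx)
  nPlots <- nrow(centers)
  K <- config@subplotsPerPlot
  sim <- withSeed(deriveSeed(config@seed, "plots"), {
    jitter <- matrix(rnorm(2 * nPlots, sd = config@geolocationSD), ncol = 2)
    noise <- matrix(rnorm(nPlots * K), nPlots, K)
    list(jitter = jitter, noise = noise)
  })
  px <- pmin(pmax(centers$x + sim$jitter[, 1], ps / 2), extX - ps / 2)
  py <- pmin(pmax(centers$y + sim$jitter[, 2], ps / 2), extY - ps / 2)
  rowC <- yToRow(py, ps); colC <- xToCol(px, ps)
  # the 56.42 m plot footprint is sub-pixel at 1 ha resolution: all
  # sub-plots sample the field at the (possibly mis-located) plot pixel,
  # and sub-plot scatter comes from the measurement noise
  truth <- agb[cbind(rowC, colC)]
  sub <- matrix(pmax(0, truth * (1 + config@subplotNoisePct / 100 *
                                   sim$noise)), nPlots, K)
  plots <- data.frame(plot_id = seq_len(nPlots), x = px, y = py,
                      row = rowC, col = colC)
  for (k in seq_len(K)) plots[[paste0("agb_sub", k)]] <- sub[, k]
  plots$agb_plot <- rowMeans(sub)
  plots$agb_true <- truth
  plots$slope_deg <- if (is.null(slope)) 0 else slope[cbind(rowC, colC)]
  plots
}

#' Simulate plot-aggregated LiDAR metrics along strips
#'
#' Vertical strips of \code{lidarStripWidth} pixels are laid out to cover
#' \code{lidarCoverageFraction} of the scene columns. Each metric is a
#' power law of true AGB, \code{m_k = a_k * AGB^b_k + noise}, with
#' coefficients drawn once from the scene seed; metrics are \code{NA}
#' off-strip.
#'
#' @param scene \code{\linkS4class{SyntheticScene}} or list with
#'   \code{trueAGB}.
#' @param config a \code{\linkS4class{SceneConfig}}.
#' @param coefA,coefB optional fixed power-law coefficients (length
#'   \code{nLidarMetrics}) overriding the seeded draw.
#' @return \code{list(lidarMetrics = <named list>, stripMask = <logical
#'   matrix>)}.
#' @export
simulateLidar <- function(scene, config, coefA = NULL, coefB = NULL) {
  agb <- if (is(scene, "SyntheticScene")) scene@trueAGB else scene$trueAGB
  if (is.null(agb)) stop("true AGB field required before LiDAR simulation")
  if (config@nLidarMetrics < 1L) stop("need at least one LiDAR metric")
  nr <- nrow(agb); nc <- ncol(agb)
  w <- config@lidarStripWidth
  mask <- matrix(FALSE, nr, nc)
  if (config@lidarCoverageFraction > 0) {
    nStrips <- max(1L, round(config@lidarCoverageFraction * nc / w))
    if (config@lidarCoverageFraction >= 1 || nStrips * w >= nc) {
      mask[] <- TRUE
    } else {
      starts <- unique(round(seq(1, nc - w + 1, length.out = nStrips)))
      for (s in starts) mask[, s:(s + w - 1L)] <- TRUE
    }
  }
  K <- config@nLidarMetrics
  seeded <- withSeed(deriveSeed(config@seed, "lidar"), {
    list(a = runif(K, 0.5, 2), b = runif(K, 0.4, 1.2),
         noise = lapply(seq_len(K), function(k) matrix(rnorm(nr * nc), nr, nc)))
  })
  if (is.null(coefA)) coefA <- seeded$a
  if (is.null(coefB)) coefB <- seeded$b
  stopifnot(length(coefA) == K, length(coefB) == K)
  metrics <- vector("list", K)
  names(metrics) <- sprintf("lidar_m%02d", seq_len(K))
  for (k in seq_len(K)) {
    signal <- coefA[k] * agb^coefB[k]
    m <- signal + config@lidarNoiseSD * sd(as.vector(signal)) *
      seeded$noise[[k]]
    m[!mask] <- NA_real_
    metrics[[k]] <- m
  }
  list(lidarMetrics = metrics, stripMask = mask)
}

## Mean backscatter curve in dB: A + B * (1 - exp(-alpha * AGB)).
sarMeanDb <- function(agb, p) p$A + p$B * (1 - exp(-p$alpha * agb))

#' Simulate SAR, optical, tree-cover and terrain predictor layers
#'
#' HH/HV backscatter follows a saturating curve in dB,
#' \code{A + B (1 - exp(-alpha AGB))}; speckle is applied multiplicatively
#' in linear power as unit-mean gamma noise with shape \code{looks}, and
#' the layer is returned in dB. Optical bands decay (or grow) exponentially
#' towards a saturation reflectance with additive Gaussian noise; NDVI is
#' derived from the red and NIR bands; tree cover is a noiseless logistic
#' function of AGB scaled to \code{[0, 100]}; altitude and slope come from
#' an independent random field.
#'
#' @param scene \code{\linkS4class{SyntheticScene}} or list with
#'   \code{trueAGB}.
#' @param config a \code{\linkS4class{SceneConfig}}.
#' @param speckle logical; multiply SAR power by gamma speckle (default
#'   \code{TRUE}).
#' @param opticalNoise logical; add noise to optical bands (default
#'   \code{TRUE}).
#' @return Named list of predictor rasters.
#' @export
simulateSatellite <- function(scene, config, speckle = TRUE,
                              opticalNoise = TRUE) {
  agb <- if (is(scene, "SyntheticScene")) scene@trueAGB else scene$trueAGB
  if (is.null(agb)) stop("true AGB field required before satellite simulation")
  L <- config@sarParams$looks
  if (!is.finite(L) || L <= 0) stop("'looks' must be > 0")
  nr <- nrow(agb); nc <- ncol(agb)
  layers <- list()
  for (pol in c("HH", "HV")) {
    power <- dbToPower(sarMeanDb(agb, config@sarParams[[pol]]))
    if (speckle) {
      sp <- withSeed(deriveSeed(config@seed, paste0("sar_", pol)),
                     matrix(rgamma(nr * nc, shape = L, rate = L), nr, nc))
      power <- power * sp
    }
    layers[[pol]] <- powerToDb(power)
  }
  op <- config@opticalParams
  for (band in c("red", "nir", "swir1", "swir2")) {
    p <- op[[band]]
    refl <- p$bsat + (p$b0 - p$bsat) * exp(-p$k * agb)
    if (opticalNoise) {
      refl <- refl + withSeed(deriveSeed(config@seed, paste0("opt_", band)),
                              matrix(rnorm(nr * nc, sd = p$noiseSD), nr, nc))
    }
    layers[[band]] <- pmax(refl, 0)
  }
  layers$ndvi <- ndvi(layers$red, layers$nir)
  tc <- op$treeCover
  layers$tree_cover <- 100 / (1 + exp(-(agb - tc$mid) / tc$scale))
  terr <- simulateTerrain(config)
  layers$altitude <- terr$altitude
  layers$slope <- terr$slope
  layers
}

#' Generate a complete synthetic scene
#'
#' Orchestrates \code{\link{simulateTrueAGB}},
#' \code{\link{simulateSatellite}}, \code{\link{simulateLidar}} and
#' \code{\link{simulatePlots}} under the configuration's master seed (each
#' layer draws from its own derived child seed, so the scene is bit-
#' reproducible and adding layers never shifts existing ones).
#'
#' @param config a \code{\linkS4class{SceneConfig}}.
#' @return A validated \code{\linkS4class{SyntheticScene}}.
#' @export
#' @examples
#' sc <- simulateScene(SceneConfig(gridRows = 40, gridCols = 40,
#'                                 plotSpacing = 500, seed = 3))
#' sc
simulateScene <- function(config) {
  validObject(config)
  agb <- simulateTrueAGB(config)
  layers <- simulateSatellite(list(trueAGB = agb), config)
  lid <- simulateLidar(list(trueAGB = agb), config)
  plots <- simulatePlots(list(trueAGB = agb, slope = layers$slope), config)
  new("SyntheticScene", trueAGB = agb, predictorLayers = layers,
      lidarMetrics = lid$lidarMetrics, stripMask = lid$stripMask,
      plots = plots, config = config)
}

#' Write / read a scene as a plain-text directory
#'
#' One whitespace-separated text file per raster layer, \code{plots.csv}
#' for the plot table, and \code{scene.yaml} echoing the configuration.
#'
#' @param scene a \code{\linkS4class{SyntheticScene}}.
#' @param dir output directory (created if needed).
#' @return \code{writeScene} returns \code{dir} invisibly;
#'   \code{readScene} returns a \code{SyntheticScene}.
#' @export
writeScene <- function(scene, dir) {
  stopifnot(is(scene, "SyntheticScene"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLayer <- function(m, name) {
    utils::write.table(m, file.path(dir, paste0(name, ".tsv")),
                       row.names = FALSE, col.names = FALSE)
  }
  writeLayer(scene@trueAGB, "true_agb")
  for (nm in names(scene@predictorLayers))
    writeLayer(scene@predictorLayers[[nm]], paste0("pred_", nm))
  for (nm in names(scene@lidarMetrics))
    writeLayer(scene@lidarMetrics[[nm]], nm)
  writeLayer(scene@stripMask * 1, "strip_mask")
  plots <- scene@plots
  attr(plots, "subRow") <- NULL
  attr(plots, "subCol") <- NULL
  utils::write.csv(plots, file.path(dir, "plots.csv"), row.names = FALSE)
  cfg <- scene@config
  cfgList <- lapply(slotNames(cfg), function(s) slot(cfg, s))
  names(cfgList) <- slotNames(cfg)
  yaml::write_yaml(cfgList, file.path(dir, "scene.yaml"))
  invisible(dir)
}

#' @rdname writeScene
#' @export
readScene <- function(dir) {
  readLayer <- function(name) {
    as.matrix(utils::read.table(file.path(dir, paste0(name, ".tsv"))))
  }
  cfgList <- yaml::read_yaml(file.path(dir, "scene.yaml"))
  config <- do.call(SceneConfig, cfgList[
    intersect(names(cfgList), names(formals(SceneConfig)))])
  agb <- unname(readLayer("true_agb"))
  predNames <- sub("^pred_(.*)\\.tsv$", "\\1",
                   grep("^pred_.*\\.tsv$", list.files(dir), value = TRUE))
  predOrder <- c("HH", "HV", "red", "nir", "swir1", "swir2", "ndvi",
                 "tree_cover", "altitude", "slope")
  predNames <- c(intersect(predOrder, predNames),
                 setdiff(predNames, predOrder))
  layers <- lapply(predNames, function(nm) unname(readLayer(paste0("pred_", nm))))
  names(layers) <- predNames
  metNames <- sub("\\.tsv$", "",
                  grep("^lidar_m.*\\.tsv$", list.files(dir), value = TRUE))
  metrics <- lapply(sort(metNames), function(nm) unname(readLayer(nm)))
  names(metrics) <- sort(metNames)
  mask <- unname(readLayer("strip_mask")) > 0
  plots <- utils::read.csv(file.path(dir, "plots.csv"))
  new("SyntheticScene", trueAGB = agb, predictorLayers = layers,
      lidarMetrics = metrics, stripMask = mask, plots = plots,
      config = config)
}
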