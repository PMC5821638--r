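test_that("true AGB field hits the configured moments after clipping", {
  cfg <- SceneConfig(gridRows = 500, gridCols = 500, agbMean = 45,
                     agbSD = 35, agbMax = 160, seed = 21)
  agb <- simulateTrueAGB(cfg)
  expect_lt(abs(mean(agb) - 45), 3)
  expect_lt(abs(sd(as.vector(agb)) - 35), 5)
  expect_true(all(agb >= 0) && all(agb <= 160))

  # degenerate variance
  agb0 <- simulateTrueAGB(SceneConfig(gridRows = 10, gridCols = 10,
                                      agbSD = 0))
  expect_true(all(agb0 == 45))

  expect_error(gaussianRandomField(10, 10, -1, 1), "correlationLength")
  expect_error(SceneConfig(agbMax = 10, agbMean = 45), "agbMax")
})

test_that("scenes are bit-reproducible and layer draws are independent", {
  s1 <- simulateScene(tinyConfig())
  s2 <- simulateScene(tinyConfig())
  expect_identical(trueAGB(s1), trueAGB(s2))
  expect_identical(scenePlots(s1), scenePlots(s2))
  expect_identical(lidarMetrics(s1), lidarMetrics(s2))
  expect_identical(predictorLayers(s1), predictorLayers(s2))

  # changing the LiDAR layer count must not shift any other layer's draws
  s3 <- simulateScene(tinyConfig(nLidarMetrics = 5))
  expect_identical(trueAGB(s1), trueAGB(s3))
  expect_identical(predictorLayers(s1)$HV, predictorLayers(s3)$HV)
  expect_identical(scenePlots(s1), scenePlots(s3))
})

test_that("plot network geometry and the noiseless identity", {
  cfg <- SceneConfig(gridRows = 100, gridCols = 100, plotSpacing = 1000,
                     geolocationSD = 0, subplotNoisePct = 0, seed = 5)
  sc <- simulateScene(cfg)
  p <- scenePlots(sc)
  expect_equal(nrow(p), 100)
  # zero jitter and zero noise: plot AGB equals truth at the plot pixel
  expect_equal(p$agb_plot, p$agb_true, tolerance = 1e-12)
  expect_equal(p$agb_plot,
               trueAGB(sc)[cbind(p$row, p$col)], tolerance = 1e-12)
  expect_error(simulatePlots(list(trueAGB = trueAGB(sc)),
                             tinyConfig(plotSpacing = 50)), "pixel")
})

test_that("sub-plot measurement noise averages at the CLT rate", {
  # constant field so the only plot-level error is the sub-plot noise;
  # 4 sub-plots at 10% noise -> 5% SD of the relative plot error
  cfg <- SceneConfig(gridRows = 200, gridCols = 200, agbMean = 100,
                     agbSD = 0, agbMax = 200, plotSpacing = 200,
                     subplotNoisePct = 10, geolocationSD = 0, seed = 9)
  p <- simulatePlots(list(trueAGB = simulateTrueAGB(cfg), slope = NULL), cfg)
  expect_equal(nrow(p), 1e4)
  relErr <- (p$agb_plot - p$agb_true) / p$agb_true
  expect_lt(abs(sd(relErr) - 0.05), 0.003)
})

test_that("LiDAR strips and metrics behave to contract", {
  full <- simulateLidar(list(trueAGB = matrix(50, 20, 20)),
                        tinyConfig(lidarCoverageFraction = 1))
  expect_true(all(full$stripMask))

  # identity metric: a = 1, b = 1, no noise
  agb <- simulateTrueAGB(tinyConfig())
  ident <- simulateLidar(list(trueAGB = agb),
                         tinyConfig(nLidarMetrics = 1, lidarNoiseSD = 0),
                         coefA = 1, coefB = 1)
  on <- ident$stripMask
  expect_equal(ident$lidarMetrics[[1]][on], agb[on], tolerance = 1e-12)
  expect_true(all(is.na(ident$lidarMetrics[[1]][!on])))

  # default-noise metrics still carry signal: r > 0.6 on strips
  sc <- simulateScene(tinyConfig())
  on <- stripMask(sc)
  rs <- vapply(lidarMetrics(sc),
               function(m) cor(m[on], trueAGB(sc)[on]), numeric(1))
  expect_true(all(rs > 0.6))

  expect_error(tinyConfig(nLidarMetrics = 0), "nLidarMetrics")
})

test_that("SAR backscatter follows the saturating curve with speckle", {
  cfg <- tinyConfig()
  # saturation limit: alpha -> infinity gives A + B for any AGB > 0
  cfgSat <- tinyConfig(sarParams = list(
    HH = list(A = -14, B = 6, alpha = 1e6),
    HV = list(A = -22, B = 10, alpha = 1e6), looks = 4))
  lay <- simulateSatellite(list(trueAGB = matrix(30, 10, 10)), cfgSat,
                           speckle = FALSE)
  expect_equal(lay$HV, matrix(-12, 10, 10), tolerance = 1e-6)
  # zero biomass gives the offset A
  lay0 <- simulateSatellite(list(trueAGB = matrix(0, 10, 10)), cfg,
                            speckle = FALSE)
  expect_equal(lay0$HV, matrix(-22, 10, 10), tolerance = 1e-9)

  # speckle-free linear power is strictly increasing and bounded by A + B
  ramp <- matrix(seq(0, 200, length.out = 100), 10, 10)
  layR <- simulateSatellite(list(trueAGB = ramp), cfg, speckle = FALSE)
  hvPow <- dbToPower(layR$HV)[order(as.vector(ramp))]
  expect_true(all(diff(hvPow) > 0))
  expect_true(all(hvPow < dbToPower(-22 + 10)))

  # gamma speckle over a constant field: ENL of linear power ~ looks
  cfgC <- SceneConfig(gridRows = 320, gridCols = 320, agbSD = 0, seed = 3)
  layC <- simulateSatellite(list(trueAGB = simulateTrueAGB(cfgC)), cfgC)
  expect_lt(abs(enl(dbToPower(layC$HV)) - 4), 0.1)
  expect_error(tinyConfig(sarParams = list(HH = list(A = -14, B = 6,
                                                     alpha = 0.03),
                                           HV = list(A = -22, B = 10,
                                                     alpha = 0.04),
                                           looks = 0)), "looks")
})

test_that("tree cover is monotone in noiseless AGB and bounded", {
  ramp <- matrix(seq(0, 200, length.out = 400), 20, 20)
  lay <- simulateSatellite(list(trueAGB = ramp), tinyConfig(),
                           speckle = FALSE, opticalNoise = FALSE)
  tc <- lay$tree_cover[order(as.vector(ramp))]
  expect_true(all(diff(tc) > 0))
  expect_true(all(tc >= 0 & tc <= 100))
  # NDVI layer is consistent with its bands
  expect_equal(lay$ndvi, ndvi(lay$red, lay$nir))
})

test_that("scene validity catches inconsistent layers", {
  sc <- simulateScene(tinyConfig())
  broken <- sc
  broken@predictorLayers$tree_cover[1, 1] <- 150
  expect_error(validObject(broken), "tree_cover")
  broken2 <- sc
  m <- broken2@lidarMetrics[[1]]  # put data off-strip
  m[which(!broken2@stripMask)[1]] <- 1
  broken2@lidarMetrics[[1]] <- m
  expect_error(validObject(broken2), "outside the strip")
})

test_that("scene directory round-trip preserves every layer", {
  sc <- simulateScene(tinyConfig(gridRows = 25, gridCols = 25))
  dir <- file.path(tempdir(), "scene-roundtrip")
  writeScene(sc, dir)
  back <- readScene(dir)
  expect_equal(trueAGB(back), trueAGB(sc), tolerance = 1e-8)
  expect_equal(names(predictorLayers(back)), names(predictorLayers(sc)))
  expect_equal(predictorLayers(back)$HV, predictorLayers(sc)$HV,
               tolerance = 1e-8)
  expect_identical(stripMask(back), stripMask(sc))
  expect_equal(back@plots$agb_plot, sc@plots$agb_plot, tolerance = 1e-8)
  expect_equal(sceneConfig(back)@agbMean, sceneConfig(sc)@agbMean)
  unlink(dir, recursive = TRUE)
})
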