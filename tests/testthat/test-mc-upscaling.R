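test_that("residual screening keeps the expected normal mass", {
  expect_true(all(residualOutlierMask(rep(5, 10), rep(5, 10))))

  set.seed(1)
  r <- rnorm(1e5)
  keep <- residualOutlierMask(r, rep(0, 1e5), k = 2)
  expect_lt(abs(mean(keep) - 0.9545), 0.003)

  # a single gross outlier among perfect fits is exactly what goes
  obs <- c(rep(10, 99), 60)
  pred <- rep(10, 100)
  keep1 <- residualOutlierMask(obs, pred, k = 2)
  expect_identical(which(!keep1), 100L)
  expect_error(residualOutlierMask(1:5, 1:4), "length")
})

test_that("CI95 half-width matches quantile oracles", {
  # constant ensemble
  const <- matrix(5, 10, 4)     # 10 realizations x 4 pixels
  expect_equal(ci95(const), rep(0, 4))

  # two-point ensemble: half the gap
  two <- matrix(rep(c(10, 30), each = 50), ncol = 1)
  expect_equal(ci95(two), 10)

  # normal ensemble at n = 1e4: 1.96 sigma within 3%
  set.seed(2)
  m <- matrix(rnorm(1e4 * 20, 100, 10), nrow = 1e4)
  hw <- ci95(m)
  expect_lt(abs(mean(hw) - qnorm(0.975) * 10) / (qnorm(0.975) * 10), 0.01)
  expect_true(all(abs(hw - qnorm(0.975) * 10) / (qnorm(0.975) * 10) < 0.05))
  expect_error(ci95(matrix(1, 1, 3)), "realizations")
})

test_that("ensemble summaries are permutation- and scale-invariant", {
  set.seed(3)
  arr <- array(rgamma(10 * 10 * 40, 4, 1 / 20), c(10, 10, 40))
  stack <- new("PredictionStack", values = arr, provenance = list())
  perm <- new("PredictionStack", values = arr[, , sample(40)],
              provenance = list())
  expect_equal(ci95(stack), ci95(perm))
  expect_equal(relativeUncertainty(stack)@relUncertainty,
               relativeUncertainty(perm)@relUncertainty)

  scaled <- new("PredictionStack", values = arr * 3, provenance = list())
  expect_equal(relativeUncertainty(stack, meanGuard = 0.1)@relUncertainty,
               relativeUncertainty(scaled, meanGuard = 0.1)@relUncertainty,
               tolerance = 1e-12)
})

test_that("relative uncertainty implements the CI95/mean ratio with guard", {
  const <- matrix(50, 20, 3)
  s <- relativeUncertainty(const)
  expect_equal(uncertaintySurface(s), matrix(0, 3, 1))

  # N(100, 17): 100 * 1.96 * 17 / 100 = 33.3
  set.seed(4)
  m <- matrix(rnorm(1e4 * 10, 100, 17), nrow = 1e4)
  s2 <- relativeUncertainty(m)
  expect_true(all(abs(uncertaintySurface(s2) - 33.3) < 1.5))

  # sub-guard means are nodata
  tiny <- matrix(rnorm(100, 0.5, 0.05), 100, 1)
  s3 <- relativeUncertainty(cbind(tiny, matrix(rnorm(100 * 1, 50, 5), 100)),
                            meanGuard = 1)
  expect_true(is.na(uncertaintySurface(s3)[1, 1]))
  expect_false(is.na(uncertaintySurface(s3)[2, 1]))
})

test_that("uncertainty screen and forest mask use strict thresholds", {
  rel <- matrix(c(10, 50, 90, NA), 2, 2)
  surf <- new("UncertaintySurface", meanAGB = matrix(50, 2, 2),
              ci95Halfwidth = matrix(1, 2, 2), relUncertainty = rel)
  keep <- uncertaintyScreen(surf, 50)
  expect_identical(as.vector(keep), c(TRUE, FALSE, FALSE, FALSE))
  expect_true(all(uncertaintyScreen(matrix(0, 3, 3))))

  expect_identical(forestMask(matrix(c(10, 10.1, 0, 99), 2, 2)),
                   matrix(c(FALSE, TRUE, FALSE, TRUE), 2, 2))
  expect_false(any(forestMask(matrix(0, 3, 3))))
  expect_error(forestMask(matrix(120, 2, 2)), "0, 100")
})

test_that("carbon totals apply area and conversion factor", {
  expect_equal(totalCarbon(matrix(100, 1, 1)), 48)
  expect_equal(totalCarbon(matrix(NA_real_, 3, 3)), 0)
  expect_equal(totalCarbon(matrix(c(50, 150), 1, 2)), 96)
  expect_equal(totalCarbon(matrix(100, 1, 1), pixelArea = 0.25), 12)
  expect_error(totalCarbon(matrix(1, 1, 1), factor = 0), "factor")
})

test_that("Monte-Carlo fit-predict propagates (only) response noise", {
  # zero field error + deterministic learner: all maps identical
  base <- seq(10, 150, length.out = 60)
  rs0 <- generateRealizations(base, 0, n = 4, masterSeed = 1)
  X <- cbind(hv = base + 0)
  target <- cbind(hv = seq(10, 150, length.out = 25))
  st <- mcFitPredict(rs0, X, target, dims = c(5, 5))
  v <- stackValues(st)
  for (r in 2:4) expect_equal(v[, , r], v[, , 1], tolerance = 1e-12)

  # identity setup: single predictor equal to the response recovers it
  expect_equal(as.vector(v[, , 1]), as.vector(target), tolerance = 1e-6)

  # with field error the ensemble must spread
  rs <- generateRealizations(base, 17, n = 10, masterSeed = 2)
  st2 <- mcFitPredict(rs, X, target, dims = c(5, 5))
  expect_true(all(apply(matrix(stackValues(st2), 25, 10), 1, sd) > 0))

  # rows with missing predictors are dropped with a message
  Xna <- X; Xna[3, 1] <- NA
  expect_message(mcFitPredict(rs0, Xna, target, dims = c(5, 5)),
                 "dropped")
  expect_error(mcFitPredict(matrix(base, nrow = 1), X, target,
                            dims = c(5, 5)), "realizations")
})

test_that("a zero-noise scene yields zero propagated uncertainty", {
  cfg <- noiselessConfig(gridRows = 50, gridCols = 50, plotSpacing = 300,
                         seed = 4)
  sc <- simulateScene(cfg)
  for (scen in c("nfi_direct", "lidar_two_stage")) {
    res <- runScenario(sc, scen, n = 4, epsField = 0, seed = 1)
    rel <- uncertaintySurface(res$surface)
    expect_lt(max(rel[is.finite(rel)]), 1e-8)
  }
})

test_that("scenario bookkeeping: slope exclusion and filter counts", {
  sc <- simulateScene(tinyConfig(seed = 2))
  res <- runScenario(sc, "nfi_direct", n = 4, seed = 1)
  rep <- res$report
  p <- scenePlots(sc)
  expect_equal(rep$n_plots_total, nrow(p))
  expect_equal(rep$n_plots_after_slope, sum(p$slope_deg <= 15))
  expect_lt(rep$n_plots_after_slope, rep$n_plots_total)
  expect_equal(rep$n_calibration_plots + rep$n_validation_plots,
               rep$n_plots_after_slope)
  expect_equal(rep$n_forest_pixels,
               sum(forestMask(predictorLayers(sc)$tree_cover)))
  # final surface is forest-masked
  expect_true(all(is.na(
    meanSurface(res$surface)[!forestMask(predictorLayers(sc)$tree_cover)])))

  res2 <- runScenario(sc, "lidar_two_stage", n = 4, seed = 1)
  rep2 <- res2$report
  expect_lte(rep2$n_plots_on_strips, rep2$n_plots_after_slope)
  expect_equal(rep2$n_plots_stage1 + rep2$n_plots_outlier_excluded,
               rep2$n_plots_on_strips)
  expect_equal(rep2$n_strip_pixels, sum(stripMask(sc)))

  res3 <- runScenario(sc, "lidar_two_stage_screened", n = 4, seed = 1)
  expect_lte(res3$report$n_strip_pixels_screened,
             res3$report$n_strip_pixels)

  dir <- file.path(tempdir(), "scenario-out")
  writeScenario(res, dir)
  expect_true(file.exists(file.path(dir, "agb_mean.tsv")))
  repBack <- jsonlite::read_json(file.path(dir, "report.json"))
  expect_equal(repBack$scenario, "nfi_direct")
  unlink(dir, recursive = TRUE)
})
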