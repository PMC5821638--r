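# Small scene configurations used across test files; built in code so the
# suite carries no binary fixtures.

tinyConfig <- function(...) {
  args <- list(gridRows = 60, gridCols = 60, plotSpacing = 500,
               lidarStripWidth = 6, lidarCoverageFraction = 0.3,
               seed = 11)
  args[names(list(...))] <- list(...)
  do.call(SceneConfig, args)
}

# noise-free variant: constant field, no jitter, no measurement noise
noiselessConfig <- function(...) {
  tinyConfig(subplotNoisePct = 0, geolocationSD = 0, lidarNoiseSD = 0, ...)
}

stackFromMatrix <- function(m, nrowPx = nrow(m)) {
  # realizations in rows -> PredictionStack with npix x 1 grid
  new("PredictionStack",
      values = array(t(m), c(ncol(m), 1L, nrow(m))),
      provenance = list(scenario = "test"))
}
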