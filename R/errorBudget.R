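#' @include AllClasses.R
NULL

#' Sampling intensity of a sub-plot network
#'
#' Fraction of a reference area covered by the measured sub-plots, in
#' percent. With 160 sub-plots of 0.04 ha in a 50 ha reference stand this is
#' 12.8%: the intensity at which stand AGB is known to about +/- 10%.
#'
#' @param nPlots number of sub-plots measured.
#' @param subplotArea area of one sub-plot (ha).
#' @param referenceArea reference area (ha).
#' @return Sampling intensity in percent.
#' @export
#' @examples
#' samplingIntensity(160, 0.04, 50)  # 12.8
samplingIntensity <- function(nPlots, subplotArea, referenceArea) {
  stopifnot(nPlots >= 0, subplotArea > 0)
  if (!is.finite(referenceArea) || referenceArea <= 0)
    stop("'referenceArea' must be positive")
  100 * nPlots * subplotArea / referenceArea
}

#' Sub-plots required to reach a sampling intensity in a pixel
#'
#' Transfers a sampling intensity to a (typically 1 ha) map pixel: the
#' fractional number of sub-plots that would realise that intensity there.
#'
#' @param intensity sampling intensity (%).
#' @param pixelArea pixel area (ha); default 1.
#' @param subplotArea area of one sub-plot (ha); default 0.04.
#' @return Fractional sub-plot count.
#' @export
#' @examples
#' requiredSubplots(12.8)  # 3.2
requiredSubplots <- function(intensity, pixelArea = 1, subplotArea = 0.04) {
  stopifnot(intensity > 0, pixelArea > 0)
  if (!is.finite(subplotArea) || subplotArea <= 0)
    stop("'subplotArea' must be positive")
  (intensity / 100) * pixelArea / subplotArea
}

#' Sampling error of plot-level AGB
#'
#' Scales a base relative uncertainty by the square root of the ratio of
#' required to actually measured sub-plots: with 4 sub-plots where 3.2 would
#' give 10%, the sampling error is 10 * sqrt(3.2/4) = 8.9%.
#'
#' @param baseUncertainty relative uncertainty at the required count (%).
#' @param required required (possibly fractional) sub-plot count.
#' @param sampled sub-plots actually measured.
#' @return Sampling error in percent.
#' @export
#' @examples
#' samplingError(10, 3.2, 4)  # 8.944
samplingError <- function(baseUncertainty = 10, required, sampled = 4) {
  stopifnot(baseUncertainty >= 0, required > 0)
  if (!is.finite(sampled) || sampled <= 0)
    stop("'sampled' must be positive")
  baseUncertainty * sqrt(required / sampled)
}

#' Combine independent relative errors in quadrature
#'
#' Root sum of squares of independent, random relative error components.
#'
#' @param components numeric vector of error components (%), all \code{>= 0}.
#' @return Composed error in percent.
#' @export
#' @examples
#' composeError(c(10, 11, 8.9))  # 17.28 ("around 17")
#' composeError(c(3, 4))         # 5
composeError <- function(components) {
  if (length(components) == 0L) return(0)
  if (any(!is.finite(components)) || any(components < 0))
    stop("error components must be finite and >= 0")
  sqrt(sum(components^2))
}

#' Build the field-AGB error budget
#'
#' Combines the measurement, allometric-model and sampling components of the
#' relative error of field-estimated plot AGB. If \code{samplingPct} is not
#' given it is derived from the sub-plot design: a reference stand sampled at
#' known intensity fixes the intensity needed for
#' \code{baseUncertainty}-level precision, which is transferred to one pixel
#' and compared with the sub-plots actually measured.
#'
#' With all defaults the budget reproduces the canonical chain: intensity
#' 12.8%, 3.2 required sub-plots, sampling error 8.9%, total about 17%.
#'
#' @param measurementPct stand-level tree-measurement error (%); default 10.
#' @param allometryPct allometric-model error (%); default 11.
#' @param samplingPct sampling error (%); derived if \code{NULL}.
#' @param baseUncertainty,referencePlots,referenceArea,subplotArea,pixelArea,
#'   sampledSubplots parameters of the sampling-error derivation.
#' @return An \code{\linkS4class{ErrorBudget}}.
#' @export
#' @examples
#' errorBudget()  # total approximately 17.3%
errorBudget <- function(measurementPct = 10, allometryPct = 11,
                        samplingPct = NULL, baseUncertainty = 10,
                        referencePlots = 160, referenceArea = 50,
                        subplotArea = 0.04, pixelArea = 1,
                        sampledSubplots = 4) {
  if (is.null(samplingPct)) {
    intensity <- samplingIntensity(referencePlots, subplotArea, referenceArea)
    required <- requiredSubplots(intensity, pixelArea, subplotArea)
    samplingPct <- samplingError(baseUncertainty, required, sampledSubplots)
  }
  new("ErrorBudget", measurementPct = measurementPct,
      allometryPct = allometryPct, samplingPct = samplingPct,
      totalPct = composeError(c(measurementPct, allometryPct, samplingPct)))
}

#' @rdname accessors
#' @param object an \code{ErrorBudget}.
#' @export
totalErrorPct <- function(object) {
  stopifnot(is(object, "ErrorBudget"))
  object@totalPct
}

#' Generate Monte-Carlo realizations of field-estimated AGB
#'
#' Realization \code{r} of reference value \code{base[k]} is
#' \code{base[k] * (1 + eps/100 * X)} with \code{X ~ N(0, 1)} drawn
#' independently per cell, then clipped at zero. Each row is drawn from its
#' own counter-derived seed, so realization \code{r} is reproducible without
#' generating the first \code{r - 1} rows.
#'
#' @param base reference AGB vector (t/ha), all \code{>= 0}.
#' @param epsField relative field error (%); an
#'   \code{\linkS4class{ErrorBudget}} may be passed and its total is used.
#' @param n number of realizations; default 100.
#' @param masterSeed integer master seed.
#' @return A \code{\linkS4class{RealizationSet}}.
#' @export
#' @examples
#' rs <- generateRealizations(c(50, 100), errorBudget(), n = 10, masterSeed = 1)
#' realizationValues(rs)
generateRealizations <- function(base, epsField, n = 100, masterSeed = 1L) {
  if (is(epsField, "ErrorBudget")) epsField <- epsField@totalPct
  stopifnot(is.numeric(base), n >= 1)
  if (any(!is.finite(base)) || any(base < 0))
    stop("'base' must be finite and >= 0")
  if (!is.finite(epsField) || epsField < 0)
    stop("'epsField' must be >= 0")
  m <- length(base)
  values <- matrix(0, nrow = n, ncol = m)
  eps <- epsField / 100
  for (r in seq_len(n)) {
    x <- withSeed(deriveSeed(masterSeed, paste0("realization:", r)), rnorm(m))
    values[r, ] <- pmax(0, base * (1 + eps * x))
  }
  new("RealizationSet", values = values, base = as.numeric(base),
      epsFieldPct = epsField, masterSeed = as.integer(masterSeed))
}

#' Write / read a realization set as plain text
#'
#' The table is a long-format CSV (\code{realization}, \code{index},
#' \code{agb}) with a YAML sidecar holding the error and seed metadata.
#'
#' @param object a \code{\linkS4class{RealizationSet}}.
#' @param path CSV path; the sidecar is \code{<path>.yaml}.
#' @return \code{writeRealizations} returns \code{path} invisibly;
#'   \code{readRealizations} returns a \code{RealizationSet}.
#' @export
writeRealizations <- function(object, path) {
  stopifnot(is(object, "RealizationSet"))
  v <- object@values
  long <- data.frame(
    realization = rep(seq_len(nrow(v)), times = ncol(v)),
    index = rep(seq_len(ncol(v)), each = nrow(v)),
    agb = as.vector(v))
  utils::write.csv(long, path, row.names = FALSE)
  yaml::write_yaml(list(eps_field_pct = object@epsFieldPct,
                        master_seed = object@masterSeed,
                        base = as.numeric(object@base)),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname writeRealizations
#' @export
readRealizations <- function(path) {
  long <- utils::read.csv(path)
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  n <- max(long$realization)
  m <- max(long$index)
  v <- matrix(NA_real_, n, m)
  v[cbind(long$realization, long$index)] <- long$agb
  new("RealizationSet", values = v, base = as.numeric(meta$base),
      epsFieldPct = meta$eps_field_pct,
      masterSeed = as.integer(meta$master_seed))
}
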