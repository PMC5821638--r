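#' @importFrom stats rnorm rgamma runif sd var cor quantile fft predict
#' @importFrom methods new validObject is slot slotNames
NULL

#' Derive a reproducible child seed from a master seed and a component name
#'
#' Child seeds are a stable polynomial hash of the component name folded into
#' the master seed, so adding a new layer to a scene never shifts the random
#' draws of existing layers, and individual Monte-Carlo realizations can be
#' regenerated in isolation.
#'
#' @param masterSeed integer master seed.
#' @param component character scalar naming the consumer (e.g. "true_agb",
#'   "realization:7").
#' @return A single integer in \code{[1, 2^31 - 2]}.
#' @export
#' @examples
#' deriveSeed(42L, "true_agb")
deriveSeed <- function(masterSeed, component) {
  stopifnot(length(masterSeed) == 1L, is.finite(masterSeed),
            is.character(component), length(component) == 1L)
  m <- 2147483647  # 2^31 - 1, Mersenne prime
  h <- as.double(masterSeed) %% m
  for (code in utf8ToInt(component)) {
    h <- (h * 31 + code) %% m
  }
  as.integer(h %% (m - 1) + 1)
}

## Evaluate expr with a private RNG state; the caller's .Random.seed is
## untouched.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

## FFT frequencies in cycles per sample (numpy fftfreq convention).
fftFreq <- function(n) {
  k <- 0:(n - 1)
  k[k > n / 2] <- k[k > n / 2] - n
  k / n
}

#' Simulate a stationary Gaussian random field by spectral synthesis
#'
#' White noise is filtered in the Fourier domain with the amplitude spectrum
#' of a 2-D exponential covariance, \eqn{S(k) \propto (1 + (2\pi k L)^2)^{-3/2}},
#' giving an approximately exponential correlation with e-folding length
#' \code{correlationLength} (in pixels). The field is standardized to mean 0,
#' SD 1.
#'
#' @param nrow,ncol raster dimensions in pixels.
#' @param correlationLength correlation length in pixels; must be positive.
#' @param seed integer seed; the same seed gives a bit-identical field.
#' @return A \code{nrow x ncol} numeric matrix.
#' @export
gaussianRandomField <- function(nrow, ncol, correlationLength, seed) {
  stopifnot(nrow >= 1, ncol >= 1)
  if (!is.finite(correlationLength) || correlationLength <= 0) {
    stop("'correlationLength' must be positive")
  }
  w <- withSeed(seed, matrix(rnorm(nrow * ncol), nrow, ncol))
  if (nrow == 1L && ncol == 1L) return(w)
  ky <- fftFreq(nrow)
  kx <- fftFreq(ncol)
  k2 <- outer((2 * pi * ky)^2, rep(1, ncol)) +
        outer(rep(1, nrow), (2 * pi * kx)^2)
  amp <- (1 + k2 * correlationLength^2)^(-0.75)
  f <- Re(fft(fft(w) * amp, inverse = TRUE)) / (nrow * ncol)
  s <- sd(as.vector(f))
  if (s == 0) return(matrix(0, nrow, ncol))
  (f - mean(f)) / s
}

## Pixel-center coordinate helpers for the planar scene grid (row 1 at y = 0).
colToX <- function(col, pixelSize) (col - 0.5) * pixelSize
rowToY <- function(row, pixelSize) (row - 0.5) * pixelSize
xToCol <- function(x, pixelSize) pmax(1L, as.integer(ceiling(x / pixelSize)))
yToRow <- function(y, pixelSize) pmax(1L, as.integer(ceiling(y / pixelSize)))
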