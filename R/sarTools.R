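#' @include AllClasses.R
NULL

#' Convert between SAR linear power and decibels
#'
#' \code{powerToDb} floors at -50 dB so zero power stays finite.
#'
#' @param db,power numeric vectors/matrices.
#' @return Converted values.
#' @export
dbToPower <- function(db) 10^(db / 10)

#' @rdname dbToPower
#' @export
powerToDb <- function(power) {
  out <- suppressWarnings(10 * log10(power))
  out[!is.finite(out) | out < -50] <- -50
  out
}

## Local box mean with mirror-padded edges via a summed-area table.
boxMean <- function(m, window) {
  half <- (window - 1L) %/% 2L
  nr <- nrow(m); nc <- ncol(m)
  if (half == 0L) return(m)
  ri <- c(rev(seq_len(min(half, nr))), seq_len(nr),
          rev(seq_len(nr))[seq_len(min(half, nr))])
  ci <- c(rev(seq_len(min(half, nc))), seq_len(nc),
          rev(seq_len(nc))[seq_len(min(half, nc))])
  p <- m[ri, ci, drop = FALSE]
  # summed-area table with zero border
  S <- matrix(0, nrow(p) + 1L, ncol(p) + 1L)
  S[-1, -1] <- t(apply(apply(p, 2, cumsum), 1, cumsum))
  r0 <- seq_len(nr); c0 <- seq_len(nc)
  # window sum of block [r0, r0 + window - 1] x [c0, c0 + window - 1]
  tot <- S[r0 + window, c0 + window, drop = FALSE] -
    S[r0 + window, c0, drop = FALSE] -
    S[r0, c0 + window, drop = FALSE] +
    S[r0, c0, drop = FALSE]
  tot / (window * window)
}

#' Multi-temporal speckle filter for co-registered SAR images
#'
#' For \code{M} co-registered linear-power images the filtered image
#' \code{k} is \code{J_k(x) = (mean_w I_k(x) / M) * sum_i I_i(x) / mean_w
#' I_i(x)}, where \code{mean_w} is the local mean over a square window with
#' edge-mirrored padding. Averaging the normalized channels trades the
#' (assumed uncorrelated) temporal speckle fluctuations against each other
#' while preserving each date's local radiometry; with one image the
#' formula collapses to the identity. Pixels where any local mean is
#' non-positive pass through unfiltered.
#'
#' @param stack list of linear-power matrices on one grid (or a single
#'   matrix).
#' @param window odd window edge length in pixels; default 7.
#' @return List of filtered matrices (same shape as the input).
#' @export
queganFilter <- function(stack, window = 7L) {
  if (is.matrix(stack)) stack <- list(stack)
  stopifnot(length(stack) >= 1)
  if (window %% 2L != 1L || window < 1L) stop("'window' must be odd")
  d <- dim(stack[[1]])
  for (img in stack) {
    if (!identical(dim(img), d)) stop("all images must share one grid")
    if (any(img < 0, na.rm = TRUE)) stop("linear power must be >= 0")
  }
  M <- length(stack)
  means <- lapply(stack, boxMean, window = window)
  bad <- Reduce(`|`, lapply(means, function(mu) !is.finite(mu) | mu <= 0))
  ratioSum <- matrix(0, d[1], d[2])
  for (i in seq_len(M)) {
    ratio <- stack[[i]] / means[[i]]
    ratio[bad] <- 0
    ratioSum <- ratioSum + ratio
  }
  out <- vector("list", M)
  names(out) <- names(stack)
  for (k in seq_len(M)) {
    Jk <- means[[k]] / M * ratioSum
    Jk[bad] <- stack[[k]][bad]   # pass-through where a local mean is degenerate
    out[[k]] <- Jk
  }
  out
}

#' Equivalent number of looks of a homogeneous linear-power sample
#'
#' \code{ENL = mean^2 / variance}; for fully developed L-look gamma speckle
#' over a constant target this estimates L, so larger values mean weaker
#' speckle.
#'
#' @param values numeric vector (or matrix) of linear-power values over a
#'   homogeneous region; non-finite values are dropped.
#' @return ENL (dimensionless).
#' @export
#' @examples
#' set.seed(1); enl(rgamma(1e5, shape = 4, rate = 4))  # about 4
enl <- function(values) {
  v <- as.vector(values)
  v <- v[is.finite(v)]
  if (length(v) < 2L) stop("need at least 2 finite values")
  s2 <- var(v)
  if (s2 <= 0) stop("ENL undefined: zero variance")
  mean(v)^2 / s2
}

#' Normalized difference vegetation index
#'
#' \code{(nir - red) / (nir + red)}; \code{NA} where both bands are zero,
#' and \code{NA} inputs propagate.
#'
#' @param red,nir reflectance matrices/vectors, \code{>= 0}.
#' @return NDVI in \code{[-1, 1]}.
#' @export
ndvi <- function(red, nir) {
  if (any(red < 0, na.rm = TRUE) || any(nir < 0, na.rm = TRUE))
    stop("reflectances must be >= 0")
  out <- (nir - red) / (nir + red)
  out[!is.na(red) & !is.na(nir) & red == 0 & nir == 0] <- NA_real_
  out
}

#' Aggregate a raster to coarser blocks
#'
#' \code{method = "mean"} block-averages (continuous layers); trailing
#' partial blocks are averaged over their available cells. \code{method =
#' "nearest"} keeps the top-left pixel of every block (categorical layers).
#'
#' @param raster numeric matrix.
#' @param factor block edge length in input pixels.
#' @param method \code{"mean"} or \code{"nearest"}.
#' @return Aggregated matrix of dimension \code{ceiling(dim / factor)}.
#' @export
#' @examples
#' blockAggregate(matrix(1:4, 2, 2), 2)  # 2.5
blockAggregate <- function(raster, factor, method = c("mean", "nearest")) {
  method <- match.arg(method)
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L) stop("'factor' must be >= 1")
  if (factor == 1L) return(raster)
  nr <- nrow(raster); nc <- ncol(raster)
  outR <- as.integer(ceiling(nr / factor))
  outC <- as.integer(ceiling(nc / factor))
  if (method == "nearest") {
    return(raster[seq(1L, nr, by = factor), seq(1L, nc, by = factor),
                  drop = FALSE])
  }
  # pad to full blocks with NA, then average each block over available cells
  p <- matrix(NA_real_, outR * factor, outC * factor)
  p[seq_len(nr), seq_len(nc)] <- raster
  a <- array(p, c(factor, outR, factor, outC))
  sums <- colSums(aperm(a, c(1, 3, 2, 4)), dims = 2, na.rm = TRUE)
  counts <- colSums(!is.na(aperm(a, c(1, 3, 2, 4))), dims = 2)
  out <- sums / counts
  out[counts == 0] <- NA_real_
  out
}
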