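#' @include AllClasses.R
NULL

## Smoothing constant of the leaf-to-root blend (Quinlan's k).
.SMOOTH_K <- 15

## Least-squares fit with intercept; aliased columns get coefficient 0 so a
## node model is always defined, also under rank deficiency.
fitNodeLM <- function(X, y) {
  Z <- cbind(1, X)
  fit <- stats::lm.fit(Z, y)
  beta <- fit$coefficients
  beta[!is.finite(beta)] <- 0
  res <- y - as.vector(Z %*% beta)
  list(coef = unname(beta), sse = sum(res^2),
       npar = sum(beta != 0))
}

## Best SD-reduction (equivalently SSE-minimizing) binary split.
## Ties broken by lowest predictor index, then lowest threshold: predictors
## are scanned in index order and thresholds in increasing order, and only
## strict improvements are kept.
findBestSplit <- function(X, y, minLeafSize) {
  n <- length(y)
  if (n < 2 * minLeafSize) return(NULL)
  T1 <- sum(y); T2 <- sum(y^2)
  parentSSE <- T2 - T1^2 / n
  best <- NULL
  bestSSE <- parentSSE * (1 - 1e-10)
  for (j in seq_len(ncol(X))) {
    o <- order(X[, j])
    xs <- X[o, j]
    ys <- y[o]
    S1 <- cumsum(ys); S2 <- cumsum(ys^2)
    i <- seq(minLeafSize, n - minLeafSize)
    valid <- xs[i] < xs[i + 1]
    if (!any(valid)) next
    i <- i[valid]
    sseL <- S2[i] - S1[i]^2 / i
    sseR <- (T2 - S2[i]) - (T1 - S1[i])^2 / (n - i)
    tot <- sseL + sseR
    k <- which.min(tot)   # increasing threshold order: first minimum wins
    if (tot[k] < bestSSE) {
      bestSSE <- tot[k]
      best <- list(var = j, threshold = (xs[i[k]] + xs[i[k] + 1]) / 2)
    }
  }
  best
}

growTree <- function(X, y, idx, depth, minLeafSize, maxDepth) {
  n <- length(idx)
  lmFit <- fitNodeLM(X[idx, , drop = FALSE], y[idx])
  node <- list(leaf = TRUE, n = n, coef = lmFit$coef, sse = lmFit$sse,
               npar = lmFit$npar)
  ySD <- sd(y[idx])
  if (depth >= maxDepth || n < 2 * minLeafSize ||
      !is.finite(ySD) || ySD < 1e-10 * (abs(mean(y[idx])) + 1)) {
    return(node)
  }
  split <- findBestSplit(X[idx, , drop = FALSE], y[idx], minLeafSize)
  if (is.null(split)) return(node)
  goLeft <- X[idx, split$var] <= split$threshold
  node$leaf <- FALSE
  node$var <- split$var
  node$threshold <- split$threshold
  node$left <- growTree(X, y, idx[goLeft], depth + 1, minLeafSize, maxDepth)
  node$right <- growTree(X, y, idx[!goLeft], depth + 1, minLeafSize, maxDepth)
  node
}

## M5 pessimistic error estimate: SSE inflated by (n + v)/(n - v).
adjustedError <- function(sse, n, npar) {
  sse * (n + npar) / max(1, n - npar)
}

subtreeError <- function(node) {
  if (node$leaf) return(adjustedError(node$sse, node$n, node$npar))
  subtreeError(node$left) + subtreeError(node$right)
}

## Collapse subtrees whose pessimistic error does not beat the node's own
## linear model.
pruneTree <- function(node) {
  if (node$leaf) return(node)
  node$left <- pruneTree(node$left)
  node$right <- pruneTree(node$right)
  if (adjustedError(node$sse, node$n, node$npar) <= subtreeError(node)) {
    node <- list(leaf = TRUE, n = node$n, coef = node$coef, sse = node$sse,
                 npar = node$npar)
  }
  node
}

countLeaves <- function(node) {
  if (node$leaf) return(1L)
  countLeaves(node$left) + countLeaves(node$right)
}

## Smoothed prediction: each leaf prediction is blended with the linear
## models of all ancestors, child-first: p <- (n_child p_child + k p_node) /
## (n_child + k).
predictNode <- function(node, Z, rows, smoothing) {
  nodePred <- as.vector(Z[rows, , drop = FALSE] %*% node$coef)
  if (node$leaf) return(nodePred)
  out <- numeric(length(rows))
  goLeft <- Z[rows, node$var + 1] <= node$threshold
  for (side in c("left", "right")) {
    sel <- if (side == "left") goLeft else !goLeft
    if (!any(sel)) next
    child <- node[[side]]
    childPred <- predictNode(child, Z, rows[sel], smoothing)
    out[sel] <- if (smoothing) {
      (child$n * childPred + .SMOOTH_K * nodePred[sel]) /
        (child$n + .SMOOTH_K)
    } else childPred
  }
  out
}

#' Fit a rule-based model tree
#'
#' Grows a regression tree by recursive binary splitting on the standard-
#' deviation-reduction criterion, fits a multivariate linear model at every
#' node, prunes subtrees whose pessimistic error does not beat their node's
#' linear model, and (by default) smooths predictions by blending each leaf
#' model with its ancestors' models on the path to the root. This is the
#' rule-with-linear-models regression family used for biomass upscaling:
#' each rule (root-to-leaf path) carries a multivariate linear model, and
#' the final prediction is a smoothed combination, hence less step-like than
#' the raw tree and less extrapolation-prone than a single global model.
#'
#' Committee members beyond the first are fitted on residual-adjusted
#' responses (\code{2 y - prediction of the previous member}) and averaged.
#' Predictions are clamped to the training response range extended by
#' \code{extrapolationCap} times that range.
#'
#' @param X numeric predictor matrix (rows = cases); no missing values.
#' @param y numeric response vector (t/ha in the AGB application).
#' @param minLeafSize minimum cases per leaf; default 8, in line with the
#'   small rule coverage typical of rule-based regression practice. Larger
#'   values (for instance twice the predictor count plus one) give fully
#'   determined leaf models at the price of stiffer fits.
#' @param maxDepth maximum tree depth; default 8.
#' @param smoothing logical; blend leaf predictions with ancestor models
#'   (default \code{TRUE}).
#' @param nCommittees number of committee members; default 1.
#' @param extrapolationCap fraction of the training response range by which
#'   predictions may leave it; default 0.1.
#' @param seed kept in the config echo for provenance; the fit itself is
#'   deterministic.
#' @return A \code{\linkS4class{ModelTree}}.
#' @export
#' @examples
#' x <- matrix(seq(0, 10, length.out = 200), ncol = 1,
#'             dimnames = list(NULL, "x"))
#' fit <- modelTree(x, 2 * x[, 1] + 1)
#' max(abs(predict(fit, x) - (2 * x[, 1] + 1)))  # ~ 0
modelTree <- function(X, y, minLeafSize = NULL, maxDepth = 8,
                      smoothing = TRUE, nCommittees = 1,
                      extrapolationCap = 0.1, seed = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  if (nrow(X) != length(y)) stop("rows of 'X' must match length of 'y'")
  if (anyNA(X) || anyNA(y)) stop("missing values are not allowed")
  if (is.null(minLeafSize)) minLeafSize <- 8
  if (nrow(X) < minLeafSize)
    stop("fewer training rows than 'minLeafSize'")
  stopifnot(nCommittees >= 1, maxDepth >= 0, extrapolationCap >= 0)
  committees <- vector("list", nCommittees)
  Z <- cbind(1, X)
  yc <- y
  pred <- NULL
  for (m in seq_len(nCommittees)) {
    if (m > 1) yc <- 2 * y - pred
    tree <- pruneTree(growTree(X, yc, seq_along(yc), 0L, minLeafSize,
                               maxDepth))
    committees[[m]] <- tree
    if (m < nCommittees)
      pred <- predictNode(tree, Z, seq_along(yc), smoothing)
  }
  new("ModelTree", committees = committees,
      predictorNames = colnames(X) %||% character(),
      yRange = range(y),
      config = list(minLeafSize = minLeafSize, maxDepth = maxDepth,
                    smoothing = smoothing, nCommittees = nCommittees,
                    extrapolationCap = extrapolationCap, seed = seed))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict from a fitted model tree
#'
#' @param object a \code{\linkS4class{ModelTree}}.
#' @param newdata numeric matrix or data.frame with the training columns.
#' @param ... ignored.
#' @return Numeric vector of predictions, clamped to the (extended)
#'   training response range.
#' @export
setMethod("predict", "ModelTree", function(object, newdata, ...) {
  X <- as.matrix(newdata)
  storage.mode(X) <- "double"
  if (length(object@predictorNames)) {
    if (is.null(colnames(X))) {
      if (ncol(X) != length(object@predictorNames))
        stop("'newdata' has ", ncol(X), " columns; model expects ",
             length(object@predictorNames))
    } else if (!identical(colnames(X), object@predictorNames)) {
      stop("'newdata' columns do not match the training predictors")
    }
  }
  Z <- cbind(1, X)
  smoothing <- isTRUE(object@config$smoothing)
  preds <- vapply(object@committees, function(tree)
    predictNode(tree, Z, seq_len(nrow(Z)), smoothing),
    numeric(nrow(Z)))
  out <- if (is.matrix(preds)) rowMeans(preds) else mean(preds)
  cap <- object@config$extrapolationCap * diff(object@yRange)
  pmin(pmax(out, object@yRange[1] - cap), object@yRange[2] + cap)
})

## ---- JSON audit serialization ----

#' Serialize a model tree to a self-describing JSON document
#'
#' Rules (root-to-leaf paths), per-node linear coefficients, training
#' response range and configuration are written out so a fitted model can be
#' audited or rebuilt without the training data.
#'
#' @param model a \code{\linkS4class{ModelTree}}.
#' @param path optional file to write to.
#' @return JSON character scalar (invisibly if \code{path} is given).
#' @export
modelTreeToJSON <- function(model, path = NULL) {
  stopifnot(is(model, "ModelTree"))
  doc <- list(
    type = "model-tree",
    predictors = model@predictorNames,
    y_range = model@yRange,
    config = model@config,
    committees = lapply(model@committees, identity))
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                           null = "null")
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}

restoreNode <- function(node) {
  node$leaf <- isTRUE(node$leaf)
  node$coef <- as.numeric(node$coef)
  node$n <- as.integer(node$n)
  if (!node$leaf) {
    node$var <- as.integer(node$var)
    node$threshold <- as.numeric(node$threshold)
    node$left <- restoreNode(node$left)
    node$right <- restoreNode(node$right)
  }
  node
}

#' @rdname modelTreeToJSON
#' @param json JSON text or file path produced by \code{modelTreeToJSON}.
#' @export
modelTreeFromJSON <- function(json) {
  doc <- jsonlite::fromJSON(json, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE,
                            simplifyMatrix = FALSE)
  cfg <- doc$config
  cfg$seed <- cfg$seed %||% NULL
  new("ModelTree",
      committees = lapply(doc$committees, restoreNode),
      predictorNames = as.character(doc$predictors),
      yRange = as.numeric(doc$y_range),
      config = cfg)
}
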