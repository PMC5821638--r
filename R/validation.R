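#' @include AllClasses.R utils.R
NULL

#' Stratified calibration/validation split by biomass class
#'
#' Plots are binned into \code{nClasses} AGB classes of width
#' \code{classWidth} (last class open-ended); within each class,
#' round-half-up of \code{calFraction} times the class size is drawn at
#' random into calibration and the remainder goes to validation. Defaults
#' mirror the standard inventory design: ten 30 t/ha classes, 67\%
#' calibration.
#'
#' @param plots data.frame with an \code{agb_plot} column, or a numeric
#'   AGB vector.
#' @param classWidth class width (t/ha); default 30.
#' @param nClasses number of classes; default 10.
#' @param calFraction calibration fraction in \code{(0, 1)}; default 0.67.
#' @param seed integer seed; the split is reproducible.
#' @return \code{list(cal, val)} of the same type as \code{plots};
#'   together they partition the input.
#' @export
#' @examples
#' s <- stratifiedSplit(runif(100, 0, 300), seed = 1)
#' lengths(s)
stratifiedSplit <- function(plots, classWidth = 30, nClasses = 10,
                            calFraction = 0.67, seed = 1) {
  stopifnot(classWidth > 0, nClasses >= 1,
            calFraction > 0, calFraction < 1)
  agb <- if (is.data.frame(plots)) plots$agb_plot else as.numeric(plots)
  n <- length(agb)
  take <- function(obj, i) if (is.data.frame(obj))
    obj[i, , drop = FALSE] else obj[i]
  if (n == 0) return(list(cal = take(plots, integer(0)),
                          val = take(plots, integer(0))))
  cls <- pmin(floor(agb / classWidth) + 1L, nClasses)
  calIdx <- withSeed(seed, {
    unlist(lapply(split(seq_len(n), cls), function(idx) {
      nCal <- floor(calFraction * length(idx) + 0.5)  # round half up
      if (nCal == 0) integer(0) else sample(idx, nCal)
    }), use.names = FALSE)
  })
  list(cal = take(plots, sort(calIdx)),
       val = take(plots, setdiff(seq_len(n), calIdx)))
}

#' Goodness-of-fit statistics between observed and predicted AGB
#'
#' @param observed,predicted numeric vectors of equal length (>= 2).
#' @return One-row data.frame: \code{r2} (squared Pearson correlation;
#'   \code{NA} with a warning if either vector has zero variance),
#'   \code{rmse}, \code{bias} (mean predicted minus observed) and \code{n}.
#' @export
#' @examples
#' fitStats(c(0, 10), c(10, 0))  # r2 1, rmse 10, bias 0
fitStats <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 2)
  r2 <- if (sd(observed) == 0 || sd(predicted) == 0) {
    warning("r2 undefined: zero variance")
    NA_real_
  } else cor(observed, predicted)^2
  data.frame(r2 = r2,
             rmse = sqrt(mean((predicted - observed)^2)),
             bias = mean(predicted - observed),
             n = length(observed))
}

## ---- planar polygon helpers (no geometry package in the stack) ----

## Ray-casting point-in-polygon; boundary points count as inside.
pointInPolygon <- function(px, py, poly) {
  nv <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- nv
  for (i in seq_len(nv)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  # count boundary vertices/edges as inside (tolerant containment)
  onEdge <- rep(FALSE, length(px))
  j <- nv
  for (i in seq_len(nv)) {
    len2 <- (poly[i, 1] - poly[j, 1])^2 + (poly[i, 2] - poly[j, 2])^2
    if (len2 > 0) {   # zero-length edges carry no containment information
      d <- abs((poly[i, 1] - poly[j, 1]) * (py - poly[j, 2]) -
               (px - poly[j, 1]) * (poly[i, 2] - poly[j, 2]))
      t <- ((px - poly[j, 1]) * (poly[i, 1] - poly[j, 1]) +
            (py - poly[j, 2]) * (poly[i, 2] - poly[j, 2])) / len2
      onEdge <- onEdge | (d < 1e-9 * sqrt(len2) & t >= 0 & t <= 1)
    }
    j <- i
  }
  inside | onEdge
}

## Remove consecutive (near-)duplicate vertices a clipping pass can emit.
dedupPolygon <- function(poly, tol = 1e-9) {
  if (is.null(poly) || nrow(poly) < 2) return(poly)
  keep <- rep(TRUE, nrow(poly))
  for (i in seq_len(nrow(poly))) {
    j <- if (i == 1) nrow(poly) else i - 1
    if (i > 1 && all(abs(poly[i, ] - poly[j, ]) < tol)) keep[i] <- FALSE
  }
  out <- poly[keep, , drop = FALSE]
  # also drop a trailing vertex equal to the first
  n <- nrow(out)
  if (n > 1 && all(abs(out[n, ] - out[1, ]) < 1e-9)) {
    out <- out[-n, , drop = FALSE]
  }
  out
}

## Sutherland-Hodgman clip of a convex/concave polygon to a rectangle.
clipPolygonRect <- function(poly, xmin, xmax, ymin, ymax) {
  clipEdge <- function(pts, inside, intersect) {
    if (nrow(pts) == 0) return(pts)
    out <- matrix(numeric(0), ncol = 2)
    n <- nrow(pts)
    for (i in seq_len(n)) {
      cur <- pts[i, ]; prv <- pts[if (i == 1) n else i - 1, ]
      curIn <- inside(cur); prvIn <- inside(prv)
      if (curIn) {
        if (!prvIn) out <- rbind(out, intersect(prv, cur))
        out <- rbind(out, cur)
      } else if (prvIn) {
        out <- rbind(out, intersect(prv, cur))
      }
    }
    out
  }
  ix <- function(p, q, val, coord) {
    t <- (val - p[coord]) / (q[coord] - p[coord])
    p + t * (q - p)
  }
  poly <- clipEdge(poly, function(p) p[1] >= xmin,
                   function(p, q) ix(p, q, xmin, 1))
  poly <- clipEdge(poly, function(p) p[1] <= xmax,
                   function(p, q) ix(p, q, xmax, 1))
  poly <- clipEdge(poly, function(p) p[2] >= ymin,
                   function(p, q) ix(p, q, ymin, 2))
  poly <- clipEdge(poly, function(p) p[2] <= ymax,
                   function(p, q) ix(p, q, ymax, 2))
  poly
}

polygonArea <- function(poly) {
  if (is.null(poly) || nrow(poly) < 3) return(0)
  x <- poly[, 1]; y <- poly[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' Hexagonal validation mesh over a bounding box
#'
#' Flat-topped hexagons of the requested cell area tessellate the bounds;
#' cells are clipped at the bounds and empty cells dropped. 650 km2 is the
#' conventional cell size for sub-national biomass validation.
#'
#' @param bounds numeric \code{c(xmin, xmax, ymin, ymax)} in metres.
#' @param hexArea cell area in km2; default 650.
#' @return List of zones: \code{list(id, center, vertices, polygon,
#'   area)} with \code{vertices} the unclipped hexagon and \code{polygon}
#'   the part inside the bounds (m2 area).
#' @export
#' @examples
#' length(hexMesh(c(0, 20000, 0, 20000), hexArea = 650))
hexMesh <- function(bounds, hexArea = 650) {
  stopifnot(length(bounds) == 4)
  xmin <- bounds[1]; xmax <- bounds[2]; ymin <- bounds[3]; ymax <- bounds[4]
  if (!(xmax > xmin) || !(ymax > ymin)) stop("degenerate bounds")
  if (!is.finite(hexArea) || hexArea <= 0) stop("'hexArea' must be > 0")
  areaM2 <- hexArea * 1e6
  s <- sqrt(2 * areaM2 / (3 * sqrt(3)))   # edge length from the area
  dx <- 1.5 * s
  dy <- sqrt(3) * s
  ang <- seq(0, 5) * pi / 3               # flat-topped: vertex at angle 0
  zones <- list()
  id <- 0L
  jRange <- seq(floor((xmin - s) / dx), ceiling((xmax + s) / dx))
  for (j in jRange) {
    cxj <- j * dx
    off <- if (j %% 2 == 0) 0 else dy / 2
    iRange <- seq(floor((ymin - dy - off) / dy), ceiling((ymax + dy) / dy))
    for (i in iRange) {
      cyi <- i * dy + off
      verts <- cbind(cxj + s * cos(ang), cyi + s * sin(ang))
      clipped <- dedupPolygon(clipPolygonRect(verts, xmin, xmax, ymin, ymax))
      if (polygonArea(clipped) <= 1e-9 * areaM2) next  # degenerate sliver
      id <- id + 1L
      zones[[id]] <- list(id = id, center = c(cxj, cyi), vertices = verts,
                          polygon = clipped, area = polygonArea(clipped))
    }
  }
  zones
}

#' Rectangular zones (synthetic "states")
#'
#' @param rects data.frame/matrix with columns \code{xmin, xmax, ymin,
#'   ymax}, one row per zone.
#' @return List of zones in the \code{\link{hexMesh}} format.
#' @export
rectZones <- function(rects) {
  rects <- as.data.frame(rects)
  lapply(seq_len(nrow(rects)), function(i) {
    r <- rects[i, ]
    verts <- cbind(c(r$xmin, r$xmax, r$xmax, r$xmin),
                   c(r$ymin, r$ymin, r$ymax, r$ymax))
    list(id = i, center = c((r$xmin + r$xmax) / 2, (r$ymin + r$ymax) / 2),
         vertices = verts, polygon = verts, area = polygonArea(verts))
  })
}

#' Forest-area-weighted zonal validation of an AGB map
#'
#' For each zone the map mean over the zone's forest pixels and the mean
#' AGB of the in-zone plots are both multiplied by the zone's forest
#' fraction (forest pixels over zone pixels, from the scene's tree-cover
#' mask), and goodness-of-fit statistics are computed over the zone pairs.
#' Zones without plots, without forest, or with an all-\code{NA} map are
#' dropped (reported in the result).
#'
#' @param mapMean AGB raster (matrix, t/ha); \code{NA} is nodata.
#' @param plots data.frame with \code{x}, \code{y}, \code{agb_plot}.
#' @param zones list of zones from \code{\link{hexMesh}} or
#'   \code{\link{rectZones}}.
#' @param forest logical forest mask on the map grid (e.g. from
#'   \code{\link{forestMask}}).
#' @param pixelSize pixel edge (m).
#' @return \code{list(pairs, stats, dropped)}: per-zone data.frame
#'   (\code{zone_id, obs, pred, weight}), \code{\link{fitStats}} over the
#'   pairs (\code{NULL} if fewer than 2 zones remain), and the count of
#'   dropped zones.
#' @export
zonalWeightedValidation <- function(mapMean, plots, zones, forest,
                                    pixelSize) {
  stopifnot(is.matrix(mapMean), identical(dim(mapMean), dim(forest)))
  nr <- nrow(mapMean); nc <- ncol(mapMean)
  pixX <- colToX(col(mapMean), pixelSize)
  pixY <- rowToY(row(mapMean), pixelSize)
  pairs <- data.frame(zone_id = integer(0), obs = numeric(0),
                      pred = numeric(0), weight = numeric(0))
  dropped <- 0L
  for (z in zones) {
    poly <- z$polygon
    bb <- apply(poly, 2, range)
    cand <- which(pixX >= bb[1, 1] & pixX <= bb[2, 1] &
                  pixY >= bb[1, 2] & pixY <= bb[2, 2])
    inZone <- cand[pointInPolygon(pixX[cand], pixY[cand], poly)]
    plotIn <- pointInPolygon(plots$x, plots$y, poly)
    if (length(inZone) == 0 || !any(plotIn)) { dropped <- dropped + 1L; next }
    ff <- mean(forest[inZone])
    if (ff == 0) { dropped <- dropped + 1L; next }
    mapVals <- mapMean[inZone][forest[inZone]]
    mapVals <- mapVals[is.finite(mapVals)]
    if (length(mapVals) == 0) { dropped <- dropped + 1L; next }
    pairs <- rbind(pairs, data.frame(
      zone_id = z$id,
      obs = mean(plots$agb_plot[plotIn]) * ff,
      pred = mean(mapVals) * ff,
      weight = ff))
  }
  stats <- if (nrow(pairs) >= 2) fitStats(pairs$obs, pairs$pred) else NULL
  list(pairs = pairs, stats = stats, dropped = dropped)
}

#' Export zones as GeoJSON
#'
#' Planar coordinates are written as-is (no CRS).
#'
#' @param zones list of zones.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
zonesToGeoJSON <- function(zones, path) {
  features <- lapply(zones, function(z) {
    ring <- rbind(z$polygon, z$polygon[1, , drop = FALSE])
    list(type = "Feature",
         properties = list(id = z$id, area_m2 = z$area),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                           function(i) as.numeric(ring[i, ])))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
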