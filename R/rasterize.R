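## Contour rasterization under the LIDC convention: contours trace the
## pixels just OUTSIDE the region, so the region is the strict interior of
## the polygon through the contour pixel centers, and contour-path pixels
## themselves are never foreground.

.bresenham <- function(x0, y0, x1, y1) {
  dx <- abs(x1 - x0); dy <- abs(y1 - y0)
  sx <- sign(x1 - x0); sy <- sign(y1 - y0)
  n <- max(dx, dy) + 1L
  xs <- integer(n); ys <- integer(n)
  err <- dx - dy
  x <- x0; y <- y0
  for (i in seq_len(n)) {
    xs[i] <- x; ys[i] <- y
    if (x == x1 && y == y1) { xs <- xs[1:i]; ys <- ys[1:i]; break }
    e2 <- 2L * err
    if (e2 > -dy) { err <- err - dy; x <- x + sx }
    if (e2 < dx) { err <- err + dx; y <- y + sy }
  }
  cbind(xs, ys)
}

## all pixels on the closed polygon path (vertices plus the Bresenham
## digitization of each edge, the closing edge included)
.contourPathPixels <- function(pts) {
  n <- nrow(pts)
  segs <- lapply(seq_len(n), function(i) {
    j <- if (i == n) 1L else i + 1L
    .bresenham(pts[i, 1L], pts[i, 2L], pts[j, 1L], pts[j, 2L])
  })
  unique(do.call(rbind, segs))
}

## even-odd (crossing-number) point-in-polygon, vectorized over query points
.pointInPolygonEO <- function(px, py, pts) {
  n <- nrow(pts)
  inside <- rep(FALSE, length(px))
  x1 <- pts[, 1L]; y1 <- pts[, 2L]
  x2 <- pts[c(2:n, 1L), 1L]; y2 <- pts[c(2:n, 1L), 2L]
  for (e in seq_len(n)) {
    if (y1[e] == y2[e]) next  # horizontal edges never cross the test ray
    cross <- ((y1[e] > py) != (y2[e] > py)) &
      (px < x1[e] + (py - y1[e]) * (x2[e] - x1[e]) / (y2[e] - y1[e]))
    inside <- xor(inside, cross)
  }
  inside
}

.isCollinear <- function(pts) {
  p0 <- pts[1L, ]
  d <- sweep(pts[-1L, , drop = FALSE], 2L, p0)
  all(d[, 1L] * d[1L, 2L] - d[, 2L] * d[1L, 1L] == 0L)
}

.selfIntersects <- function(pts) {
  n <- nrow(pts)
  if (n > 400L) return(FALSE)  # skip the O(n^2) check on dense contours
  a1 <- pts; a2 <- pts[c(2:n, 1L), , drop = FALSE]
  for (i in seq_len(n - 2L)) {
    js <- (i + 2L):n
    js <- js[!(i == 1L & js == n)]  # closing edge is adjacent to edge 1
    if (!length(js)) next
    d1 <- (a2[i, 1L] - a1[i, 1L]) * (a1[js, 2L] - a1[i, 2L]) -
          (a2[i, 2L] - a1[i, 2L]) * (a1[js, 1L] - a1[i, 1L])
    d2 <- (a2[i, 1L] - a1[i, 1L]) * (a2[js, 2L] - a1[i, 2L]) -
          (a2[i, 2L] - a1[i, 2L]) * (a2[js, 1L] - a1[i, 1L])
    d3 <- (a2[js, 1L] - a1[js, 1L]) * (a1[i, 2L] - a1[js, 2L]) -
          (a2[js, 2L] - a1[js, 2L]) * (a1[i, 1L] - a1[js, 1L])
    d4 <- (a2[js, 1L] - a1[js, 1L]) * (a2[i, 2L] - a1[js, 2L]) -
          (a2[js, 2L] - a1[js, 2L]) * (a2[i, 1L] - a1[js, 1L])
    if (any(d1 * d2 < 0 & d3 * d4 < 0)) return(TRUE)
  }
  FALSE
}

#' Rasterize one planar contour to its strict interior
#'
#' Returns the pixels strictly interior to the closed polygon through the
#' contour pixel centers.  Pixels on the contour path (the vertices and the
#' digitized segments between consecutive vertices, closure included) are
#' always background, honouring the convention that contour pixels lie just
#' outside the region.  Self-intersecting polygons are filled with the
#' even-odd rule after a warning.
#'
#' @param roi a [ContourRoi-class] with at least 3 points, or an n x 2
#'   matrix of 0-based `(x, y)` pixel indices.
#' @param shape image shape as `(rows, columns)`.
#' @return logical matrix with `dim = c(columns, rows)`, indexed
#'   `[x + 1, y + 1]`.
#' @export
rasterizeRoi <- function(roi, shape) {
  pts <- if (is(roi, "ContourRoi")) roi@points else
    matrix(as.integer(round(as.matrix(roi))), ncol = 2L)
  if (nrow(pts) >= 2L &&
      all(pts[nrow(pts), ] == pts[1L, ])) pts <- pts[-nrow(pts), , drop = FALSE]
  if (nrow(pts) < 3L)
    stop("degenerate contour: fewer than 3 distinct points", call. = FALSE)
  if (.isCollinear(pts))
    stop("degenerate contour: all points are collinear", call. = FALSE)
  rows <- shape[1L]; cols <- shape[2L]
  if (any(pts[, 1L] < 0L | pts[, 1L] >= cols | pts[, 2L] < 0L |
          pts[, 2L] >= rows))
    stop("contour points outside image bounds", call. = FALSE)
  if (.selfIntersects(pts))
    warning("self-intersecting contour; even-odd fill rule applied",
            call. = FALSE)

  mask <- matrix(FALSE, nrow = cols, ncol = rows)
  ## restrict the fill test to the contour bounding box
  xr <- range(pts[, 1L]); yr <- range(pts[, 2L])
  xs <- xr[1L]:xr[2L]; ys <- yr[1L]:yr[2L]
  grid <- expand.grid(x = xs, y = ys)
  inside <- .pointInPolygonEO(grid$x, grid$y, pts)
  mask[cbind(grid$x + 1L, grid$y + 1L)] <- inside
  path <- .contourPathPixels(pts)
  mask[path + 1L] <- FALSE
  mask
}

#' Reconstruct a filled mask volume from an annotation's contours
#'
#' Per slice, the mask is the union of the strict interiors of the included
#' ROIs minus the union of the strict interiors of the excluded ROIs; slices
#' are stacked into a volume aligned to the CT frame of reference.  An
#' excluded ROI on a slice with no included ROI contributes nothing.
#'
#' @param ann a [NoduleAnnotation-class]; every ROI's slice reference must
#'   resolve in `g` (by SOP instance UID, or by z position when the
#'   reference is empty).
#' @param g the series [ScanGeometry-class].
#' @return a [MaskVolume-class]; an annotation whose contours enclose no
#'   pixel at all is an error (a volumetric annotation is expected).
#' @export
buildMask <- function(ann, g) {
  sh <- g@imageShape
  nz <- length(g@slicePositions)
  vol <- array(FALSE, dim = c(sh[2L], sh[1L], nz))
  slices <- vapply(ann@rois, function(r) .resolveSlice(g, r), numeric(1))
  for (k in unique(slices)) {
    here <- ann@rois[slices == k]
    inc <- Reduce(`|`, lapply(Filter(function(r) r@inclusion, here),
                              rasterizeRoi, shape = sh),
                  matrix(FALSE, sh[2L], sh[1L]))
    exc <- Reduce(`|`, lapply(Filter(function(r) !r@inclusion, here),
                              rasterizeRoi, shape = sh),
                  matrix(FALSE, sh[2L], sh[1L]))
    vol[, , k] <- inc & !exc
  }
  ne <- which(apply(vol, 3L, any))
  if (length(ne) == 0L)
    stop("annotation '", ann@annotationId,
         "' produced an empty mask volume", call. = FALSE)
  new("MaskVolume", voxels = vol, geometry = g,
      nonemptySlices = as.integer(ne))
}
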