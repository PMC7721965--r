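## Quantitative nodule measurements: maximal in-plane diameter over
## boundary pixels, mesh surface area from a triangulated isosurface at
## level 0.5, and volume by voxel counting.

.maskSpacing <- function(mask) {
  g <- mask@geometry
  step <- if (length(g@slicePositions) > 1L)
    stats::median(abs(diff(g@slicePositions))) else 1
  c(g@pixelSpacing[2L], g@pixelSpacing[1L], step)  # (dx=col, dy=row, dz)
}

.checkNonEmpty <- function(mask) {
  if (sum(mask@voxels) == 0L) stop("empty mask", call. = FALSE)
}

#' Maximal in-plane nodule diameter
#'
#' The maximum, over slices, of the maximum pairwise patient-space distance
#' between foreground boundary pixel centers on that slice (the LIDC
#' "greatest in-plane dimension" framing).  Restricting to boundary pixels
#' is exact for the maximum and cheaper than all foreground pixels.
#'
#' @param mask a non-empty [MaskVolume-class].
#' @return diameter in mm (0 for a single-voxel mask).  A value above the
#'   30 mm in-scope range raises a warning, not an error.
#' @export
noduleDiameter <- function(mask) {
  .checkNonEmpty(mask)
  sp <- .maskSpacing(mask)
  v <- mask@voxels
  best <- 0
  for (k in mask@nonemptySlices) {
    sl <- v[, , k]
    nx <- dim(sl)[1L]; ny <- dim(sl)[2L]
    ## boundary: foreground with at least one background 4-neighbour
    pad <- matrix(FALSE, nx + 2L, ny + 2L)
    pad[2:(nx + 1L), 2:(ny + 1L)] <- sl
    inner <- pad[1:nx, 2:(ny + 1L)] & pad[3:(nx + 2L), 2:(ny + 1L)] &
             pad[2:(nx + 1L), 1:ny] & pad[2:(nx + 1L), 3:(ny + 2L)]
    bnd <- which(sl & !inner, arr.ind = TRUE)
    if (nrow(bnd) == 0L) bnd <- which(sl, arr.ind = TRUE)
    pts <- cbind((bnd[, 1L] - 1L) * sp[1L], (bnd[, 2L] - 1L) * sp[2L])
    if (nrow(pts) >= 2L) best <- max(best, max(stats::dist(pts)))
  }
  if (best > 30) warning("diameter ", format(best),
                         " mm exceeds the 3-30 mm in-scope range", call. = FALSE)
  best
}

## ---- marching tetrahedra isosurface --------------------------------------

## cube corner offsets, index 0..7 (x, y, z)
.MT_CORNERS <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
                     c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1))
## 6-tetrahedron decomposition of the cube around the 0-6 diagonal
.MT_TETS <- rbind(c(0, 1, 2, 6), c(0, 2, 3, 6), c(0, 3, 7, 6),
                  c(0, 7, 4, 6), c(0, 4, 5, 6), c(0, 5, 1, 6)) + 1L

## triangle area sum for vertex matrices p1, p2, p3 (n x 3 each)
.triArea <- function(p1, p2, p3) {
  u <- p2 - p1; v <- p3 - p1
  cx <- u[, 2L] * v[, 3L] - u[, 3L] * v[, 2L]
  cy <- u[, 3L] * v[, 1L] - u[, 1L] * v[, 3L]
  cz <- u[, 1L] * v[, 2L] - u[, 2L] * v[, 1L]
  0.5 * sum(sqrt(cx^2 + cy^2 + cz^2))
}

## separable 3-point mean filter along every axis (index space)
.boxSmooth3 <- function(V) {
  for (ax in 1:3) {
    d <- dim(V); n <- d[ax]
    slab <- function(i) {
      a <- list(quote(expr = ), quote(expr = ), quote(expr = ))
      a[[ax]] <- pmin(pmax(i, 1L), n)
      do.call(`[`, c(list(V), a))
    }
    V <- (slab(0:(n - 1L)) + slab(1:n) + slab(2:(n + 1L))) / 3
  }
  V
}

#' Surface area of the mesh isosurface of a mask
#'
#' Extracts a triangulated isosurface at iso-level 0.5 from the binary
#' volume by marching tetrahedra (each grid cube split into six tetrahedra,
#' surface vertices linearly interpolated along sign-changing edges) with
#' the voxel spacing applied, and returns the summed triangle area.
#'
#' The binary volume is first regularized with a separable 3-voxel mean
#' filter, clamped so that every foreground voxel stays above and every
#' background voxel below the iso-level: the staircase of the voxelization
#' is relaxed towards the underlying smooth surface (removing the large
#' positive area bias a jagged binary isosurface carries) while the
#' topology and voxel membership of the mask are preserved exactly.
#'
#' @param mask a non-empty [MaskVolume-class].
#' @return surface area in mm^2.
#' @export
meshSurfaceArea <- function(mask) {
  .checkNonEmpty(mask)
  sp <- .maskSpacing(mask)
  v0 <- mask@voxels
  d <- dim(v0)
  ## zero-pad (2 voxels for the smoothing support) to close the surface
  V <- array(0, d + 4L)
  V[3:(d[1] + 2L), 3:(d[2] + 2L), 3:(d[3] + 2L)] <- v0
  S <- .boxSmooth3(V)
  S <- pmax(S, ifelse(V > 0, 0.502, 0))
  S <- pmin(S, ifelse(V > 0, 1, 0.498))
  dim(S) <- dim(V)

  nc <- dim(S) - 1L  # marching cells per axis
  idx <- function(off) {
    S[(1L + off[1]):(nc[1] + off[1]),
      (1L + off[2]):(nc[2] + off[2]),
      (1L + off[3]):(nc[3] + off[3])]
  }
  corner <- lapply(seq_len(8L), function(ci) as.vector(idx(.MT_CORNERS[ci, ])))
  nIn <- Reduce(`+`, lapply(corner, function(cv) cv > 0.5))
  active <- which(nIn > 0 & nIn < 8)
  if (length(active) == 0L) return(0)
  base <- arrayInd(active, nc)
  vals <- lapply(corner, function(cv) cv[active])
  coords <- lapply(seq_len(8L), function(ci)
    sweep(base, 2L, .MT_CORNERS[ci, ] - 1L, `+`) %*% diag(sp))
  interp <- function(a, b, sel) {
    va <- vals[[a]][sel]; vb <- vals[[b]][sel]
    t <- (0.5 - va) / (vb - va)
    coords[[a]][sel, , drop = FALSE] +
      t * (coords[[b]][sel, , drop = FALSE] - coords[[a]][sel, , drop = FALSE])
  }
  area <- 0
  for (t in seq_len(nrow(.MT_TETS))) {
    tc <- .MT_TETS[t, ]
    inside <- cbind(vals[[tc[1]]], vals[[tc[2]]],
                    vals[[tc[3]]], vals[[tc[4]]]) > 0.5
    cnt <- rowSums(inside)
    ## one corner on its own side of the surface -> one triangle
    for (lone in 1:4) {
      sel1 <- which((cnt == 1L & inside[, lone]) |
                    (cnt == 3L & !inside[, lone]))
      if (!length(sel1)) next
      oth <- setdiff(1:4, lone)
      area <- area + .triArea(interp(tc[lone], tc[oth[1]], sel1),
                              interp(tc[lone], tc[oth[2]], sel1),
                              interp(tc[lone], tc[oth[3]], sel1))
    }
    ## two corners inside -> quad split into two triangles
    pairs <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
    for (pi in seq_len(nrow(pairs))) {
      a1 <- pairs[pi, 1]; a2 <- pairs[pi, 2]
      sel2 <- which(cnt == 2L & inside[, a1] & inside[, a2])
      if (!length(sel2)) next
      bs <- setdiff(1:4, c(a1, a2))
      q1 <- interp(tc[a1], tc[bs[1]], sel2)
      q2 <- interp(tc[a1], tc[bs[2]], sel2)
      q3 <- interp(tc[a2], tc[bs[2]], sel2)
      q4 <- interp(tc[a2], tc[bs[1]], sel2)
      area <- area + .triArea(q1, q2, q3) + .triArea(q1, q3, q4)
    }
  }
  area
}

#' Nodule volume by voxel counting
#'
#' Foreground voxel count times the voxel volume (pixel spacing product
#' times slice step).
#'
#' @param mask a non-empty [MaskVolume-class].
#' @return volume in mm^3.
#' @export
noduleVolume <- function(mask) {
  .checkNonEmpty(mask)
  sp <- .maskSpacing(mask)
  sum(mask@voxels) * prod(sp)
}

#' All three coded measurements of a mask
#'
#' @param mask a non-empty [MaskVolume-class].
#' @return named list with `diameter_mm`, `surface_area_mm2`, `volume_mm3`.
#' @export
measureNodule <- function(mask) {
  list(diameter_mm = noduleDiameter(mask),
       surface_area_mm2 = meshSurfaceArea(mask),
       volume_mm3 = noduleVolume(mask))
}
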