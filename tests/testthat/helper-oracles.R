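## Shared fixtures and independent oracles.  Every oracle here uses a
## different algorithm than the implementation it checks.

## minimal axial geometry built directly (no DICOM files involved)
mkGeometry <- function(nSlices = 5L, shape = c(32L, 32L), spacing = c(1, 1),
                       step = 1) {
  uids <- sprintf("1.2.840.99.%d", seq_len(nSlices))
  ctx <- stats::setNames(character(10),
    c("PatientName", "PatientID", "PatientBirthDate", "PatientSex",
      "StudyInstanceUID", "StudyDate", "StudyTime",
      "ReferringPhysicianName", "StudyID", "AccessionNumber"))
  ctx["PatientID"] <- "TEST-0001"
  ctx["StudyInstanceUID"] <- "1.2.840.99.0.1"
  new("ScanGeometry", pixelSpacing = spacing,
      slicePositions = (seq_len(nSlices) - 1) * step,
      sliceOrigins = cbind(0, 0, (seq_len(nSlices) - 1) * step),
      orientation = c(1, 0, 0, 0, 1, 0),
      sliceTable = stats::setNames(seq_len(nSlices), uids),
      imageShape = as.integer(shape),
      seriesUID = "1.2.840.99.0.2", studyUID = "1.2.840.99.0.1",
      frameUID = "1.2.840.99.0.3", context = ctx)
}

## axis-aligned rectangular ring of pixels: the border of the w x h block
## whose top-left pixel is (x0, y0); returned in cyclic order
ringPoints <- function(x0, y0, w, h) {
  xs <- x0:(x0 + w - 1L); ys <- y0:(y0 + h - 1L)
  top <- cbind(xs, y0)
  right <- cbind(x0 + w - 1L, ys[-1L])
  bottom <- cbind(rev(xs[-w]), y0 + h - 1L)
  left <- cbind(x0, rev(ys[-c(1L, h)]))
  rbind(top, right, bottom, left)
}

## independent strict point-in-polygon: winding number by signed-angle
## summation (the implementation uses even-odd crossing counting)
windingInside <- function(px, py, pts) {
  n <- nrow(pts)
  vx <- outer(px, pts[, 1L], function(a, b) b - a)
  vy <- outer(py, pts[, 2L], function(a, b) b - a)
  vx2 <- vx[, c(2:n, 1L), drop = FALSE]; vy2 <- vy[, c(2:n, 1L), drop = FALSE]
  ang <- atan2(vx * vy2 - vy * vx2, vx * vx2 + vy * vy2)
  abs(rowSums(ang)) > pi
}

## brute-force oracle mask: every pixel center strictly inside the polygon
## and not one of the contour pixels themselves
oracleRoiMask <- function(pts, shape) {
  rows <- shape[1L]; cols <- shape[2L]
  grid <- expand.grid(x = 0:(cols - 1L), y = 0:(rows - 1L))
  inside <- windingInside(grid$x, grid$y, pts)
  m <- matrix(FALSE, nrow = cols, ncol = rows)
  m[cbind(grid$x + 1L, grid$y + 1L)] <- inside
  m[pts + 1L] <- FALSE
  m
}

## random digitized blob (union of overlapping discs) and its ordered
## one-pixel exterior ring; vertices are 8-adjacent so the contour path is
## exactly the vertex set
randomBlobRing <- function(shape, rmin = 2, rmax = 5) {
  rows <- shape[1L]; cols <- shape[2L]
  cx <- runif(1, rmax + 3, cols - rmax - 4)
  cy <- runif(1, rmax + 3, rows - rmax - 4)
  xs <- 0:(cols - 1L); ys <- 0:(rows - 1L)
  blob <- matrix(FALSE, cols, rows)
  for (i in seq_len(sample(1:3, 1L))) {
    r <- runif(1, rmin, rmax)
    ox <- cx + runif(1, -2, 2); oy <- cy + runif(1, -2, 2)
    blob <- blob | (outer((xs - ox)^2, (ys - oy)^2, `+`) <= r^2)
  }
  if (!any(blob)) return(NULL)
  ## chebyshev-dilate and take the shell, ordered by angle
  nx <- nrow(blob); ny <- ncol(blob)
  pad <- matrix(FALSE, nx + 2L, ny + 2L)
  pad[2:(nx + 1L), 2:(ny + 1L)] <- blob
  dil <- pad
  for (ox in -1:1) for (oy in -1:1) {
    if (ox == 0L && oy == 0L) next
    dil[2:(nx + 1L), 2:(ny + 1L)] <- dil[2:(nx + 1L), 2:(ny + 1L)] |
      pad[2:(nx + 1L) + ox, 2:(ny + 1L) + oy]
  }
  shell <- dil[2:(nx + 1L), 2:(ny + 1L)] & !blob
  w <- which(shell, arr.ind = TRUE) - 1L
  ctr <- colMeans(which(blob, arr.ind = TRUE) - 1L)
  ord <- order(atan2(w[, 2L] - ctr[2L], w[, 1L] - ctr[1L]),
               (w[, 1L] - ctr[1L])^2 + (w[, 2L] - ctr[2L])^2)
  list(blob = blob, ring = w[ord, , drop = FALSE])
}

## brute-force union-find connected components over a distance matrix
unionFindClusters <- function(D, tol) {
  n <- nrow(D)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && D[i, j] <= tol) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

## single-point annotation at voxel (x, y) on slice k (for distance tests)
pointAnnotation <- function(id, x, y, k, g, session = 1L) {
  noduleAnnotation(id, list(
    contourRoi(cbind(x, y), zPos = g@slicePositions[k],
               sliceRef = names(g@sliceTable)[match(k, g@sliceTable)])),
    sessionIndex = session)
}

## digitized sphere as a MaskVolume on an isotropic unit geometry
sphereMaskFixture <- function(radius, spacing = 1) {
  n <- as.integer(ceiling(2 * radius / spacing) + 9L)
  g <- mkGeometry(nSlices = n, shape = c(n, n),
                  spacing = c(spacing, spacing), step = spacing)
  analyticSphereMask(g, rep((radius + 4 * spacing), 3L), radius)
}

## standard two-nodule phantom used by the end-to-end tests
e2ePhantomSpec <- function(seed = 7L) {
  phantomSpec(
    imageShape = c(96L, 96L), pixelSpacing = c(0.7, 0.7), sliceStep = 2.5,
    nSlices = 20L,
    nodules = list(
      list(center = c(20, 20, 20), radius = 6, nReaders = 3, jitter = 0.4),
      list(center = c(45, 45, 30), radius = 8, nReaders = 3, jitter = 0.4)),
    centerMarks = 1L, seed = seed)
}

pythonValidatorAvailable <- function() {
  nzchar(Sys.which("python")) &&
    system2(Sys.which("python"), c("-c", shQuote("import pydicom")),
            stdout = FALSE, stderr = FALSE) == 0L
}
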