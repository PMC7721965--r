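## Composite-context attributes copied from the source CT into derived
## objects: patient and study identification.
.CONTEXT_TAGS <- c(
  PatientName = "0010,0010", PatientID = "0010,0020",
  PatientBirthDate = "0010,0030", PatientSex = "0010,0040",
  StudyInstanceUID = "0020,000D", StudyDate = "0008,0020",
  StudyTime = "0008,0030", ReferringPhysicianName = "0008,0090",
  StudyID = "0020,0010", AccessionNumber = "0008,0050")

#' Derive the coordinate frame of a CT series
#'
#' Reads the geometry attributes of every slice in a directory, checks that
#' they form a single consistent axial series, and sorts the slices by their
#' patient-space position along the slice normal (never by file name or
#' instance number).
#'
#' Series with mixed series UIDs, inconsistent in-plane spacing or
#' orientation, duplicate slice positions, a non-uniform slice step (beyond
#' `stepTol`), or a non-axial / gantry-tilted orientation are rejected with
#' an explicit error: silent mis-binding of contours to slices is worse
#' than refusal.
#'
#' @param ctDir directory containing one DICOM file per slice.
#' @param stepTol maximum tolerated deviation of any slice step from the
#'   median step, in mm (guards against gaps in the series).
#' @return a [ScanGeometry-class].
#' @export
buildGeometry <- function(ctDir, stepTol = 0.01) {
  files <- list.files(ctDir, full.names = TRUE)
  files <- files[!dir.exists(files)]
  slices <- lapply(files, function(f)
    tryCatch(dcmRead(f), error = function(e) NULL))
  slices <- slices[!vapply(slices, is.null, logical(1))]
  if (length(slices) < 2L)
    stop("need at least 2 readable DICOM slices in '", ctDir, "'")

  seriesUIDs <- vapply(slices, function(s) dcmGet(s, "0020,000E", ""), character(1))
  if (length(unique(seriesUIDs)) != 1L)
    stop("mixed series in directory: ", paste(unique(seriesUIDs), collapse = ", "))

  spAll <- t(vapply(slices, function(s) dcmGet(s, "0028,0030"), numeric(2)))
  if (max(abs(sweep(spAll, 2L, spAll[1L, ]))) > 1e-6)
    stop("inconsistent in-plane pixel spacing across slices")
  spacing <- spAll[1L, ]  # (row, column)

  iopAll <- t(vapply(slices, function(s) dcmGet(s, "0020,0037"), numeric(6)))
  if (max(abs(sweep(iopAll, 2L, iopAll[1L, ]))) > 1e-6)
    stop("inconsistent image orientation across slices")
  iop <- iopAll[1L, ]
  rowdir <- iop[1:3]; coldir <- iop[4:6]
  if (abs(sum(rowdir * coldir)) > 1e-4 ||
      abs(sum(rowdir^2) - 1) > 1e-4 || abs(sum(coldir^2) - 1) > 1e-4)
    stop("image orientation cosines are not orthonormal")
  normal <- c(rowdir[2] * coldir[3] - rowdir[3] * coldir[2],
              rowdir[3] * coldir[1] - rowdir[1] * coldir[3],
              rowdir[1] * coldir[2] - rowdir[2] * coldir[1])
  if (abs(abs(normal[3]) - 1) > 1e-4)
    stop("non-axial or gantry-tilted series; only axial CT is supported")

  ipp <- t(vapply(slices, function(s) dcmGet(s, "0020,0032"), numeric(3)))
  zpos <- as.numeric(ipp %*% normal)
  uids <- vapply(slices, function(s) dcmGet(s, "0008,0018", ""), character(1))

  dup <- duplicated(round(zpos, 6)) | duplicated(round(zpos, 6), fromLast = TRUE)
  if (any(dup))
    stop("duplicate slice position(s) for instance(s): ",
         paste(uids[dup], collapse = ", "))

  ord <- order(zpos)
  zpos <- zpos[ord]; ipp <- ipp[ord, , drop = FALSE]; uids <- uids[ord]
  steps <- diff(zpos)
  if (max(abs(steps - stats::median(steps))) > stepTol)
    stop("non-uniform slice step (possible gap in series); max deviation ",
         format(max(abs(steps - stats::median(steps)))), " mm exceeds stepTol")

  s1 <- slices[[ord[1L]]]
  rows <- as.integer(dcmGet(s1, "0028,0010"))
  cols <- as.integer(dcmGet(s1, "0028,0011"))
  ctx <- vapply(.CONTEXT_TAGS, function(tag) {
    v <- dcmGet(s1, tag, "")
    if (length(v) == 0L) "" else paste(v, collapse = "\\")
  }, character(1))

  new("ScanGeometry",
      pixelSpacing = spacing, slicePositions = zpos, sliceOrigins = ipp,
      orientation = iop, sliceTable = stats::setNames(seq_along(uids), uids),
      imageShape = c(rows, cols),
      seriesUID = seriesUIDs[1L],
      studyUID = dcmGet(s1, "0020,000D", ""),
      frameUID = dcmGet(s1, "0020,0052", ""),
      context = ctx)
}

#' Map voxel indices to patient coordinates
#'
#' The voxel index convention is `(i = column, j = row, k = slice)`, all
#' 0-based.  The mapping is the standard DICOM one:
#' `P = IPP(k) + i * dc * X + j * dr * Y`, where `X`/`Y` are the direction
#' cosines of increasing column/row index and `dc`/`dr` the column/row
#' spacing.
#'
#' @param g a [ScanGeometry-class].
#' @param ijk numeric triple or n x 3 matrix of 0-based voxel indices.
#' @return patient-space coordinates in mm, same shape as the input.
#' @export
voxelToPatient <- function(g, ijk) {
  m <- if (is.matrix(ijk)) ijk else matrix(ijk, ncol = 3L)
  sh <- g@imageShape  # (rows, cols)
  if (any(m[, 1L] < 0 | m[, 1L] > sh[2L] - 1L |
          m[, 2L] < 0 | m[, 2L] > sh[1L] - 1L |
          m[, 3L] < 0 | m[, 3L] > length(g@slicePositions) - 1L))
    stop("voxel index out of bounds")
  X <- g@orientation[1:3]; Y <- g@orientation[4:6]
  dr <- g@pixelSpacing[1L]; dc <- g@pixelSpacing[2L]
  org <- g@sliceOrigins[m[, 3L] + 1L, , drop = FALSE]
  out <- org + outer(m[, 1L] * dc, X) + outer(m[, 2L] * dr, Y)
  if (is.matrix(ijk)) out else as.numeric(out)
}

#' Map patient coordinates back to voxel indices
#'
#' Inverse of [voxelToPatient()]; `patientToVoxel(g, voxelToPatient(g, ijk))`
#' is the identity to better than 1e-6 mm.
#'
#' @param g a [ScanGeometry-class].
#' @param xyz numeric triple or n x 3 matrix of patient coordinates (mm).
#' @return 0-based (possibly fractional) voxel indices, same shape as input.
#' @export
patientToVoxel <- function(g, xyz) {
  m <- if (is.matrix(xyz)) xyz else matrix(xyz, ncol = 3L)
  X <- g@orientation[1:3]; Y <- g@orientation[4:6]
  dr <- g@pixelSpacing[1L]; dc <- g@pixelSpacing[2L]
  normal <- c(X[2] * Y[3] - X[3] * Y[2], X[3] * Y[1] - X[1] * Y[3],
              X[1] * Y[2] - X[2] * Y[1])
  z <- as.numeric(m %*% normal)
  k <- vapply(z, function(zi) which.min(abs(g@slicePositions - zi)) - 1L,
              numeric(1))
  step <- if (length(g@slicePositions) > 1L)
    stats::median(diff(g@slicePositions)) else 1
  k <- k + (z - g@slicePositions[k + 1L]) / step
  rel <- m - g@sliceOrigins[pmax(1L, pmin(length(g@slicePositions),
                                          round(k) + 1L)), , drop = FALSE]
  i <- as.numeric(rel %*% X) / dc
  j <- as.numeric(rel %*% Y) / dr
  out <- cbind(i, j, k)
  if (is.matrix(xyz)) out else as.numeric(out)
}

## resolve a ContourRoi to a 1-based slice index within g
.resolveSlice <- function(g, roi) {
  if (nzchar(roi@sliceRef)) {
    k <- g@sliceTable[roi@sliceRef]
    if (is.na(k))
      stop("slice reference '", roi@sliceRef,
           "' does not resolve in this series", call. = FALSE)
    return(unname(k))
  }
  d <- abs(g@slicePositions - roi@zPos)
  k <- which.min(d)
  step <- if (length(g@slicePositions) > 1L)
    stats::median(abs(diff(g@slicePositions))) else 1
  if (d[k] > step / 2)
    stop("contour z position ", roi@zPos,
         " mm does not match any slice of the series", call. = FALSE)
  k
}
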