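## Synthetic CT phantom + LIDC-dialect annotation generator with analytic
## ground truth.  The phantom is geometry-faithful (consistent UIDs,
## orientation, positions) with trivial intensity content: a uniform
## background plus hyperdense spherical nodules; intensity realism is
## irrelevant to conversion correctness.

.rngUID <- function(root = "2.25") {
  d <- paste(sample(0:9, 32, replace = TRUE), collapse = "")
  d <- sub("^0+", "", d)
  if (d == "") d <- "1"
  paste0(root, ".", d)
}

#' Describe a synthetic CT + annotation phantom
#'
#' @param imageShape `(rows, columns)` of each slice.
#' @param pixelSpacing `(row, column)` spacing in mm.
#' @param sliceStep slice spacing in mm.
#' @param nSlices number of slices.
#' @param nodules list of nodule descriptions; each a list with `center`
#'   (patient-space mm, `c(x, y, z)`), `radius` (mm), and optionally
#'   `nReaders` (default 4), `jitter` (per-reader radius jitter in mm,
#'   default 0.5), `characteristics` (named rating vector applied to every
#'   reader, a list of per-reader vectors, or `NULL` to sample uniformly
#'   over each attribute's value set).
#' @param centerMarks number of additional center-only (non-volumetric)
#'   marks to emit, exercising the volumetric-selection filter.
#' @param seed RNG seed; a fixed seed makes both generators byte-identical
#'   across runs.
#' @return a validated [PhantomSpec-class]; nodules that do not fit inside
#'   the volume (with their jitter margin) or are smaller than 2 voxels in
#'   radius are rejected.
#' @export
phantomSpec <- function(imageShape = c(128L, 128L),
                        pixelSpacing = c(0.7, 0.7), sliceStep = 2.5,
                        nSlices = 20L, nodules = list(), centerMarks = 0L,
                        seed = 1L) {
  spec <- new("PhantomSpec", imageShape = as.integer(imageShape),
              pixelSpacing = as.numeric(pixelSpacing),
              sliceStep = as.numeric(sliceStep), nSlices = as.integer(nSlices),
              nodules = nodules, centerMarks = as.integer(centerMarks),
              seed = as.integer(seed))
  ext <- c((imageShape[2L] - 1L) * pixelSpacing[2L],
           (imageShape[1L] - 1L) * pixelSpacing[1L],
           (nSlices - 1L) * sliceStep)
  for (nd in nodules) {
    r <- nd$radius
    jit <- nd$jitter %||% 0.5
    if (r < 2 * max(pixelSpacing))
      stop("nodule radius ", r, " mm is below 2 voxels", call. = FALSE)
    margin <- r + jit + 2 * max(pixelSpacing, sliceStep)
    if (any(nd$center - margin < 0) || any(nd$center + margin > ext))
      stop("nodule at (", paste(nd$center, collapse = ", "),
           ") mm protrudes outside the volume", call. = FALSE)
  }
  spec
}

.withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Generate a synthetic CT series
#'
#' Writes one DICOM file per slice (axial orientation, ImagePositionPatient
#' advancing by the slice step) plus a machine-readable ground-truth record
#' `ground_truth.json` with the true nodule centers, radii and analytic
#' sphere volumes/areas.
#'
#' @param spec a [PhantomSpec-class].
#' @param outDir output directory (created if needed).
#' @return the ground-truth record, invisibly.
#' @export
generateCtSeries <- function(spec, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  .withSeed(spec@seed, {
    studyUID <- .rngUID(); seriesUID <- .rngUID(); frameUID <- .rngUID()
    sopUIDs <- vapply(seq_len(spec@nSlices), function(i) .rngUID(),
                      character(1))
    rows <- spec@imageShape[1L]; cols <- spec@imageShape[2L]
    dr <- spec@pixelSpacing[1L]; dc <- spec@pixelSpacing[2L]
    patientID <- sprintf("PHANTOM-%04d", spec@seed %% 10000L)
    xs <- (seq_len(cols) - 1L) * dc
    ys <- (seq_len(rows) - 1L) * dr
    for (k in seq_len(spec@nSlices)) {
      z <- (k - 1L) * spec@sliceStep
      img <- matrix(24L, nrow = cols, ncol = rows)  # -1000 HU background
      for (nd in spec@nodules) {
        dz <- z - nd$center[3L]
        if (abs(dz) >= nd$radius) next
        rd2 <- nd$radius^2 - dz^2
        d2 <- outer((xs - nd$center[1L])^2, (ys - nd$center[2L])^2, `+`)
        img[d2 <= rd2] <- 2024L  # +1000 HU nodule
      }
      ds <- list(
        "0008,0008" = dcmEl("CS", c("ORIGINAL", "PRIMARY", "AXIAL")),
        "0008,0016" = dcmEl("UI", UID_CT_STORAGE),
        "0008,0018" = dcmEl("UI", sopUIDs[k]),
        "0008,0020" = dcmEl("DA", .SEG_CONTENT_DATE),
        "0008,0030" = dcmEl("TM", .SEG_CONTENT_TIME),
        "0008,0050" = dcmEl("SH", "1"),
        "0008,0060" = dcmEl("CS", "CT"),
        "0008,0070" = dcmEl("LO", "noduleSEG phantom"),
        "0008,0090" = dcmEl("PN", ""),
        "0010,0010" = dcmEl("PN", "Phantom^Synthetic"),
        "0010,0020" = dcmEl("LO", patientID),
        "0010,0030" = dcmEl("DA", ""),
        "0010,0040" = dcmEl("CS", "O"),
        "0018,0050" = dcmEl("DS", spec@sliceStep),
        "0020,000D" = dcmEl("UI", studyUID),
        "0020,000E" = dcmEl("UI", seriesUID),
        "0020,0010" = dcmEl("SH", "1"),
        "0020,0011" = dcmEl("IS", 1L),
        "0020,0013" = dcmEl("IS", k),
        "0020,0032" = dcmEl("DS", c(0, 0, z)),
        "0020,0037" = dcmEl("DS", c(1, 0, 0, 0, 1, 0)),
        "0020,0052" = dcmEl("UI", frameUID),
        "0028,0002" = dcmEl("US", 1L),
        "0028,0004" = dcmEl("CS", "MONOCHROME2"),
        "0028,0010" = dcmEl("US", rows),
        "0028,0011" = dcmEl("US", cols),
        "0028,0030" = dcmEl("DS", spec@pixelSpacing),
        "0028,0100" = dcmEl("US", 16L),
        "0028,0101" = dcmEl("US", 16L),
        "0028,0102" = dcmEl("US", 15L),
        "0028,0103" = dcmEl("US", 0L),
        "0028,1052" = dcmEl("DS", -1024),
        "0028,1053" = dcmEl("DS", 1),
        "7FE0,0010" = dcmEl("OW", writeBin(as.integer(img), raw(),
                                           size = 2L, endian = "little")))
      dcmWrite(ds, file.path(outDir, sprintf("ct_%03d.dcm", k)))
    }
    gt <- list(
      patient_id = patientID, study_uid = studyUID, series_uid = seriesUID,
      frame_uid = frameUID, sop_uids = sopUIDs,
      image_shape = spec@imageShape, pixel_spacing = spec@pixelSpacing,
      slice_step = spec@sliceStep, n_slices = spec@nSlices,
      nodules = lapply(spec@nodules, function(nd) list(
        center_mm = nd$center, radius_mm = nd$radius,
        volume_mm3 = 4 / 3 * pi * nd$radius^3,
        surface_area_mm2 = 4 * pi * nd$radius^2)))
    jsonlite::write_json(gt, file.path(outDir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
    invisible(gt)
  })
}

## pixels just outside the digitized disc: the one-pixel (chebyshev) shell,
## ordered by angle around the disc center to form a closed simple ring
.discRing <- function(inDisc, cxPix, cyPix) {
  nx <- nrow(inDisc); ny <- ncol(inDisc)
  pad <- matrix(FALSE, nx + 2L, ny + 2L)
  pad[2:(nx + 1L), 2:(ny + 1L)] <- inDisc
  dil <- pad
  for (ox in -1:1) for (oy in -1:1) {
    if (ox == 0L && oy == 0L) next
    dil[(2:(nx + 1L)) , (2:(ny + 1L))] <-
      dil[2:(nx + 1L), 2:(ny + 1L)] | pad[2:(nx + 1L) + ox, 2:(ny + 1L) + oy]
  }
  shell <- dil[2:(nx + 1L), 2:(ny + 1L)] & !inDisc
  w <- which(shell, arr.ind = TRUE)
  px <- w[, 1L] - 1L; py <- w[, 2L] - 1L  # 0-based pixel indices
  ang <- atan2(py - cyPix, px - cxPix)
  rad <- (px - cxPix)^2 + (py - cyPix)^2
  ord <- order(ang, rad)
  cbind(px[ord], py[ord])
}

## uniform characteristic sample over each attribute's documented range
.sampleCharacteristics <- function() {
  stats::setNames(vapply(LIDC_CHARACTERISTICS, function(nm)
    sample.int(LIDC_RATING_MAX[[nm]], 1L), integer(1)),
    LIDC_CHARACTERISTICS)
}

#' Generate LIDC-dialect annotations for a phantom
#'
#' For each nodule and reader, traces per-slice contours through the pixels
#' just outside the digitized sphere cross-section (the convention the
#' rasterizer assumes), with a per-reader random radius jitter, and
#' populates the characteristics blocks.  Center-only marks are emitted as
#' single-point ROIs so the volumetric-selection filter has something to
#' drop.
#'
#' @param spec the [PhantomSpec-class] used for the series.
#' @param g the [ScanGeometry-class] built from the generated series.
#' @param outPath output XML path, or `NULL` to skip writing.
#' @return the list of [NoduleAnnotation-class] (invisibly when written).
#' @export
generateAnnotations <- function(spec, g, outPath = NULL) {
  .withSeed(spec@seed + 1L, {
    dr <- g@pixelSpacing[1L]; dc <- g@pixelSpacing[2L]
    rows <- g@imageShape[1L]; cols <- g@imageShape[2L]
    xs <- (seq_len(cols) - 1L) * dc
    ys <- (seq_len(rows) - 1L) * dr
    uidBySlice <- character(length(g@slicePositions))
    uidBySlice[g@sliceTable] <- names(g@sliceTable)
    anns <- list()
    for (ni in seq_along(spec@nodules)) {
      nd <- spec@nodules[[ni]]
      nReaders <- nd$nReaders %||% 4L
      jit <- nd$jitter %||% 0.5
      for (ri in seq_len(nReaders)) {
        rr <- nd$radius + stats::runif(1L, -jit, jit)
        ch <- if (is.null(nd$characteristics)) .sampleCharacteristics()
              else if (is.list(nd$characteristics)) nd$characteristics[[ri]]
              else nd$characteristics
        roiList <- list()
        for (k in seq_along(g@slicePositions)) {
          dz <- g@slicePositions[k] - nd$center[3L]
          if (abs(dz) >= rr) next
          rd2 <- rr^2 - dz^2
          inDisc <- outer((xs - nd$center[1L])^2, (ys - nd$center[2L])^2,
                          `+`) <= rd2
          if (!any(inDisc)) next
          ring <- .discRing(inDisc, nd$center[1L] / dc, nd$center[2L] / dr)
          if (nrow(ring) < 3L) next
          roiList[[length(roiList) + 1L]] <- contourRoi(
            ring, zPos = g@slicePositions[k], inclusion = TRUE,
            sliceRef = uidBySlice[k])
        }
        if (length(roiList) == 0L) next
        anns[[length(anns) + 1L]] <- noduleAnnotation(
          sprintf("%d", 100L * ni + ri), roiList, ch, sessionIndex = ri)
      }
    }
    for (mi in seq_len(spec@centerMarks)) {
      k <- max(1L, length(g@slicePositions) %/% 2L)
      anns[[length(anns) + 1L]] <- noduleAnnotation(
        sprintf("CM%d", mi),
        list(contourRoi(cbind(2L + mi, 2L), zPos = g@slicePositions[k],
                        inclusion = TRUE, sliceRef = uidBySlice[k])),
        NULL, sessionIndex = 1L)
    }
    if (!is.null(outPath)) {
      writeAnnotationXml(anns, outPath, seriesUID = g@seriesUID)
      return(invisible(anns))
    }
    anns
  })
}

#' Analytic digitized-sphere mask
#'
#' Membership oracle for the phantom's spheres: the set of voxels whose
#' centers lie within `radius` of `center`, as a [MaskVolume-class].
#'
#' @param g a [ScanGeometry-class].
#' @param center patient-space `(x, y, z)` in mm.
#' @param radius sphere radius in mm.
#' @return a [MaskVolume-class].
#' @export
analyticSphereMask <- function(g, center, radius) {
  rows <- g@imageShape[1L]; cols <- g@imageShape[2L]
  dr <- g@pixelSpacing[1L]; dc <- g@pixelSpacing[2L]
  xs <- (seq_len(cols) - 1L) * dc
  ys <- (seq_len(rows) - 1L) * dr
  vol <- array(FALSE, dim = c(cols, rows, length(g@slicePositions)))
  for (k in seq_along(g@slicePositions)) {
    dz <- g@slicePositions[k] - center[3L]
    if (abs(dz) > radius) next
    rd2 <- radius^2 - dz^2
    vol[, , k] <- outer((xs - center[1L])^2, (ys - center[2L])^2, `+`) <= rd2
  }
  new("MaskVolume", voxels = vol, geometry = g,
      nonemptySlices = as.integer(which(apply(vol, 3L, any))))
}
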