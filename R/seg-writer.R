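## DICOM Segmentation (binary, one segment per object) encoder/decoder
## following the collection conventions: one SEG per annotation, frames only
## for non-empty slices, "Nodule <n> - Annotation <id>" labelling, tracking
## pair shared with the SR, distinct display colors within a cluster.

.SEG_CONTENT_DATE <- "20200101"
.SEG_CONTENT_TIME <- "000000"

## fixed cycle of high-saturation display colors, indexed by the annotation
## ordinal within its cluster; colors carry no semantics
SEG_PALETTE <- list(
  c(255L, 64L, 64L), c(64L, 255L, 64L), c(64L, 64L, 255L),
  c(255L, 255L, 64L), c(255L, 64L, 255L), c(64L, 255L, 255L),
  c(255L, 160L, 32L), c(160L, 64L, 255L))

## ---- colorimetry ---------------------------------------------------------

.M_RGB2XYZ <- matrix(c(0.4124564, 0.3575761, 0.1804375,
                       0.2126729, 0.7151522, 0.0721750,
                       0.0193339, 0.1191920, 0.9503041),
                     nrow = 3L, byrow = TRUE)
## Bradford chromatic adaptation D65 -> D50, derived from the Bradford cone
## response matrix and the two white points (so white maps to white exactly)
.M_BRADFORD <- matrix(c(0.8951, 0.2664, -0.1614,
                        -0.7502, 1.7135, 0.0367,
                        0.0389, -0.0685, 1.0296),
                      nrow = 3L, byrow = TRUE)
.WHITE_D65 <- c(0.95047, 1.0, 1.08883)
.WHITE_D50 <- c(0.96422, 1.0, 0.82521)
.M_D65_D50 <- solve(.M_BRADFORD) %*%
  diag(as.numeric(.M_BRADFORD %*% .WHITE_D50) /
       as.numeric(.M_BRADFORD %*% .WHITE_D65)) %*% .M_BRADFORD

.labF <- function(t) {
  d <- (6 / 29)^3
  ifelse(t > d, t^(1 / 3), t / (3 * (6 / 29)^2) + 4 / 29)
}
.labFinv <- function(f) {
  d <- 6 / 29
  ifelse(f > d, f^3, 3 * d^2 * (f - 4 / 29))
}

#' Convert an RGB display color to 16-bit scaled CIELab
#'
#' sRGB bytes to CIELab under the DICOM convention (D50 reference white,
#' Bradford-adapted from the sRGB D65 primaries), scaled to 16-bit unsigned:
#' L* 0..100 maps to 0..0xFFFF, a*/b* -128..127 map to 0..0xFFFF with 0 at
#' 0x8080.
#'
#' @param rgb integer triple, components 0..255.
#' @return integer triple `(L, a, b)` in 0..65535.
#' @export
rgbToCielab16 <- function(rgb) {
  stopifnot(length(rgb) == 3L, all(rgb >= 0 & rgb <= 255))
  s <- rgb / 255
  lin <- ifelse(s <= 0.04045, s / 12.92, ((s + 0.055) / 1.055)^2.4)
  xyz <- as.numeric(.M_D65_D50 %*% (.M_RGB2XYZ %*% lin))
  f <- .labF(xyz / .WHITE_D50)
  L <- 116 * f[2] - 16
  a <- 500 * (f[1] - f[2])
  b <- 200 * (f[2] - f[3])
  u <- round(c(L * 65535 / 100,
               (a + 128) * 65535 / 255,
               (b + 128) * 65535 / 255))
  as.integer(pmin(pmax(u, 0), 65535))
}

#' Convert 16-bit scaled CIELab back to RGB bytes
#' @param lab16 integer triple in 0..65535 as stored in
#'   RecommendedDisplayCIELabValue.
#' @return integer RGB triple 0..255 (inverse of [rgbToCielab16()] up to
#'   rounding).
#' @export
cielab16ToRgb <- function(lab16) {
  L <- lab16[1] * 100 / 65535
  a <- lab16[2] * 255 / 65535 - 128
  b <- lab16[3] * 255 / 65535 - 128
  fy <- (L + 16) / 116
  f <- c(fy + a / 500, fy, fy - b / 200)
  xyz <- .labFinv(f) * .WHITE_D50
  lin <- as.numeric(solve(.M_RGB2XYZ) %*% (solve(.M_D65_D50) %*% xyz))
  lin <- pmin(pmax(lin, 0), 1)
  s <- ifelse(lin <= 0.0031308, 12.92 * lin, 1.055 * lin^(1 / 2.4) - 0.055)
  as.integer(round(s * 255))
}

## ---- code sequence helpers ----------------------------------------------

.codeItem <- function(cc) {
  list("0008,0100" = dcmEl("SH", cc@value),
       "0008,0102" = dcmEl("SH", cc@scheme),
       "0008,0104" = dcmEl("LO", cc@meaning))
}

.codeFromItem <- function(item) {
  codedConcept(dcmGet(item, "0008,0100"), dcmGet(item, "0008,0102"),
               dcmGet(item, "0008,0104"))
}

.contextElements <- function(ctx) {
  vrs <- c(PatientName = "PN", PatientID = "LO", PatientBirthDate = "DA",
           PatientSex = "CS", StudyInstanceUID = "UI", StudyDate = "DA",
           StudyTime = "TM", ReferringPhysicianName = "PN", StudyID = "SH",
           AccessionNumber = "SH")
  out <- list()
  for (nm in names(.CONTEXT_TAGS)) {
    v <- ctx[nm]
    if (is.na(v)) v <- ""
    out[[.CONTEXT_TAGS[[nm]]]] <- dcmEl(vrs[[nm]], unname(v))
  }
  out
}

#' Build the SEG labelling conventions for one annotation
#'
#' @param noduleNumber the owning cluster's nodule number.
#' @param annotationId annotation identifier from the XML file.
#' @param trackingUID the cluster's tracking UID.
#' @param ordinal annotation ordinal within the cluster (selects the display
#'   color from the fixed palette).
#' @return a [SegConventions-class].
#' @export
segConventions <- function(noduleNumber, annotationId, trackingUID,
                           ordinal = 1L) {
  label <- sprintf("Nodule %d - Annotation %s", noduleNumber, annotationId)
  col <- SEG_PALETTE[[(ordinal - 1L) %% length(SEG_PALETTE) + 1L]]
  new("SegConventions", seriesDescription = label, segmentLabel = label,
      trackingId = label, trackingUID = trackingUID, displayColor = col)
}

#' Encode a mask volume as a DICOM Segmentation object
#'
#' Binary segmentation with one segment and one frame per non-empty slice
#' only; each frame carries its plane position and a derivation reference to
#' the source CT slice.  The segment carries the constant category / type /
#' anatomy codes, the tracking pair, and the display color as 16-bit CIELab.
#' Patient and study composite context are copied from the source series;
#' the object receives fresh series and instance UIDs.
#'
#' @param mask a non-empty [MaskVolume-class].
#' @param conv a [SegConventions-class].
#' @param ctRefs character vector of source-slice SOP instance UIDs in
#'   sorted slice order; defaults to the geometry's slice table.  Must cover
#'   every non-empty slice.
#' @param file optional output path.
#' @param sct use numeric SCT codes instead of SRT identifiers.
#' @param uidRoot root for the generated UIDs.
#' @return raw vector of the encoded object (invisibly when written).
#' @export
encodeSeg <- function(mask, conv, ctRefs = NULL, file = NULL, sct = FALSE,
                      uidRoot = getOption("noduleSEG.uid_root", "2.25")) {
  .checkNonEmpty(mask)
  g <- mask@geometry
  if (is.null(ctRefs)) {
    ctRefs <- character(length(g@slicePositions))
    ctRefs[g@sliceTable] <- names(g@sliceTable)
  }
  frames <- mask@nonemptySlices
  if (any(!nzchar(ctRefs[frames])))
    stop("source CT reference missing for non-empty slice(s) ",
         paste(frames[!nzchar(ctRefs[frames])], collapse = ", "), call. = FALSE)

  sem <- segmentationSemantics(sct = sct)
  sopUID <- genUID(uidRoot)
  seriesUID <- genUID(uidRoot)
  dimUID <- genUID(uidRoot)
  sh <- g@imageShape
  step <- if (length(g@slicePositions) > 1L)
    stats::median(abs(diff(g@slicePositions))) else 1

  bits <- unlist(lapply(frames, function(k) as.logical(mask@voxels[, , k])),
                 use.names = FALSE)
  if (length(bits) %% 8L != 0L)
    bits <- c(bits, logical(8L - length(bits) %% 8L))
  pixelData <- packBits(bits, type = "raw")

  perFrame <- lapply(seq_along(frames), function(fi) {
    k <- frames[fi]
    list(
      "0008,9124" = dcmEl("SQ", list(list(
        "0008,2112" = dcmEl("SQ", list(list(
          "0008,1150" = dcmEl("UI", UID_CT_STORAGE),
          "0008,1155" = dcmEl("UI", ctRefs[k]),
          "0040,A170" = dcmEl("SQ", list(.codeItem(codedConcept(
            "121322", "DCM",
            "Source image for image processing operation"))))))),
        "0008,9215" = dcmEl("SQ", list(.codeItem(codedConcept(
          "113076", "DCM", "Segmentation"))))))),
      "0020,9111" = dcmEl("SQ", list(list(
        "0020,9157" = dcmEl("UL", c(1, fi))))),
      "0020,9113" = dcmEl("SQ", list(list(
        "0020,0032" = dcmEl("DS", g@sliceOrigins[k, ])))),
      "0062,000A" = dcmEl("SQ", list(list(
        "0062,000B" = dcmEl("US", 1L)))))
  })

  segItem <- list(
    "0062,0004" = dcmEl("US", 1L),                 # SegmentNumber
    "0062,0005" = dcmEl("LO", conv@segmentLabel),  # SegmentLabel
    "0062,0006" = dcmEl("ST", conv@segmentLabel),  # SegmentDescription
    "0062,0008" = dcmEl("CS", "MANUAL"),           # SegmentAlgorithmType
    "0062,000D" = dcmEl("US", rgbToCielab16(conv@displayColor)),
    "0062,0003" = dcmEl("SQ", list(.codeItem(sem$category))),
    "0062,000F" = dcmEl("SQ", list(.codeItem(sem$type))),
    "0008,2218" = dcmEl("SQ", list(.codeItem(sem$anatomy))),
    "0062,0020" = dcmEl("LO", conv@trackingId),
    "0062,0021" = dcmEl("UI", conv@trackingUID))

  refInstances <- lapply(which(nzchar(ctRefs)), function(k) list(
    "0008,1150" = dcmEl("UI", UID_CT_STORAGE),
    "0008,1155" = dcmEl("UI", ctRefs[k])))

  ds <- c(.contextElements(g@context), list(
    "0008,0008" = dcmEl("CS", c("DERIVED", "PRIMARY")),
    "0008,0016" = dcmEl("UI", UID_SEG_STORAGE),
    "0008,0018" = dcmEl("UI", sopUID),
    "0008,0021" = dcmEl("DA", .SEG_CONTENT_DATE),  # SeriesDate
    "0008,0023" = dcmEl("DA", .SEG_CONTENT_DATE),  # ContentDate
    "0008,0031" = dcmEl("TM", .SEG_CONTENT_TIME),
    "0008,0033" = dcmEl("TM", .SEG_CONTENT_TIME),
    "0008,0060" = dcmEl("CS", "SEG"),
    "0008,0070" = dcmEl("LO", "noduleSEG"),
    "0008,103E" = dcmEl("LO", conv@seriesDescription),
    "0008,1115" = dcmEl("SQ", list(list(
      "0008,114A" = dcmEl("SQ", refInstances),
      "0020,000E" = dcmEl("UI", g@seriesUID)))),
    "0020,000D" = dcmEl("UI", unname(g@context["StudyInstanceUID"])),
    "0020,000E" = dcmEl("UI", seriesUID),
    "0020,0011" = dcmEl("IS", 300L),
    "0020,0013" = dcmEl("IS", 1L),
    "0020,0052" = dcmEl("UI", g@frameUID),
    "0020,9221" = dcmEl("SQ", list(list(
      "0020,9164" = dcmEl("UI", dimUID)))),
    "0020,9222" = dcmEl("SQ", list(
      list("0020,9164" = dcmEl("UI", dimUID),
           "0020,9165" = dcmEl("AT", "0062,000B"),
           "0020,9167" = dcmEl("AT", "0062,000A")),
      list("0020,9164" = dcmEl("UI", dimUID),
           "0020,9165" = dcmEl("AT", "0020,0032"),
           "0020,9167" = dcmEl("AT", "0020,9113")))),
    "0028,0002" = dcmEl("US", 1L),
    "0028,0004" = dcmEl("CS", "MONOCHROME2"),
    "0028,0008" = dcmEl("IS", length(frames)),
    "0028,0010" = dcmEl("US", sh[1L]),
    "0028,0011" = dcmEl("US", sh[2L]),
    "0028,0100" = dcmEl("US", 1L),
    "0028,0101" = dcmEl("US", 1L),
    "0028,0102" = dcmEl("US", 0L),
    "0028,0103" = dcmEl("US", 0L),
    "0028,2110" = dcmEl("CS", "00"),
    "0062,0001" = dcmEl("CS", "BINARY"),
    "0062,0002" = dcmEl("SQ", list(segItem)),
    "0070,0080" = dcmEl("CS", "SEGMENTATION"),
    "0070,0081" = dcmEl("LO", conv@seriesDescription),
    "5200,9229" = dcmEl("SQ", list(list(
      "0020,9116" = dcmEl("SQ", list(list(
        "0020,0037" = dcmEl("DS", g@orientation)))),
      "0028,9110" = dcmEl("SQ", list(list(
        "0018,0050" = dcmEl("DS", step),
        "0018,0088" = dcmEl("DS", step),
        "0028,0030" = dcmEl("DS", g@pixelSpacing))))))),
    "5200,9230" = dcmEl("SQ", perFrame),
    "7FE0,0010" = dcmEl("OB", pixelData)))

  out <- dcmWrite(ds, path = file)
  if (is.null(file)) out else invisible(out)
}

#' Decode a DICOM Segmentation object back into a mask volume
#'
#' Reconstructs the mask in the CT frame using the per-frame plane
#' positions, and recovers the labelling conventions (labels, tracking pair,
#' display color).
#'
#' @param x file path or raw vector of a binary, single-segment SEG.
#' @param g the [ScanGeometry-class] of the source CT series.
#' @return `list(mask = MaskVolume, conventions = SegConventions)`.
#' @export
decodeSeg <- function(x, g) {
  ds <- if (is.raw(x) || is.character(x)) dcmRead(x) else x
  if (!identical(dcmGet(ds, "0008,0016"), UID_SEG_STORAGE))
    stop("not a DICOM Segmentation object", call. = FALSE)
  if (!identical(dcmGet(ds, "0020,0052"), g@frameUID))
    stop("frame of reference does not match the supplied geometry",
         call. = FALSE)
  segs <- dcmGet(ds, "0062,0002")
  if (length(segs) != 1L) stop("expected exactly one segment", call. = FALSE)
  rows <- dcmGet(ds, "0028,0010"); cols <- dcmGet(ds, "0028,0011")
  if (rows != g@imageShape[1L] || cols != g@imageShape[2L])
    stop("SEG frame size does not match the CT geometry", call. = FALSE)
  nFrames <- as.integer(dcmGet(ds, "0028,0008"))
  pf <- dcmGet(ds, "5200,9230")
  if (length(pf) != nFrames) stop("per-frame groups inconsistent with ",
                                  "NumberOfFrames", call. = FALSE)
  step <- if (length(g@slicePositions) > 1L)
    stats::median(abs(diff(g@slicePositions))) else 1
  bits <- as.logical(rawToBits(dcmGet(ds, "7FE0,0010")))
  npix <- as.numeric(rows) * cols
  vol <- array(FALSE, dim = c(cols, rows, length(g@slicePositions)))
  for (fi in seq_len(nFrames)) {
    ipp <- dcmGet(pf[[fi]][["0020,9113"]]$value[[1L]], "0020,0032")
    zd <- abs(g@slicePositions - ipp[3L])
    k <- which.min(zd)
    if (zd[k] > step / 2)
      stop("frame ", fi, " is not alignable to the CT geometry", call. = FALSE)
    fb <- bits[((fi - 1L) * npix + 1L):(fi * npix)]
    vol[, , k] <- vol[, , k] | matrix(fb, nrow = cols, ncol = rows)
  }
  seg <- segs[[1L]]
  lab16 <- dcmGet(seg, "0062,000D", c(65535L, 32896L, 32896L))
  conv <- new("SegConventions",
              seriesDescription = dcmGet(ds, "0008,103E", ""),
              segmentLabel = dcmGet(seg, "0062,0005", ""),
              trackingId = dcmGet(seg, "0062,0020", ""),
              trackingUID = dcmGet(seg, "0062,0021", ""),
              displayColor = cielab16ToRgb(lab16))
  mask <- new("MaskVolume", voxels = vol, geometry = g,
              nonemptySlices = as.integer(which(apply(vol, 3L, any))))
  list(mask = mask, conventions = conv)
}
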