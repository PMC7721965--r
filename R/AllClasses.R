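#' @import methods
NULL

## Characteristic attribute names (XML dialect spelling) and rating ranges.
## internalStructure is a 4-category attribute, calcification 6, the rest
## 5-point ordinals.
LIDC_CHARACTERISTICS <- c("subtlety", "internalStructure", "calcification",
                          "sphericity", "margin", "lobulation", "spiculation",
                          "texture", "malignancy")
LIDC_RATING_MAX <- c(subtlety = 5L, internalStructure = 4L, calcification = 6L,
                     sphericity = 5L, margin = 5L, lobulation = 5L,
                     spiculation = 5L, texture = 5L, malignancy = 5L)

#' ContourRoi: one planar contour of a nodule annotation
#'
#' A single region of interest on one CT slice: an ordered closed polygon of
#' integer pixel indices through the pixels just *outside* the region it
#' delineates, flagged as an included or excluded region.
#'
#' @slot sliceRef opaque slice identifier (SOP instance UID in the LIDC
#'   dialect); may be empty when only `zPos` identifies the slice.
#' @slot zPos patient-space z coordinate of the slice in mm.
#' @slot inclusion `TRUE` for an included region, `FALSE` for an excluded one.
#' @slot points n x 2 integer matrix of 0-based `(x = column, y = row)` pixel
#'   indices.
#' @export
setClass("ContourRoi", representation(
  sliceRef = "character", zPos = "numeric", inclusion = "logical",
  points = "matrix"))

setValidity("ContourRoi", function(object) {
  p <- object@points
  if (!is.numeric(p) || ncol(p) != 2L) return("points must be an n x 2 matrix")
  if (nrow(p) < 1L) return("points must be non-empty")
  if (any(p != round(p))) return("points must be integer pixel indices")
  if (length(object@inclusion) != 1L) return("inclusion must be a scalar")
  TRUE
})

#' NoduleAnnotation: one reading session's volumetric annotation of a nodule
#'
#' @slot annotationId identifier as assigned in the XML annotation file.
#' @slot rois list of [ContourRoi-class] objects.
#' @slot characteristics named integer vector; a subset of the nine
#'   characteristic ratings (subtlety, internalStructure, calcification,
#'   sphericity, margin, lobulation, spiculation, texture, malignancy).
#' @slot sessionIndex ordinal of the reading session in the file; bookkeeping
#'   only, never a reader identity.
#' @export
setClass("NoduleAnnotation", representation(
  annotationId = "character", rois = "list", characteristics = "integer",
  sessionIndex = "integer"))

setValidity("NoduleAnnotation", function(object) {
  if (length(object@annotationId) != 1L || !nzchar(object@annotationId))
    return("annotationId must be a non-empty string")
  if (!all(vapply(object@rois, is, logical(1), class2 = "ContourRoi")))
    return("rois must all be ContourRoi")
  ch <- object@characteristics
  if (length(ch) && (is.null(names(ch)) ||
                     !all(names(ch) %in% LIDC_CHARACTERISTICS)))
    return("characteristics must be named by the nine LIDC attributes")
  TRUE
})

#' ScanGeometry: voxel/patient coordinate frame of a CT series
#'
#' @slot pixelSpacing `(row, column)` spacing in mm.
#' @slot slicePositions patient-space z of each slice along the slice normal,
#'   strictly monotonic, in sorted slice order (mm).
#' @slot sliceOrigins n x 3 matrix; ImagePositionPatient of each sorted slice.
#' @slot orientation direction cosines `(rowdir, coldir)` as a length-6
#'   vector: first triplet is the patient direction of increasing column
#'   index, second of increasing row index.
#' @slot sliceTable named integer vector mapping slice identifier (SOP
#'   instance UID) to 1-based sorted slice index.
#' @slot imageShape `(rows, columns)`.
#' @slot seriesUID,studyUID,frameUID series / study / frame-of-reference UIDs.
#' @slot context named character vector of composite-context attributes
#'   (patient and study identification) copied into derived objects.
#' @export
setClass("ScanGeometry", representation(
  pixelSpacing = "numeric", slicePositions = "numeric",
  sliceOrigins = "matrix", orientation = "numeric", sliceTable = "integer",
  imageShape = "integer", seriesUID = "character", studyUID = "character",
  frameUID = "character", context = "character"))

setValidity("ScanGeometry", function(object) {
  n <- length(object@slicePositions)
  d <- diff(object@slicePositions)
  if (n >= 2L && !(all(d > 0) || all(d < 0)))
    return("slicePositions must be strictly monotonic")
  if (any(object@pixelSpacing <= 0)) return("pixel spacing must be positive")
  if (length(object@sliceTable) != n)
    return("sliceTable must map every slice")
  if (!setequal(object@sliceTable, seq_len(n)))
    return("sliceTable must be a bijection onto 1..n_slices")
  if (nrow(object@sliceOrigins) != n)
    return("one origin per slice required")
  TRUE
})

#' MaskVolume: binary voxel mask of one annotation in the CT frame
#'
#' @slot voxels 3-D logical array in `(column, row, slice)` order, matching
#'   the `(x, y, z)` voxel index convention.
#' @slot geometry the [ScanGeometry-class] the mask is aligned to.
#' @slot nonemptySlices sorted 1-based indices of slices with foreground.
#' @export
setClass("MaskVolume", representation(
  voxels = "array", geometry = "ScanGeometry", nonemptySlices = "integer"))

setValidity("MaskVolume", function(object) {
  v <- object@voxels
  if (length(dim(v)) != 3L) return("voxels must be a 3-D array")
  ne <- which(apply(v, 3L, any))
  if (!identical(as.integer(ne), object@nonemptySlices))
    return("nonemptySlices inconsistent with voxels")
  sh <- dim(v)
  g <- object@geometry
  if (sh[1] != g@imageShape[2] || sh[2] != g@imageShape[1] ||
      sh[3] != length(g@slicePositions))
    return("voxel array shape does not match geometry")
  TRUE
})

#' NoduleCluster: annotations judged to be the same physical nodule
#'
#' @slot noduleNumber 1-based consecutive nodule number within the scan.
#' @slot trackingUID globally unique tracking identifier shared by all
#'   SEG/SR objects derived from this nodule.
#' @slot members list of [NoduleAnnotation-class].
#' @slot memberIndex positions of the members in the input annotation list.
#' @export
setClass("NoduleCluster", representation(
  noduleNumber = "integer", trackingUID = "character", members = "list",
  memberIndex = "integer"))

setValidity("NoduleCluster", function(object) {
  if (length(object@members) == 0L) return("members must be non-empty")
  if (length(object@trackingUID) != 1L || !nzchar(object@trackingUID))
    return("trackingUID must be a non-empty string")
  TRUE
})

#' CodedConcept: a (value, scheme, meaning) terminology triplet
#'
#' @slot value code value, e.g. `"M-03010"`.
#' @slot scheme coding scheme designator, e.g. `"SRT"`, `"UCUM"`,
#'   `"99LIDCQIICR"`.
#' @slot meaning human-readable code meaning.
#' @export
setClass("CodedConcept", representation(
  value = "character", scheme = "character", meaning = "character"))

setValidity("CodedConcept", function(object) {
  if (!all(nzchar(c(object@value, object@scheme, object@meaning))))
    return("value, scheme and meaning must all be non-empty")
  ok <- c("SRT", "SCT", "UCUM", "IBSI", "DCM", "99LIDCQIICR", "RFC5646", "LN")
  if (!object@scheme %in% ok)
    return(paste0("unexpected coding scheme '", object@scheme, "'"))
  TRUE
})

#' Create a coded concept
#' @param value,scheme,meaning the triplet components.
#' @return a [CodedConcept-class].
#' @export
codedConcept <- function(value, scheme, meaning) {
  new("CodedConcept", value = as.character(value), scheme = scheme,
      meaning = meaning)
}

#' SegConventions: per-object labelling conventions for one SEG
#'
#' @slot seriesDescription `"Nodule <n> - Annotation <id>"`.
#' @slot segmentLabel same string as the series description.
#' @slot trackingId human-readable tracking label, unique within the scan.
#' @slot trackingUID the owning cluster's tracking UID.
#' @slot displayColor RGB bytes (0..255) recommended for display.
#' @export
setClass("SegConventions", representation(
  seriesDescription = "character", segmentLabel = "character",
  trackingId = "character", trackingUID = "character",
  displayColor = "integer"))

setValidity("SegConventions", function(object) {
  if (length(object@displayColor) != 3L ||
      any(object@displayColor < 0L | object@displayColor > 255L))
    return("displayColor must be three bytes 0..255")
  TRUE
})

#' MeasurementGroup: content of one TID 1500 measurement group
#'
#' @slot trackingId,trackingUID tracking pair, identical to the SEG's.
#' @slot findingType finding type [CodedConcept-class] (Nodule).
#' @slot segmentUID SOP instance UID of the referenced SEG.
#' @slot segmentNumber referenced segment number within the SEG.
#' @slot sourceSeriesUID series UID of the segmented CT.
#' @slot evaluations list of `list(concept =, value =)` coded pairs.
#' @slot measurements list of `list(concept =, value = <numeric>, unit =)`.
#' @export
setClass("MeasurementGroup", representation(
  trackingId = "character", trackingUID = "character",
  findingType = "CodedConcept", segmentUID = "character",
  segmentNumber = "integer", sourceSeriesUID = "character",
  evaluations = "list", measurements = "list"))

setValidity("MeasurementGroup", function(object) {
  if (length(object@evaluations) > 9L)
    return("at most nine qualitative evaluations")
  vals <- vapply(object@measurements, function(m) m$value, numeric(1))
  if (length(vals) && any(!is.finite(vals) | vals < 0))
    return("measurement values must be finite and non-negative")
  TRUE
})

#' PhantomSpec: parameters of a synthetic CT + annotation phantom
#'
#' @slot imageShape `(rows, columns)` of every slice.
#' @slot pixelSpacing `(row, column)` mm.
#' @slot sliceStep slice spacing in mm.
#' @slot nSlices number of slices.
#' @slot nodules list of nodule descriptions (see [phantomSpec()]).
#' @slot centerMarks number of extra center-only (non-volumetric) marks.
#' @slot seed integer RNG seed; a fixed seed yields byte-identical output.
#' @export
setClass("PhantomSpec", representation(
  imageShape = "integer", pixelSpacing = "numeric", sliceStep = "numeric",
  nSlices = "integer", nodules = "list", centerMarks = "integer",
  seed = "integer"))

## ---- show methods --------------------------------------------------------

setMethod("show", "ContourRoi", function(object) {
  cat(sprintf("ContourRoi: %d points, slice z=%.2f mm, %s\n",
              nrow(object@points), object@zPos,
              if (object@inclusion) "included" else "excluded"))
})

setMethod("show", "NoduleAnnotation", function(object) {
  cat(sprintf("NoduleAnnotation '%s': %d ROIs, %d/9 characteristics, session %d\n",
              object@annotationId, length(object@rois),
              length(object@characteristics), object@sessionIndex))
})

setMethod("show", "ScanGeometry", function(object) {
  n <- length(object@slicePositions)
  cat(sprintf("ScanGeometry: %d x %d pixels, %d slices\n",
              object@imageShape[1], object@imageShape[2], n))
  cat(sprintf("  pixel spacing (row, col): %.4g x %.4g mm; slice step %.4g mm\n",
              object@pixelSpacing[1], object@pixelSpacing[2],
              if (n > 1L) stats::median(diff(object@slicePositions)) else NA))
  cat("  series: ", object@seriesUID, "\n", sep = "")
})

setMethod("show", "MaskVolume", function(object) {
  cat(sprintf("MaskVolume: %s voxels, %d foreground, %d non-empty slice(s)\n",
              paste(dim(object@voxels), collapse = " x "),
              sum(object@voxels), length(object@nonemptySlices)))
})

setMethod("show", "NoduleCluster", function(object) {
  cat(sprintf("NoduleCluster %d: %d annotation(s) [%s], tracking UID %s\n",
              object@noduleNumber, length(object@members),
              paste(vapply(object@members, function(a) a@annotationId,
                           character(1)), collapse = ", "),
              object@trackingUID))
})

setMethod("show", "CodedConcept", function(object) {
  cat(sprintf("(\"%s\", \"%s\", \"%s\")\n", object@value, object@scheme,
              object@meaning))
})

setMethod("show", "MeasurementGroup", function(object) {
  cat(sprintf("MeasurementGroup '%s': %d evaluations, %d measurements\n",
              object@trackingId, length(object@evaluations),
              length(object@measurements)))
})
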