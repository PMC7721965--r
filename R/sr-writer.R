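## DICOM SR measurement reports following template TID 1500: one report per
## annotation, one measurement group carrying the tracking pair, the SEG and
## source-series references, the coded qualitative evaluations and the three
## coded measurements with UCUM units.

.srItem <- function(rel, vtype, concept, body = list()) {
  c(list("0040,A010" = dcmEl("CS", rel),
         "0040,A040" = dcmEl("CS", vtype),
         "0040,A043" = dcmEl("SQ", list(.codeItem(concept)))),
    body)
}

.srConcept <- function(item) .codeFromItem(item[["0040,A043"]]$value[[1L]])

.srFindChild <- function(items, codeValue) {
  for (it in items) if (.srConcept(it)@value == codeValue) return(it)
  NULL
}

#' Assemble a TID 1500 measurement group for one annotation
#'
#' Builds the [MeasurementGroup-class] from an annotation's characteristics
#' (coded through the dictionary, in canonical attribute order; absent
#' characteristics are simply omitted) and its computed measurements.
#'
#' @param ann the [NoduleAnnotation-class].
#' @param conv the annotation's [SegConventions-class] (tracking pair).
#' @param measurements named list from [measureNodule()].
#' @param segmentUID SOP instance UID of the annotation's SEG object.
#' @param sourceSeriesUID series UID of the segmented CT.
#' @param segmentNumber referenced segment number (always 1 here).
#' @param dictionary code dictionary, `NULL` for the shipped one.
#' @return a [MeasurementGroup-class].
#' @export
buildMeasurementGroup <- function(ann, conv, measurements, segmentUID,
                                  sourceSeriesUID, segmentNumber = 1L,
                                  dictionary = NULL) {
  evals <- list()
  for (nm in LIDC_CHARACTERISTICS) {
    if (nm %in% names(ann@characteristics))
      evals[[length(evals) + 1L]] <-
        evaluationCode(nm, ann@characteristics[[nm]], dictionary)
  }
  mc <- measurementCodes()
  meas <- lapply(c("diameter", "surface_area", "volume"), function(nm) {
    key <- c(diameter = "diameter_mm", surface_area = "surface_area_mm2",
             volume = "volume_mm3")[[nm]]
    list(concept = mc[[nm]]$concept, value = measurements[[key]],
         unit = mc[[nm]]$unit)
  })
  new("MeasurementGroup", trackingId = conv@trackingId,
      trackingUID = conv@trackingUID,
      findingType = segmentationSemantics()$type,
      segmentUID = segmentUID, segmentNumber = as.integer(segmentNumber),
      sourceSeriesUID = sourceSeriesUID,
      evaluations = evals, measurements = meas)
}

#' Encode a measurement group as a DICOM SR TID 1500 document
#'
#' Produces a Comprehensive SR whose content tree is an Imaging Measurement
#' Report containing one measurement group: the tracking pair, the
#' referenced segment and source series, every qualitative evaluation as a
#' coded name-value pair, and the measurements as NUM items with UCUM
#' units.  Measurement values are serialized to 6 significant digits.
#'
#' @param group a [MeasurementGroup-class]; its segment reference must be
#'   set and every measurement unit must be UCUM-coded.
#' @param context named character vector of composite-context attributes
#'   (as in `ScanGeometry@context`).
#' @param file optional output path.
#' @param uidRoot root for the generated UIDs.
#' @return raw vector of the encoded object (invisibly when written).
#' @export
encodeSr <- function(group, context, file = NULL,
                     uidRoot = getOption("noduleSEG.uid_root", "2.25")) {
  if (!nzchar(group@segmentUID))
    stop("measurement group lacks a segment reference", call. = FALSE)
  for (m in group@measurements)
    if (m$unit@scheme != "UCUM")
      stop("measurement units must use the UCUM scheme, got '",
           m$unit@scheme, "'", call. = FALSE)

  groupChildren <- c(
    list(.srItem("HAS OBS CONTEXT", "TEXT",
                 codedConcept("112039", "DCM", "Tracking Identifier"),
                 list("0040,A160" = dcmEl("UT", group@trackingId))),
         .srItem("HAS OBS CONTEXT", "UIDREF",
                 codedConcept("112040", "DCM", "Tracking Unique Identifier"),
                 list("0040,A124" = dcmEl("UI", group@trackingUID))),
         .srItem("CONTAINS", "CODE",
                 codedConcept("121071", "DCM", "Finding"),
                 list("0040,A168" = dcmEl("SQ", list(
                   .codeItem(group@findingType))))),
         .srItem("CONTAINS", "IMAGE",
                 codedConcept("121191", "DCM", "Referenced Segment"),
                 list("0008,1199" = dcmEl("SQ", list(list(
                   "0008,1150" = dcmEl("UI", UID_SEG_STORAGE),
                   "0008,1155" = dcmEl("UI", group@segmentUID),
                   "0062,000B" = dcmEl("US", group@segmentNumber)))))),
         .srItem("CONTAINS", "UIDREF",
                 codedConcept("121232", "DCM",
                              "Source series for segmentation"),
                 list("0040,A124" = dcmEl("UI", group@sourceSeriesUID)))),
    lapply(group@evaluations, function(ev)
      .srItem("CONTAINS", "CODE", ev$concept,
              list("0040,A168" = dcmEl("SQ", list(.codeItem(ev$value)))))),
    lapply(group@measurements, function(m)
      .srItem("CONTAINS", "NUM", m$concept,
              list("0040,A300" = dcmEl("SQ", list(list(
                "0040,08EA" = dcmEl("SQ", list(.codeItem(m$unit))),
                "0040,A30A" = dcmEl("DS", signif(m$value, 6L)))))))))

  tree <- list(
    .srItem("HAS CONCEPT MOD", "CODE",
            codedConcept("121049", "DCM",
                         "Language of Content Item and Descendants"),
            list("0040,A168" = dcmEl("SQ", list(.codeItem(
              codedConcept("eng", "RFC5646", "English")))))),
    .srItem("CONTAINS", "CONTAINER",
            codedConcept("126010", "DCM", "Imaging Measurements"),
            list("0040,A050" = dcmEl("CS", "SEPARATE"),
                 "0040,A730" = dcmEl("SQ", list(
                   .srItem("CONTAINS", "CONTAINER",
                           codedConcept("125007", "DCM", "Measurement Group"),
                           list("0040,A050" = dcmEl("CS", "SEPARATE"),
                                "0040,A730" = dcmEl("SQ", groupChildren))))))))

  ds <- c(.contextElements(context), list(
    "0008,0016" = dcmEl("UI", UID_SR_COMPREHENSIVE),
    "0008,0018" = dcmEl("UI", genUID(uidRoot)),
    "0008,0021" = dcmEl("DA", .SEG_CONTENT_DATE),
    "0008,0023" = dcmEl("DA", .SEG_CONTENT_DATE),
    "0008,0031" = dcmEl("TM", .SEG_CONTENT_TIME),
    "0008,0033" = dcmEl("TM", .SEG_CONTENT_TIME),
    "0008,0060" = dcmEl("CS", "SR"),
    "0008,0070" = dcmEl("LO", "noduleSEG"),
    "0008,103E" = dcmEl("LO", paste("Measurements", group@trackingId)),
    "0020,000D" = dcmEl("UI", unname(context["StudyInstanceUID"])),
    "0020,000E" = dcmEl("UI", genUID(uidRoot)),
    "0020,0011" = dcmEl("IS", 400L),
    "0020,0013" = dcmEl("IS", 1L),
    "0040,A040" = dcmEl("CS", "CONTAINER"),
    "0040,A043" = dcmEl("SQ", list(.codeItem(codedConcept(
      "126000", "DCM", "Imaging Measurement Report")))),
    "0040,A050" = dcmEl("CS", "SEPARATE"),
    "0040,A491" = dcmEl("CS", "COMPLETE"),
    "0040,A493" = dcmEl("CS", "UNVERIFIED"),
    "0040,A504" = dcmEl("SQ", list(list(
      "0008,0105" = dcmEl("CS", "DCMR"),
      "0040,DB00" = dcmEl("CS", "1500")))),
    "0040,A730" = dcmEl("SQ", tree)))

  out <- dcmWrite(ds, path = file)
  if (is.null(file)) out else invisible(out)
}

#' Decode a TID 1500 SR document back into a measurement group
#'
#' @param x file path, raw vector, or parsed dataset of an SR emitted by
#'   [encodeSr()] (or any document following the same template profile).
#' @return a [MeasurementGroup-class]; non-conforming trees raise an error
#'   naming the missing node.
#' @export
decodeSr <- function(x) {
  ds <- if (is.raw(x) || is.character(x)) dcmRead(x) else x
  if (!identical(dcmGet(ds, "0008,0016"), UID_SR_COMPREHENSIVE))
    stop("not a Comprehensive SR document", call. = FALSE)
  rootConcept <- .codeFromItem(dcmGet(ds, "0040,A043")[[1L]])
  if (rootConcept@value != "126000")
    stop("SR root is not an Imaging Measurement Report", call. = FALSE)
  tree <- dcmGet(ds, "0040,A730")
  im <- .srFindChild(tree, "126010")
  if (is.null(im))
    stop("SR content tree lacks the 'Imaging Measurements' container",
         call. = FALSE)
  grp <- .srFindChild(dcmGet(im, "0040,A730"), "125007")
  if (is.null(grp))
    stop("SR contains no 'Measurement Group'", call. = FALSE)
  kids <- dcmGet(grp, "0040,A730")

  trackingId <- trackingUID <- ""
  findingType <- NULL; segUID <- ""; segNum <- 1L; srcSeries <- ""
  evals <- list(); meas <- list()
  for (it in kids) {
    cpt <- .srConcept(it)
    vt <- dcmGet(it, "0040,A040")
    if (cpt@value == "112039") trackingId <- dcmGet(it, "0040,A160", "")
    else if (cpt@value == "112040") trackingUID <- dcmGet(it, "0040,A124", "")
    else if (cpt@value == "121071")
      findingType <- .codeFromItem(dcmGet(it, "0040,A168")[[1L]])
    else if (cpt@value == "121191") {
      ref <- dcmGet(it, "0008,1199")[[1L]]
      segUID <- dcmGet(ref, "0008,1155", "")
      segNum <- as.integer(dcmGet(ref, "0062,000B", 1L))
    } else if (cpt@value == "121232") srcSeries <- dcmGet(it, "0040,A124", "")
    else if (vt == "CODE")
      evals[[length(evals) + 1L]] <- list(
        concept = cpt, value = .codeFromItem(dcmGet(it, "0040,A168")[[1L]]))
    else if (vt == "NUM") {
      mv <- dcmGet(it, "0040,A300")[[1L]]
      meas[[length(meas) + 1L]] <- list(
        concept = cpt,
        value = as.numeric(dcmGet(mv, "0040,A30A")),
        unit = .codeFromItem(dcmGet(mv, "0040,08EA")[[1L]]))
    }
  }
  if (is.null(findingType))
    stop("measurement group lacks the 'Finding' item", call. = FALSE)
  g <- new("MeasurementGroup", trackingId = trackingId,
           trackingUID = trackingUID, findingType = findingType,
           segmentUID = segUID, segmentNumber = segNum,
           sourceSeriesUID = srcSeries, evaluations = evals,
           measurements = meas)
  attr(g, "PatientID") <- unname(dcmGet(ds, "0010,0020", ""))
  g
}

#' Flatten a collection of SR documents into one table
#'
#' One row per annotation; subject, nodule number and annotation id (parsed
#' from the tracking label), the tracking UID, one column per
#' characteristic (the rating recovered through the code dictionary; `NA`
#' when absent) and the three measurement columns.
#'
#' @param srs list of SR payloads (file paths or raw vectors), or a
#'   character vector of paths.
#' @param dictionary code dictionary, `NULL` for the shipped one.
#' @return a `data.frame`; duplicate (tracking UID, annotation) pairs are
#'   an error.
#' @export
flattenEvaluations <- function(srs, dictionary = NULL) {
  if (is.character(srs)) srs <- as.list(srs)
  d <- dictionary %||% codeDictionary()
  ## value-code -> (attribute, rating) reverse map
  rev <- list()
  for (nm in names(d$attributes))
    for (v in d$attributes[[nm]]$values)
      rev[[v$value]] <- list(attribute = nm, rating = v$rating)
  measNames <- c("M-02550" = "diameter_mm", "C0JK" = "surface_area_mm2",
                 "G-D705" = "volume_mm3")
  rows <- lapply(srs, function(s) {
    g <- decodeSr(s)
    m <- regmatches(g@trackingId,
                    regexec("^Nodule ([0-9]+) - Annotation (.+)$", g@trackingId))[[1L]]
    nodule <- if (length(m)) as.integer(m[2L]) else NA_integer_
    annId <- if (length(m)) m[3L] else g@trackingId
    row <- data.frame(subject = attr(g, "PatientID"), nodule = nodule,
                      annotation = annId, tracking_uid = g@trackingUID,
                      stringsAsFactors = FALSE)
    for (nm in LIDC_CHARACTERISTICS) row[[nm]] <- NA_integer_
    for (ev in g@evaluations) {
      hit <- rev[[ev$value@value]]
      if (!is.null(hit)) row[[hit$attribute]] <- as.integer(hit$rating)
    }
    for (nm in unname(measNames)) row[[nm]] <- NA_real_
    for (me in g@measurements) {
      key <- measNames[me$concept@value]
      if (!is.na(key)) row[[key]] <- me$value
    }
    row
  })
  out <- do.call(rbind, rows)
  if (!is.null(out) && anyDuplicated(out[, c("tracking_uid", "annotation")]))
    stop("duplicate (tracking UID, annotation) pair in SR collection",
         call. = FALSE)
  out
}
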