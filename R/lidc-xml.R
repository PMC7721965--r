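#' Construct a ContourRoi
#'
#' @param points n x 2 matrix (or 2-column data) of 0-based integer
#'   `(x = column, y = row)` pixel indices, ordered along the contour.
#' @param zPos patient-space slice z coordinate in mm.
#' @param inclusion `TRUE` for an included region, `FALSE` for excluded.
#' @param sliceRef slice identifier (SOP instance UID); may be `""`.
#' @return a [ContourRoi-class].
#' @export
contourRoi <- function(points, zPos, inclusion = TRUE, sliceRef = "") {
  points <- matrix(as.integer(round(as.matrix(points))), ncol = 2L,
                   dimnames = list(NULL, c("x", "y")))
  new("ContourRoi", sliceRef = sliceRef, zPos = as.numeric(zPos),
      inclusion = inclusion, points = points)
}

#' Construct a NoduleAnnotation
#'
#' @param annotationId per-annotation identifier from the XML file.
#' @param rois list of [ContourRoi-class].
#' @param characteristics named integer vector of ratings (subset of the
#'   nine LIDC characteristics), or `NULL`.
#' @param sessionIndex reading-session ordinal (bookkeeping only).
#' @return a [NoduleAnnotation-class].
#' @export
noduleAnnotation <- function(annotationId, rois, characteristics = NULL,
                             sessionIndex = 1L) {
  ch <- if (is.null(characteristics)) {
    stats::setNames(integer(0), character(0))
  } else {
    stats::setNames(as.integer(characteristics), names(characteristics))
  }
  new("NoduleAnnotation", annotationId = as.character(annotationId),
      rois = rois, characteristics = ch, sessionIndex = as.integer(sessionIndex))
}

.parseCharacteristics <- function(node, annId) {
  out <- integer(0)
  for (nm in LIDC_CHARACTERISTICS) {
    v <- xml2::xml_text(xml2::xml_find_first(node, nm))
    if (is.na(v) || !nzchar(trimws(v))) next
    vi <- suppressWarnings(as.integer(trimws(v)))
    if (is.na(vi) || vi < 1L || vi > LIDC_RATING_MAX[[nm]]) {
      warning("annotation '", annId, "': ", nm, " rating '", v,
              "' outside the documented range; treated as unset",
              call. = FALSE)
      next
    }
    out[nm] <- vi
  }
  out
}

#' Parse a LIDC-dialect XML annotation file
#'
#' Reads all reading sessions in document order and returns every nodule
#' annotation they contain (volumetric or not; see [selectVolumetric()] for
#' the conversion filter).  Characteristics are parsed when present; ratings
#' outside the documented range raise a warning and are left unset.
#'
#' The supported dialect is `LidcReadMessage` with `readingSession` /
#' `unblindedReadNodule` / `roi` / `edgeMap` elements; see the annotated
#' sample in `inst/extdata/sample_annotation.xml`.
#'
#' @param path path to the XML file.
#' @return list of [NoduleAnnotation-class], in document order.
#' @export
parseAnnotationFile <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    stop("malformed XML in '", path, "': ", conditionMessage(e), call. = FALSE))
  root <- xml2::xml_name(doc)
  if (root != "LidcReadMessage")
    stop("unsupported annotation dialect: root element '", root,
         "' (expected 'LidcReadMessage')", call. = FALSE)
  xml2::xml_ns_strip(doc)
  anns <- list()
  sessions <- xml2::xml_find_all(doc, "./readingSession")
  for (si in seq_along(sessions)) {
    for (nod in xml2::xml_find_all(sessions[[si]], "./unblindedReadNodule")) {
      annId <- xml2::xml_text(xml2::xml_find_first(nod, "./noduleID"))
      chNode <- xml2::xml_find_first(nod, "./characteristics")
      ch <- if (inherits(chNode, "xml_missing")) integer(0)
            else .parseCharacteristics(chNode, annId)
      roiList <- lapply(xml2::xml_find_all(nod, "./roi"), function(r) {
        z <- as.numeric(xml2::xml_text(xml2::xml_find_first(r, "./imageZposition")))
        uid <- xml2::xml_text(xml2::xml_find_first(r, "./imageSOP_UID"))
        if (is.na(uid)) uid <- ""
        incl <- toupper(trimws(xml2::xml_text(
          xml2::xml_find_first(r, "./inclusion")))) %in% c("TRUE", "1", "YES")
        em <- xml2::xml_find_all(r, "./edgeMap")
        xs <- as.integer(xml2::xml_text(xml2::xml_find_all(em, "./xCoord")))
        ys <- as.integer(xml2::xml_text(xml2::xml_find_all(em, "./yCoord")))
        contourRoi(cbind(xs, ys), zPos = z, inclusion = incl, sliceRef = uid)
      })
      anns[[length(anns) + 1L]] <- noduleAnnotation(
        annId, roiList, if (length(ch)) ch else NULL, sessionIndex = si)
    }
  }
  ids <- vapply(anns, annotationId, character(1))
  if (anyDuplicated(ids))
    stop("duplicate annotation identifier(s) in '", path, "': ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  anns
}

#' Keep only volumetrically contoured annotations
#'
#' An annotation is volumetric when at least one of its included ROIs is a
#' genuine polygon (three or more points).  Center-of-mass marks (single
#' points) and degenerate two-point outlines are dropped; these correspond
#' to the finding categories that were never contoured volumetrically and
#' are not converted.
#'
#' @param annotations list of [NoduleAnnotation-class].
#' @return the volumetric subset, input order preserved.  Idempotent.
#' @export
selectVolumetric <- function(annotations) {
  keep <- vapply(annotations, function(a) {
    any(vapply(a@rois, function(r) r@inclusion && nrow(r@points) >= 3L,
               logical(1)))
  }, logical(1))
  annotations[keep]
}

#' Serialize annotations back to the LIDC XML dialect
#'
#' Writer counterpart of [parseAnnotationFile()]; parse-write-parse is the
#' identity on the supported dialect.  Used by the synthetic phantom
#' generator and for round-trip testing.
#'
#' @param annotations list of [NoduleAnnotation-class].
#' @param path output file path.
#' @param seriesUID optional CT series UID recorded in the response header.
#' @return `path`, invisibly.
#' @export
writeAnnotationXml <- function(annotations, path, seriesUID = "") {
  doc <- xml2::xml_new_root("LidcReadMessage", xmlns = "http://www.nih.gov")
  hdr <- xml2::xml_add_child(doc, "ResponseHeader")
  xml2::xml_add_child(hdr, "Version", "1.0")
  xml2::xml_add_child(hdr, "SeriesInstanceUid", seriesUID)
  bySession <- split(annotations,
                     vapply(annotations, function(a) a@sessionIndex, integer(1)))
  for (sess in bySession) {
    sn <- xml2::xml_add_child(doc, "readingSession")
    xml2::xml_add_child(sn, "annotationVersion", "3.12")
    for (a in sess) {
      nd <- xml2::xml_add_child(sn, "unblindedReadNodule")
      xml2::xml_add_child(nd, "noduleID", a@annotationId)
      if (length(a@characteristics)) {
        cn <- xml2::xml_add_child(nd, "characteristics")
        for (nm in LIDC_CHARACTERISTICS) {
          if (!is.na(a@characteristics[nm]) && nm %in% names(a@characteristics))
            xml2::xml_add_child(cn, nm, as.character(a@characteristics[[nm]]))
        }
      }
      for (r in a@rois) {
        rn <- xml2::xml_add_child(nd, "roi")
        xml2::xml_add_child(rn, "imageZposition", .fmtDS(r@zPos))
        xml2::xml_add_child(rn, "imageSOP_UID", r@sliceRef)
        xml2::xml_add_child(rn, "inclusion", if (r@inclusion) "TRUE" else "FALSE")
        for (i in seq_len(nrow(r@points))) {
          em <- xml2::xml_add_child(rn, "edgeMap")
          xml2::xml_add_child(em, "xCoord", as.character(r@points[i, 1L]))
          xml2::xml_add_child(em, "yCoord", as.character(r@points[i, 2L]))
        }
      }
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}
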