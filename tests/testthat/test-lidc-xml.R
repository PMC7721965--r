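## a handwritten file in the supported dialect, exercising sessions,
## characteristics, include/exclude flags and a center-only mark
sampleXml <- function(path, body) {
  writeLines(c('<?xml version="1.0" encoding="UTF-8"?>',
               '<LidcReadMessage xmlns="http://www.nih.gov">',
               "<ResponseHeader><Version>1.0</Version></ResponseHeader>",
               body, "</LidcReadMessage>"), path)
  path
}

roiXml <- function(z, uid, pts, inclusion = "TRUE") {
  paste0("<roi><imageZposition>", z, "</imageZposition><imageSOP_UID>", uid,
         "</imageSOP_UID><inclusion>", inclusion, "</inclusion>",
         paste0("<edgeMap><xCoord>", pts[, 1L], "</xCoord><yCoord>",
                pts[, 2L], "</yCoord></edgeMap>", collapse = ""), "</roi>")
}

test_that("sessions, nodules, ROIs and characteristics parse in document order", {
  ring <- ringPoints(5L, 5L, 5L, 5L)
  nod <- function(id, ch = "") paste0(
    "<unblindedReadNodule><noduleID>", id, "</noduleID>", ch,
    roiXml(0, "1.2.1", ring), roiXml(1, "1.2.2", ring),
    roiXml(2, "1.2.3", ring), "</unblindedReadNodule>")
  chBlock <- paste0("<characteristics><subtlety>4</subtlety>",
                    "<internalStructure>1</internalStructure>",
                    "<calcification>6</calcification>",
                    "<sphericity>3</sphericity><margin>5</margin>",
                    "<lobulation>2</lobulation><spiculation>1</spiculation>",
                    "<texture>5</texture><malignancy>3</malignancy>",
                    "</characteristics>")
  f <- sampleXml(withr::local_tempfile(fileext = ".xml"), c(
    paste0("<readingSession>", nod("A-1", chBlock), "</readingSession>"),
    paste0("<readingSession>", nod("B-1"), "</readingSession>")))
  anns <- parseAnnotationFile(f)
  expect_length(anns, 2L)
  expect_equal(vapply(anns, annotationId, character(1)), c("A-1", "B-1"))
  expect_equal(vapply(anns, function(a) length(rois(a)), integer(1)), c(3L, 3L))
  expect_equal(vapply(anns, function(a) a@sessionIndex, integer(1)), 1:2)
  expect_equal(characteristics(anns[[1L]])[["malignancy"]], 3L)
  expect_length(characteristics(anns[[1L]]), 9L)
  expect_length(characteristics(anns[[2L]]), 0L)
  expect_false(rois(anns[[1L]])[[1L]]@inclusion == FALSE)
})

test_that("a session with zero nodules yields an empty list", {
  f <- sampleXml(withr::local_tempfile(fileext = ".xml"),
                 "<readingSession></readingSession>")
  expect_length(parseAnnotationFile(f), 0L)
})

test_that("an annotation missing one rating parses with 8 of 9 set", {
  ## mirrors the one annotation in the source collection that lacks the
  ## internal-structure assessment
  ring <- ringPoints(3L, 3L, 5L, 5L)
  ch <- paste0("<characteristics><subtlety>5</subtlety>",
               "<calcification>6</calcification><sphericity>4</sphericity>",
               "<margin>4</margin><lobulation>1</lobulation>",
               "<spiculation>2</spiculation><texture>5</texture>",
               "<malignancy>3</malignancy></characteristics>")
  f <- sampleXml(withr::local_tempfile(fileext = ".xml"), paste0(
    "<readingSession><unblindedReadNodule><noduleID>1708</noduleID>", ch,
    roiXml(0, "1.2.1", ring), "</unblindedReadNodule></readingSession>"))
  anns <- parseAnnotationFile(f)
  expect_length(characteristics(anns[[1L]]), 8L)
  expect_false("internalStructure" %in% names(characteristics(anns[[1L]])))
})

test_that("malformed XML and unknown dialects raise distinct errors", {
  bad <- withr::local_tempfile(fileext = ".xml")
  writeLines("<LidcReadMessage><unclosed>", bad)
  expect_error(parseAnnotationFile(bad), "malformed XML")
  other <- withr::local_tempfile(fileext = ".xml")
  writeLines("<SomeOtherRoot><a/></SomeOtherRoot>", other)
  expect_error(parseAnnotationFile(other), "unsupported annotation dialect")
})

test_that("out-of-range ratings warn and are treated as unset", {
  ring <- ringPoints(3L, 3L, 5L, 5L)
  ch <- "<characteristics><subtlety>9</subtlety><margin>4</margin></characteristics>"
  f <- sampleXml(withr::local_tempfile(fileext = ".xml"), paste0(
    "<readingSession><unblindedReadNodule><noduleID>X</noduleID>", ch,
    roiXml(0, "1.2.1", ring), "</unblindedReadNodule></readingSession>"))
  expect_warning(anns <- parseAnnotationFile(f), "outside the documented range")
  expect_equal(names(characteristics(anns[[1L]])), "margin")
})

test_that("volumetric selection drops center marks and degenerate outlines", {
  g <- mkGeometry()
  poly <- noduleAnnotation("P", list(
    contourRoi(ringPoints(2L, 2L, 6L, 6L), 0, sliceRef = "1.2.840.99.1")))
  mark <- noduleAnnotation("M", list(
    contourRoi(cbind(10L, 10L), 0, sliceRef = "1.2.840.99.1")))
  twoPt <- noduleAnnotation("D", list(
    contourRoi(cbind(c(1L, 2L), c(1L, 1L)), 0, sliceRef = "1.2.840.99.1")))
  exclOnly <- noduleAnnotation("E", list(
    contourRoi(ringPoints(2L, 2L, 5L, 5L), 0, inclusion = FALSE,
               sliceRef = "1.2.840.99.1")))
  kept <- selectVolumetric(list(poly, mark, twoPt, exclOnly))
  expect_equal(vapply(kept, annotationId, character(1)), "P")
  expect_length(selectVolumetric(list()), 0L)
  ## idempotence
  expect_identical(selectVolumetric(kept), kept)
})

test_that("write-parse round trip preserves annotations structurally", {
  set.seed(11)
  g <- mkGeometry(nSlices = 6L)
  anns <- list(
    noduleAnnotation("101", list(
      contourRoi(ringPoints(4L, 4L, 7L, 7L), 1, sliceRef = "1.2.840.99.2"),
      contourRoi(ringPoints(5L, 5L, 5L, 5L), 2, inclusion = FALSE,
                 sliceRef = "1.2.840.99.3")),
      characteristics = c(subtlety = 4L, malignancy = 3L), sessionIndex = 1L),
    noduleAnnotation("202", list(
      contourRoi(ringPoints(10L, 10L, 4L, 4L), 3, sliceRef = "1.2.840.99.4")),
      characteristics = stats::setNames(
        c(1L, 2L, 6L, 3L, 5L, 1L, 2L, 4L, 5L),
        c("subtlety", "internalStructure", "calcification", "sphericity",
          "margin", "lobulation", "spiculation", "texture", "malignancy")),
      sessionIndex = 2L))
  f <- withr::local_tempfile(fileext = ".xml")
  writeAnnotationXml(anns, f, seriesUID = "1.2.3")
  back <- parseAnnotationFile(f)
  expect_length(back, 2L)
  for (i in 1:2) {
    expect_equal(annotationId(back[[i]]), annotationId(anns[[i]]))
    expect_equal(length(rois(back[[i]])), length(rois(anns[[i]])))
    expect_equal(characteristics(back[[i]])[sort(names(characteristics(back[[i]])))],
                 characteristics(anns[[i]])[sort(names(characteristics(anns[[i]])))])
    for (j in seq_along(rois(back[[i]]))) {
      expect_equal(unname(rois(back[[i]])[[j]]@points),
                   unname(rois(anns[[i]])[[j]]@points))
      expect_equal(rois(back[[i]])[[j]]@inclusion, rois(anns[[i]])[[j]]@inclusion)
      expect_equal(rois(back[[i]])[[j]]@zPos, rois(anns[[i]])[[j]]@zPos)
    }
  }
})

test_that("the shipped annotated sample file parses as documented", {
  f <- system.file("extdata", "sample_annotation.xml", package = "noduleSEG")
  anns <- parseAnnotationFile(f)
  expect_length(anns, 2L)
  expect_equal(vapply(anns, annotationId, character(1)), c("101", "201"))
  expect_length(characteristics(anns[[1L]]), 9L)
  ## the second entry is a center-only mark and is never converted
  expect_equal(vapply(selectVolumetric(anns), annotationId, character(1)),
               "101")
})
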