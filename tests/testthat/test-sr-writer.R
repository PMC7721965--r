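srFixture <- function(dropInternalStructure = FALSE) {
  g <- mkGeometry()
  ch <- stats::setNames(c(4L, 1L, 6L, 3L, 5L, 2L, 1L, 5L, 3L),
                        noduleSEG:::LIDC_CHARACTERISTICS)
  if (dropInternalStructure) ch <- ch[names(ch) != "internalStructure"]
  ann <- noduleAnnotation("101", list(
    contourRoi(ringPoints(4L, 4L, 5L, 5L), 0, sliceRef = "1.2.840.99.1")),
    characteristics = ch)
  conv <- segConventions(1L, "101", "2.25.777", ordinal = 1L)
  meas <- list(diameter_mm = 11.25, surface_area_mm2 = 402.1234567,
               volume_mm3 = 905.881)
  grp <- buildMeasurementGroup(ann, conv, meas, segmentUID = "1.2.3.77",
                               sourceSeriesUID = g@seriesUID)
  list(g = g, grp = grp, conv = conv, meas = meas)
}

test_that("a fully characterized annotation encodes 9 evaluations and 3 measurements", {
  fx <- srFixture()
  expect_length(fx$grp@evaluations, 9L)
  expect_length(fx$grp@measurements, 3L)
  back <- decodeSr(encodeSr(fx$grp, fx$g@context))
  expect_length(back@evaluations, 9L)
  expect_length(back@measurements, 3L)
  expect_equal(trackingUID(back), "2.25.777")
  expect_equal(back@trackingId, fx$grp@trackingId)
})

test_that("the exception-style annotation encodes 8 evaluations", {
  fx <- srFixture(dropInternalStructure = TRUE)
  back <- decodeSr(encodeSr(fx$grp, fx$g@context))
  expect_length(back@evaluations, 8L)
  concepts <- vapply(back@evaluations, function(e) codeMeaning(e$concept),
                     character(1))
  expect_false("Internal structure" %in% concepts)
})

test_that("decode(encode(g)) recovers the group", {
  fx <- srFixture()
  back <- decodeSr(encodeSr(fx$grp, fx$g@context))
  expect_equal(back@segmentUID, fx$grp@segmentUID)
  expect_equal(back@segmentNumber, fx$grp@segmentNumber)
  expect_equal(back@sourceSeriesUID, fx$grp@sourceSeriesUID)
  expect_equal(codeValue(back@findingType), codeValue(fx$grp@findingType))
  for (i in seq_along(fx$grp@evaluations)) {
    expect_equal(codeValue(back@evaluations[[i]]$value),
                 codeValue(fx$grp@evaluations[[i]]$value))
    expect_equal(codeMeaning(back@evaluations[[i]]$value),
                 codeMeaning(fx$grp@evaluations[[i]]$value))
  }
  ## numeric values round-trip at the documented 6 significant digits
  for (i in seq_along(fx$grp@measurements)) {
    expect_equal(back@measurements[[i]]$value,
                 signif(fx$grp@measurements[[i]]$value, 6L))
    expect_equal(codeScheme(back@measurements[[i]]$unit), "UCUM")
  }
  ## surface-area unit comes back as (mm2, UCUM)
  sa <- Filter(function(m) codeValue(m$concept) == "C0JK",
               back@measurements)[[1L]]
  expect_equal(codeValue(sa$unit), "mm2")
})

test_that("structural preconditions are enforced", {
  fx <- srFixture()
  broken <- fx$grp
  broken@segmentUID <- ""
  expect_error(encodeSr(broken, fx$g@context), "segment reference")
  nonUcum <- fx$grp
  nonUcum@measurements[[1L]]$unit <- codedConcept("mm", "DCM", "millimeter")
  expect_error(encodeSr(nonUcum, fx$g@context), "UCUM")
  ## an SR whose tree lacks any measurement group is a structured error
  dcmEl <- noduleSEG:::dcmEl
  bytes <- encodeSr(fx$grp, fx$g@context)
  ds <- dcmRead(bytes)
  tree <- ds[["0040,A730"]]$value
  keep <- Filter(function(it)
    noduleSEG:::.srConcept(it)@value != "126010", tree)
  ds[["0040,A730"]] <- dcmEl("SQ", keep)
  expect_error(decodeSr(dcmWrite(ds)), "Imaging Measurements")
})

test_that("flattening reproduces the encoded values exactly", {
  fx1 <- srFixture()
  fx2 <- srFixture(dropInternalStructure = TRUE)
  grp2 <- fx2$grp
  grp2@trackingId <- "Nodule 2 - Annotation 205"
  grp2@trackingUID <- "2.25.888"
  srs <- list(encodeSr(fx1$grp, fx1$g@context),
              encodeSr(grp2, fx2$g@context))
  tab <- flattenEvaluations(srs)
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$annotation, c("101", "205"))
  expect_equal(tab$nodule, c(1L, 2L))
  expect_equal(tab$subject, rep("TEST-0001", 2L))
  expect_equal(tab$malignancy, c(3L, 3L))
  ## the exception-style SR yields exactly one null characteristic cell
  chCols <- noduleSEG:::LIDC_CHARACTERISTICS
  expect_equal(sum(is.na(unlist(tab[2L, chCols]))), 1L)
  expect_true(is.na(tab$internalStructure[2L]))
  expect_equal(sum(is.na(unlist(tab[1L, chCols]))), 0L)
  expect_equal(tab$diameter_mm, rep(11.25, 2L))
  expect_equal(tab$volume_mm3, rep(signif(905.881, 6L), 2L))
  ## duplicate tracking pair is refused
  expect_error(flattenEvaluations(list(srs[[1L]], srs[[1L]])), "duplicate")
})

test_that("emitted SRs pass the independent pydicom validator", {
  expect_true(pythonValidatorAvailable())
  fx <- srFixture()
  tmp <- withr::local_tempfile(fileext = ".dcm")
  encodeSr(fx$grp, fx$g@context, file = tmp)
  script <- system.file("py", "validate_dicom.py", package = "noduleSEG")
  out <- suppressWarnings(system2(Sys.which("python"), c(script, tmp),
                                  stdout = TRUE, stderr = TRUE))
  expect_equal(if (is.null(attr(out, "status"))) 0L else attr(out, "status"),
               0L, info = paste(out, collapse = "\n"))
})
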