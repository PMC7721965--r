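segFixture <- function() {
  g <- mkGeometry(nSlices = 8L, shape = c(32L, 32L), spacing = c(0.7, 0.7),
                  step = 2.5)
  vol <- array(FALSE, dim = c(32L, 32L, 8L))
  vol[10:14, 10:15, 3:5] <- TRUE
  vol[12, 12, 4] <- FALSE  # a hole, to make the bit pattern non-trivial
  mask <- new("MaskVolume", voxels = vol, geometry = g, nonemptySlices = 3:5)
  conv <- segConventions(1L, "101", "2.25.4242", ordinal = 1L)
  list(g = g, mask = mask, conv = conv)
}

test_that("display color conversion hits the CIELab anchor points", {
  expect_equal(rgbToCielab16(c(255L, 255L, 255L)), c(0xFFFF, 0x8080, 0x8080))
  expect_equal(rgbToCielab16(c(0L, 0L, 0L)), c(0x0000, 0x8080, 0x8080))
  ## pure red against an independently computed D50/Bradford reference
  expect_equal(rgbToCielab16(c(255L, 0L, 0L)), c(35580L, 53665L, 50856L),
               tolerance = 1e-8)
  ## inverse recovers the byte triple for the whole palette
  for (col in noduleSEG:::SEG_PALETTE)
    expect_equal(cielab16ToRgb(rgbToCielab16(col)), col)
})

test_that("encode/decode round trip is voxel-identical with metadata intact", {
  fx <- segFixture()
  bytes <- encodeSeg(fx$mask, fx$conv)
  dec <- decodeSeg(bytes, fx$g)
  expect_identical(dec$mask@voxels, fx$mask@voxels)
  expect_equal(nonemptySlices(dec$mask), 3:5)
  expect_equal(dec$conventions@seriesDescription, "Nodule 1 - Annotation 101")
  expect_equal(dec$conventions@segmentLabel, "Nodule 1 - Annotation 101")
  expect_equal(trackingUID(dec$conventions), "2.25.4242")
  expect_equal(dec$conventions@displayColor, fx$conv@displayColor)
})

test_that("only non-empty slices become frames", {
  fx <- segFixture()
  ds <- dcmRead(encodeSeg(fx$mask, fx$conv))
  expect_equal(as.integer(dcmGet(ds, "0028,0008")), 3L)  # 3 of 8 slices
  pf <- dcmGet(ds, "5200,9230")
  expect_length(pf, 3L)
  zs <- vapply(pf, function(fr)
    dcmGet(fr[["0020,9113"]]$value[[1L]], "0020,0032")[3L], numeric(1))
  expect_equal(zs, fx$g@slicePositions[3:5])
  ## every frame references its source CT instance
  srcs <- vapply(pf, function(fr) {
    src <- fr[["0008,9124"]]$value[[1L]][["0008,2112"]]$value[[1L]]
    dcmGet(src, "0008,1155")
  }, character(1))
  expect_equal(srcs, names(sliceTable(fx$g))[3:5])
})

test_that("segment semantics and composite context are carried verbatim", {
  fx <- segFixture()
  ds <- dcmRead(encodeSeg(fx$mask, fx$conv))
  seg <- dcmGet(ds, "0062,0002")[[1L]]
  cat0 <- dcmGet(seg, "0062,0003")[[1L]]
  typ0 <- dcmGet(seg, "0062,000F")[[1L]]
  ana0 <- dcmGet(seg, "0008,2218")[[1L]]
  expect_equal(dcmGet(cat0, "0008,0100"), "M-01000")
  expect_equal(dcmGet(typ0, "0008,0100"), "M-03010")
  expect_equal(dcmGet(ana0, "0008,0100"), "T-28000")
  expect_equal(dcmGet(ds, "0010,0020"), "TEST-0001")
  expect_equal(dcmGet(ds, "0020,000D"), "1.2.840.99.0.1")
  expect_equal(dcmGet(ds, "0020,0052"), fx$g@frameUID)
  ## numeric SCT alternative
  ds2 <- dcmRead(encodeSeg(fx$mask, fx$conv, sct = TRUE))
  seg2 <- dcmGet(ds2, "0062,0002")[[1L]]
  expect_equal(dcmGet(dcmGet(seg2, "0062,000F")[[1L]], "0008,0100"),
               "27925004")
})

test_that("missing source references and foreign geometries are refused", {
  fx <- segFixture()
  refs <- character(8L)
  refs[sliceTable(fx$g)] <- names(sliceTable(fx$g))
  refs[4L] <- ""
  expect_error(encodeSeg(fx$mask, fx$conv, ctRefs = refs),
               "reference missing")
  bytes <- encodeSeg(fx$mask, fx$conv)
  other <- mkGeometry(nSlices = 8L, shape = c(32L, 32L), spacing = c(0.7, 0.7),
                      step = 2.5)
  other@frameUID <- "9.9.9.9"
  expect_error(decodeSeg(bytes, other), "frame of reference")
})

test_that("annotations of one nodule get pairwise distinct colors", {
  cols <- lapply(1:6, function(i) segConventions(1L, as.character(i),
                                                 "2.25.1", ordinal = i))
  rgb <- vapply(cols, function(cc) paste(cc@displayColor, collapse = ","),
                character(1))
  expect_equal(anyDuplicated(rgb), 0L)
})

test_that("emitted SEGs pass the independent pydicom validator", {
  expect_true(pythonValidatorAvailable())
  fx <- segFixture()
  tmp <- withr::local_tempfile(fileext = ".dcm")
  encodeSeg(fx$mask, fx$conv, file = tmp)
  script <- system.file("py", "validate_dicom.py", package = "noduleSEG")
  out <- suppressWarnings(system2(Sys.which("python"), c(script, tmp),
                                  stdout = TRUE, stderr = TRUE))
  expect_equal(if (is.null(attr(out, "status"))) 0L else attr(out, "status"), 0L,
               info = paste(out, collapse = "\n"))
})
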