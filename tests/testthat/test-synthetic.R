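test_that("phantom validation rejects impossible specs", {
  expect_error(phantomSpec(nodules = list(
    list(center = c(2, 2, 2), radius = 6))), "protrudes")
  expect_error(phantomSpec(nodules = list(
    list(center = c(40, 40, 20), radius = 0.5))), "below 2 voxels")
})

test_that("the generated series reproduces the spec geometry exactly", {
  spec <- phantomSpec(imageShape = c(32L, 32L), pixelSpacing = c(0.7, 0.7),
                      sliceStep = 2.5, nSlices = 20L,
                      nodules = list(list(center = c(11, 11, 24), radius = 4,
                                          nReaders = 1, jitter = 0)),
                      seed = 5L)
  d <- withr::local_tempdir()
  gt <- generateCtSeries(spec, d)
  g <- buildGeometry(d)
  expect_equal(pixelSpacing(g), c(0.7, 0.7))
  expect_equal(diff(slicePositions(g)), rep(2.5, 19L))
  expect_length(sliceTable(g), 20L)
  ## analytic voxel positions are reproduced exactly
  expect_equal(voxelToPatient(g, c(3, 5, 2)), c(3 * 0.7, 5 * 0.7, 5.0))
})

test_that("a fixed seed makes both generators byte-identical", {
  spec <- phantomSpec(imageShape = c(24L, 24L), pixelSpacing = c(1, 1),
                      sliceStep = 2, nSlices = 12L,
                      nodules = list(list(center = c(11, 11, 11), radius = 3.5,
                                          nReaders = 2, jitter = 0.3)),
                      seed = 42L)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generateCtSeries(spec, d1); generateCtSeries(spec, d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), raw(), file.size(file.path(d1, f))),
                     readBin(file.path(d2, f), raw(), file.size(file.path(d2, f))),
                     label = f)
  }
  g <- buildGeometry(d1)
  x1 <- file.path(d1, "a.xml"); x2 <- file.path(d1, "b.xml")
  generateAnnotations(spec, g, x1)
  generateAnnotations(spec, g, x2)
  expect_identical(readLines(x1), readLines(x2))
})

test_that("generated contours rasterize to the analytic sphere (Dice >= 0.95)", {
  spec <- phantomSpec(imageShape = c(48L, 48L), pixelSpacing = c(1, 1),
                      sliceStep = 1, nSlices = 30L,
                      nodules = list(list(center = c(23, 23, 14), radius = 7,
                                          nReaders = 1, jitter = 0)),
                      seed = 9L)
  d <- withr::local_tempdir()
  generateCtSeries(spec, d)
  g <- buildGeometry(d)
  anns <- generateAnnotations(spec, g, NULL)
  m <- buildMask(anns[[1L]], g)
  truth <- analyticSphereMask(g, c(23, 23, 14), 7)
  inter <- sum(voxels(m) & voxels(truth))
  dice <- 2 * inter / (sum(voxels(m)) + sum(voxels(truth)))
  expect_gte(dice, 0.95)
})

test_that("reader multiplicity and center marks flow through as designed", {
  spec <- phantomSpec(imageShape = c(64L, 64L), pixelSpacing = c(1, 1),
                      sliceStep = 2, nSlices = 16L,
                      nodules = list(
                        list(center = c(16, 16, 14), radius = 5, nReaders = 4,
                             jitter = 0.4),
                        list(center = c(46, 46, 18), radius = 5, nReaders = 2,
                             jitter = 0.4)),
                      centerMarks = 1L, seed = 13L)
  d <- withr::local_tempdir()
  generateCtSeries(spec, d)
  g <- buildGeometry(d)
  generateAnnotations(spec, g, file.path(d, "ann.xml"))
  anns <- parseAnnotationFile(file.path(d, "ann.xml"))
  expect_length(anns, 7L)  # 4 + 2 readers + 1 center mark
  vol <- selectVolumetric(anns)
  expect_length(vol, 6L)   # the center-only mark is parsed but dropped
  expect_true("CM1" %in% vapply(anns, annotationId, character(1)))
  expect_false("CM1" %in% vapply(vol, annotationId, character(1)))
  ## one cluster per physical nodule; the 4-reader nodule clusters as 4
  cl <- clusterAnnotations(vol, g)
  expect_length(cl, 2L)
  expect_setequal(vapply(cl, function(c) length(members(c)), integer(1)),
                  c(4L, 2L))
})
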