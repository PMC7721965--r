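test_that("worked ring examples match the strict-interior oracle", {
  shape <- c(16L, 16L)
  ## ring tracing the border pixels of a 5x5 block -> 3x3 interior
  r5 <- ringPoints(4L, 4L, 5L, 5L)
  m5 <- rasterizeRoi(r5, shape)
  expect_equal(sum(m5), 9L)
  expect_equal(m5, oracleRoiMask(r5, shape))
  ## smallest closed ring: 3x3 -> single center pixel
  r3 <- ringPoints(4L, 4L, 3L, 3L)
  m3 <- rasterizeRoi(r3, shape)
  expect_equal(sum(m3), 1L)
  expect_true(m3[6L, 6L])  # 0-based (5, 5) center
  ## 9x9 included minus centered 5x5 excluded -> 49 - 9 = 40
  g <- mkGeometry(nSlices = 3L, shape = shape)
  ann <- noduleAnnotation("ex", list(
    contourRoi(ringPoints(3L, 3L, 9L, 9L), 0, sliceRef = "1.2.840.99.1"),
    contourRoi(ringPoints(5L, 5L, 5L, 5L), 0, inclusion = FALSE,
               sliceRef = "1.2.840.99.1")))
  mv <- buildMask(ann, g)
  expect_equal(sum(voxels(mv)), 40L)
  expect_equal(nonemptySlices(mv), 1L)
})

test_that("degenerate contours error; self-intersection warns", {
  expect_error(rasterizeRoi(cbind(c(1L, 2L), c(1L, 1L)), c(8L, 8L)),
               "degenerate")
  expect_error(rasterizeRoi(cbind(1:3, 1:3), c(8L, 8L)), "collinear")
  bow <- cbind(c(1L, 6L, 6L, 1L), c(1L, 5L, 1L, 5L))  # bow-tie
  expect_warning(rasterizeRoi(bow, c(8L, 8L)), "self-intersecting")
})

test_that("mask equals the brute-force oracle on randomized blobs", {
  set.seed(101)
  shape <- c(24L, 24L)
  for (i in 1:40) {
    b <- randomBlobRing(shape)
    if (is.null(b) || nrow(b$ring) < 3L) next
    m <- rasterizeRoi(b$ring, shape)
    expect_identical(m, oracleRoiMask(b$ring, shape))
    ## no contour pixel is ever foreground
    expect_false(any(m[b$ring + 1L]))
  }
})

test_that("foreground is invariant to point reversal and rotation", {
  set.seed(202)
  shape <- c(24L, 24L)
  for (i in 1:10) {
    b <- randomBlobRing(shape)
    if (is.null(b) || nrow(b$ring) < 4L) next
    m <- rasterizeRoi(b$ring, shape)
    expect_identical(rasterizeRoi(b$ring[rev(seq_len(nrow(b$ring))), ], shape), m)
    rot <- b$ring[c(3:nrow(b$ring), 1:2), ]
    expect_identical(rasterizeRoi(rot, shape), m)
  }
})

test_that("build_mask honours include/exclude semantics across slices", {
  g <- mkGeometry(nSlices = 5L, shape = c(16L, 16L))
  uid <- function(k) names(sliceTable(g))[match(k, sliceTable(g))]
  ## 3 consecutive slices each carrying the 5x5 ring -> 27 voxels
  ann <- noduleAnnotation("stack", lapply(2:4, function(k)
    contourRoi(ringPoints(4L, 4L, 5L, 5L), g@slicePositions[k],
               sliceRef = uid(k))))
  mv <- buildMask(ann, g)
  expect_equal(sum(voxels(mv)), 27L)
  expect_equal(nonemptySlices(mv), 2:4)
  ## an excluded ROI alone contributes nothing on its slice
  ann2 <- noduleAnnotation("mix", list(
    contourRoi(ringPoints(4L, 4L, 5L, 5L), 0, sliceRef = uid(1L)),
    contourRoi(ringPoints(4L, 4L, 7L, 7L), 1, inclusion = FALSE,
               sliceRef = uid(2L))))
  mv2 <- buildMask(ann2, g)
  expect_equal(nonemptySlices(mv2), 1L)
  ## unresolvable slice reference errors naming it
  ann3 <- noduleAnnotation("bad", list(
    contourRoi(ringPoints(4L, 4L, 5L, 5L), 0, sliceRef = "9.9.9")))
  expect_error(buildMask(ann3, g), "9\\.9\\.9")
  ## all-excluded annotation: empty volume is an error
  ann4 <- noduleAnnotation("empty", list(
    contourRoi(ringPoints(4L, 4L, 5L, 5L), 0, inclusion = FALSE,
               sliceRef = uid(1L))))
  expect_error(buildMask(ann4, g), "empty mask volume")
})

test_that("adding an excluded ROI never increases the foreground", {
  set.seed(303)
  g <- mkGeometry(nSlices = 3L, shape = c(24L, 24L))
  uid1 <- names(sliceTable(g))[match(1L, sliceTable(g))]
  for (i in 1:10) {
    b1 <- randomBlobRing(c(24L, 24L)); b2 <- randomBlobRing(c(24L, 24L))
    if (is.null(b1) || is.null(b2) ||
        nrow(b1$ring) < 3L || nrow(b2$ring) < 3L) next
    inc <- contourRoi(b1$ring, 0, sliceRef = uid1)
    exc <- contourRoi(b2$ring, 0, inclusion = FALSE, sliceRef = uid1)
    base <- tryCatch(buildMask(noduleAnnotation("a", list(inc)), g),
                     error = function(e) NULL)
    if (is.null(base)) next
    both <- tryCatch(buildMask(noduleAnnotation("b", list(inc, exc)), g),
                     error = function(e) NULL)
    n2 <- if (is.null(both)) 0L else sum(voxels(both))
    expect_lte(n2, sum(voxels(base)))
  }
})
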