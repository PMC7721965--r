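test_that("annotation distance: identity, 3-4-5, symmetry", {
  g <- mkGeometry(nSlices = 5L, shape = c(32L, 32L), spacing = c(1, 1),
                  step = 1)
  a <- pointAnnotation("a", 0L, 0L, 1L, g)
  b <- pointAnnotation("b", 3L, 4L, 1L, g)
  expect_equal(annotationDistance(a, a, g), 0)
  expect_equal(annotationDistance(a, b, g), 5)
  set.seed(7)
  for (i in 1:8) {
    p <- pointAnnotation("p", sample(0:31, 1), sample(0:31, 1),
                         sample(1:5, 1), g)
    q <- pointAnnotation("q", sample(0:31, 1), sample(0:31, 1),
                         sample(1:5, 1), g)
    expect_equal(annotationDistance(p, q, g), annotationDistance(q, p, g))
  }
  empty <- new("NoduleAnnotation", annotationId = "none", rois = list(),
               characteristics = stats::setNames(integer(0), character(0)),
               sessionIndex = 1L)
  expect_error(annotationDistance(empty, a, g), "no contour points")
})

test_that("a chain merges under single linkage even when its ends are far", {
  g <- mkGeometry(nSlices = 3L, shape = c(64L, 64L), spacing = c(1, 1))
  A <- pointAnnotation("A", 10L, 10L, 1L, g)
  B <- pointAnnotation("B", 11L, 10L, 1L, g)  # 1 mm from A
  C <- pointAnnotation("C", 12L, 10L, 1L, g)  # 1 mm from B, 2 mm from A
  D <- pointAnnotation("D", 40L, 10L, 1L, g)  # 28+ mm away
  cl <- clusterAnnotations(list(A, B, C, D), g, tol = 1.5)
  expect_length(cl, 2L)
  expect_setequal(vapply(members(cl[[1L]]), annotationId, character(1)),
                  c("A", "B", "C"))
  expect_equal(vapply(cl, noduleNumber, integer(1)), 1:2)
})

test_that("clustering matches the union-find oracle on random fixtures", {
  set.seed(17)
  g <- mkGeometry(nSlices = 4L, shape = c(64L, 64L), spacing = c(1, 1))
  for (rep in 1:10) {
    n <- sample(4:8, 1L)
    anns <- lapply(seq_len(n), function(i)
      pointAnnotation(sprintf("a%d", i), sample(0:63, 1), sample(0:63, 1),
                      sample(1:4, 1), g))
    tol <- runif(1, 1, 12)
    D <- matrix(0, n, n)
    for (i in 1:n) for (j in 1:n)
      D[i, j] <- annotationDistance(anns[[i]], anns[[j]], g)
    oracle <- unionFindClusters(D, tol)
    got <- clusterAnnotations(anns, g, tol = tol)
    lab <- integer(n)
    for (cl in got) lab[cl@memberIndex] <- noduleNumber(cl)
    ## same partition up to renumbering; both number by first appearance
    expect_equal(lab, oracle)
  }
})

test_that("raising the tolerance never increases the cluster count", {
  set.seed(23)
  g <- mkGeometry(nSlices = 4L, shape = c(64L, 64L), spacing = c(1, 1))
  anns <- lapply(1:7, function(i)
    pointAnnotation(sprintf("a%d", i), sample(0:63, 1), sample(0:63, 1),
                    sample(1:4, 1), g))
  counts <- vapply(c(0.5, 2, 5, 10, 25, 80), function(tol)
    length(clusterAnnotations(anns, g, tol = tol)), integer(1))
  expect_true(all(diff(counts) <= 0L))
  expect_equal(counts[length(counts)], 1L)
})

test_that("tracking UIDs are shared within and distinct across clusters", {
  g <- mkGeometry(nSlices = 3L, shape = c(64L, 64L), spacing = c(1, 1))
  near <- lapply(1:5, function(i)  # 5 members: clusters may exceed 4
    pointAnnotation(sprintf("n%d", i), 10L + i %% 2L, 10L, 1L, g))
  far <- pointAnnotation("f", 50L, 50L, 1L, g)
  cl <- clusterAnnotations(c(near, list(far)), g, tol = 2)
  expect_length(cl, 2L)
  expect_equal(length(members(cl[[1L]])), 5L)
  uids <- vapply(cl, trackingUID, character(1))
  expect_false(anyDuplicated(uids) > 0)
  expect_true(all(nzchar(uids)))
})

test_that("member sets are invariant to input order", {
  set.seed(31)
  g <- mkGeometry(nSlices = 3L, shape = c(64L, 64L), spacing = c(1, 1))
  anns <- lapply(1:6, function(i)
    pointAnnotation(sprintf("a%d", i), sample(0:63, 1), sample(0:63, 1), 1L, g))
  part <- function(cl) {
    sets <- lapply(cl, function(c)
      sort(vapply(members(c), annotationId, character(1))))
    sets[order(vapply(sets, `[`, character(1), 1L))]
  }
  p1 <- part(clusterAnnotations(anns, g, tol = 6))
  p2 <- part(clusterAnnotations(rev(anns), g, tol = 6))
  expect_equal(p1, p2)
})
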