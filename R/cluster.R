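## gather all contour points of an annotation as patient-space coordinates
.annotationPoints <- function(a, g) {
  if (length(a@rois) == 0L) stop("annotation '", a@annotationId,
                                 "' has no contour points", call. = FALSE)
  pts <- do.call(rbind, lapply(a@rois, function(r) {
    k <- .resolveSlice(g, r)
    cbind(r@points[, 1L], r@points[, 2L], k - 1L)
  }))
  if (nrow(pts) == 0L) stop("annotation '", a@annotationId,
                            "' has no contour points", call. = FALSE)
  voxelToPatient(g, pts)
}

#' Minimum patient-space distance between two annotations
#'
#' The distance used for clustering: the minimum Euclidean distance in mm
#' between the two annotations' contour point sets after mapping to patient
#' coordinates.  Zero when the point sets share or overlap points;
#' symmetric by construction.
#'
#' @param a,b [NoduleAnnotation-class] objects bound to the same geometry.
#' @param g the common [ScanGeometry-class].
#' @return distance in mm.
#' @export
annotationDistance <- function(a, b, g) {
  pa <- .annotationPoints(a, g)
  pb <- .annotationPoints(b, g)
  ## min over the cross-distance matrix, computed blockwise to bound memory
  best <- Inf
  blk <- 4096L
  for (i0 in seq(1L, nrow(pa), by = blk)) {
    ia <- i0:min(i0 + blk - 1L, nrow(pa))
    d2 <- outer(rowSums(pa[ia, , drop = FALSE]^2), rowSums(pb^2), `+`) -
      2 * (pa[ia, , drop = FALSE] %*% t(pb))
    best <- min(best, d2)
  }
  sqrt(max(best, 0))
}

#' Cluster annotations of one scan into distinct nodules
#'
#' Single-linkage connected components of the graph whose edges join
#' annotation pairs at [annotationDistance()] at most `tol`.  Clusters are
#' numbered consecutively from 1 in order of first member appearance, and
#' each cluster receives a fresh tracking UID shared by all its members.
#' Clusters may contain more than four members (as observed in the source
#' collection when distinct nodules lie very close); such clusters are
#' flagged downstream, never split automatically.
#'
#' @param anns list of [NoduleAnnotation-class].
#' @param g the scan [ScanGeometry-class].
#' @param tol linkage tolerance in mm; defaults to the scan's slice step,
#'   the natural proximity scale of per-slice contour stacks.
#' @param uidRoot UID root for the tracking UIDs.
#' @return list of [NoduleCluster-class].
#' @export
clusterAnnotations <- function(anns, g, tol = NULL,
                               uidRoot = getOption("noduleSEG.uid_root", "2.25")) {
  if (length(anns) == 0L) return(list())
  if (is.null(tol))
    tol <- if (length(g@slicePositions) > 1L)
      stats::median(abs(diff(g@slicePositions))) else 1
  stopifnot(tol >= 0)
  n <- length(anns)
  D <- matrix(0, n, n)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
      D[i, j] <- D[j, i] <- annotationDistance(anns[[i]], anns[[j]], g)
  }
  adj <- D <= tol
  gr <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                            diag = FALSE)
  comp <- igraph::components(gr)$membership
  ## renumber components by first appearance in document order
  lab <- match(comp, unique(comp))
  clusters <- lapply(seq_len(max(lab)), function(kk) {
    idx <- which(lab == kk)
    new("NoduleCluster", noduleNumber = kk, trackingUID = genUID(uidRoot),
        members = anns[idx], memberIndex = as.integer(idx))
  })
  clusters
}
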