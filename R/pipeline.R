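#' ConversionManifest: counts and parameters of one conversion run
#'
#' @slot counts named integer vector: `annotations_parsed`,
#'   `volumetric_annotations`, `clusters`, `segs_written`, `srs_written`,
#'   `excluded_marks`, `warnings`.
#' @slot params run parameters (tolerance, palette size, dictionary hash,
#'   UID root, seed).
#' @slot warnings warning messages accumulated across annotations.
#' @slot outputs data.frame of emitted objects (annotation, nodule,
#'   tracking UID, SEG/SR paths).
#' @slot version package version string.
#' @export
setClass("ConversionManifest", representation(
  counts = "integer", params = "list", warnings = "character",
  outputs = "data.frame", version = "character"))

setValidity("ConversionManifest", function(object) {
  cn <- object@counts
  if (cn[["segs_written"]] != cn[["srs_written"]])
    return("SEG and SR counts must be equal")
  if (cn[["clusters"]] > cn[["annotations_parsed"]])
    return("cannot have more clusters than annotations")
  TRUE
})

setMethod("show", "ConversionManifest", function(object) {
  cat("ConversionManifest (noduleSEG", object@version, ")\n")
  for (nm in names(object@counts))
    cat(sprintf("  %-24s %d\n", nm, object@counts[[nm]]))
  if (length(object@warnings))
    cat("  first warning:", object@warnings[1L], "\n")
})

#' Convert one scan end to end
#'
#' Runs the full pipeline: parse the XML annotations, keep the volumetric
#' ones, bind them to the CT geometry, rasterize each into a mask volume,
#' cluster annotations into nodules, measure, and emit one SEG and one SR
#' per annotation under `outDir/<subject>/<series>/`.  Failures in a single
#' annotation are reported and skipped (with a warning tally) so one data
#' defect never aborts a batch.
#'
#' @param ctDir directory with the per-slice DICOM CT series.
#' @param xmlPath LIDC-dialect annotation XML file.
#' @param outDir output directory root.
#' @param tol clustering tolerance in mm (`NULL` = the scan's slice step).
#' @param uidRoot UID root for all generated identifiers.
#' @param seed RNG seed for UID generation (determinism of the manifest).
#' @param dictionary code dictionary path, `NULL` for the shipped one.
#' @param sct emit numeric SCT codes in the SEG semantics.
#' @return a [ConversionManifest-class].
#' @export
convertScan <- function(ctDir, xmlPath, outDir, tol = NULL, uidRoot = "2.25",
                        seed = 1L, dictionary = NULL, sct = FALSE) {
  set.seed(seed)
  g <- buildGeometry(ctDir)
  allAnns <- parseAnnotationFile(xmlPath)
  vol <- selectVolumetric(allAnns)
  warnings <- character(0)
  dict <- codeDictionary(dictionary)

  clusters <- if (length(vol)) clusterAnnotations(vol, g, tol = tol,
                                                  uidRoot = uidRoot)
              else list()
  subject <- unname(g@context["PatientID"])
  if (!nzchar(subject)) subject <- "UNKNOWN"
  baseDir <- file.path(outDir, subject, g@seriesUID)
  dir.create(baseDir, recursive = TRUE, showWarnings = FALSE)

  rowsOut <- list()
  nSeg <- 0L
  for (cl in clusters) {
    for (oi in seq_along(cl@members)) {
      ann <- cl@members[[oi]]
      res <- tryCatch({
        mask <- buildMask(ann, g)
        conv <- segConventions(cl@noduleNumber, ann@annotationId,
                               cl@trackingUID, ordinal = oi)
        segPath <- file.path(baseDir, sprintf("SEG_%d_%s.dcm",
                                              cl@noduleNumber,
                                              ann@annotationId))
        segBytes <- encodeSeg(mask, conv, file = segPath, sct = sct,
                              uidRoot = uidRoot)
        segUID <- dcmGet(dcmRead(segPath), "0008,0018")
        meas <- measureNodule(mask)
        grp <- buildMeasurementGroup(ann, conv, meas, segUID, g@seriesUID,
                                     dictionary = dictionary)
        srPath <- file.path(baseDir, sprintf("SR_%d_%s.dcm",
                                             cl@noduleNumber,
                                             ann@annotationId))
        encodeSr(grp, g@context, file = srPath, uidRoot = uidRoot)
        list(seg = segPath, sr = srPath)
      }, error = function(e) e, warning = function(w) w)
      if (inherits(res, "condition")) {
        msg <- sprintf("subject %s, annotation '%s': %s", subject,
                       ann@annotationId, conditionMessage(res))
        warnings <- c(warnings, msg)
        message("skipped: ", msg)
        next
      }
      nSeg <- nSeg + 1L
      rowsOut[[length(rowsOut) + 1L]] <- data.frame(
        subject = subject, nodule = cl@noduleNumber,
        annotation = ann@annotationId, tracking_uid = cl@trackingUID,
        seg = res$seg, sr = res$sr, stringsAsFactors = FALSE)
    }
  }
  outputs <- if (length(rowsOut)) do.call(rbind, rowsOut) else
    data.frame(subject = character(0), nodule = integer(0),
               annotation = character(0), tracking_uid = character(0),
               seg = character(0), sr = character(0))
  big <- Filter(function(cl) length(cl@members) > 4L, clusters)
  if (length(big))
    warnings <- c(warnings, sprintf(
      "cluster %d has %d members (>4); may need manual regrouping",
      vapply(big, function(cl) cl@noduleNumber, integer(1)),
      vapply(big, function(cl) length(cl@members), integer(1))))

  manifest <- new("ConversionManifest",
    counts = c(annotations_parsed = length(allAnns),
               volumetric_annotations = length(vol),
               clusters = length(clusters),
               segs_written = nSeg, srs_written = nSeg,
               excluded_marks = length(allAnns) - length(vol),
               warnings = length(warnings)),
    params = list(tol = tol %||% "slice step", uid_root = uidRoot,
                  seed = seed, palette_size = length(SEG_PALETTE),
                  dictionary_hash = codeDictionaryHash(dictionary)),
    warnings = warnings, outputs = outputs,
    version = as.character(utils::packageVersion("noduleSEG")))
  jsonlite::write_json(
    list(counts = as.list(manifest@counts), params = manifest@params,
         warnings = warnings, version = manifest@version),
    file.path(baseDir, "manifest.json"), auto_unbox = TRUE, digits = NA,
    null = "null")
  utils::write.csv(outputs, file.path(baseDir, "objects.csv"),
                   row.names = FALSE)
  manifest
}

.pyValidator <- function() {
  py <- Sys.which("python")
  if (!nzchar(py)) py <- Sys.which("python3")
  script <- system.file("py", "validate_dicom.py", package = "noduleSEG")
  if (!nzchar(py) || !nzchar(script)) return(NULL)
  list(py = py, script = script)
}

#' Validate a converted collection
#'
#' Read-only consistency-check suite over a directory produced by
#' [convertScan()]:
#' \enumerate{
#'   \item 1:1 annotation-SEG and annotation-SR correspondence (count
#'     parity, no orphans);
#'   \item every evaluation concept and value in every SR is in the code
#'     dictionary;
#'   \item tracking (ID, UID) pairs agree between each SEG and its SR, and
#'     all members of a cluster share one tracking UID;
#'   \item SEG decode round-trip: frames re-read as a mask with frame count
#'     equal to the recorded non-empty slice count (on up to `sample`
#'     SEG/SR pairs);
#'   \item independent structural conformance: every SEG and SR re-parsed
#'     by an external DICOM implementation (pydicom) with required IOD
#'     attributes present and frame counts/content trees consistent.
#' }
#'
#' @param dir output root previously passed to [convertScan()].
#' @param sample maximum number of objects for the round-trip check.
#' @param ctDir,xmlPath optional source scan; when both are given, the
#'   round-trip check additionally verifies voxel-identity of each sampled
#'   SEG against a fresh rasterization of its annotation.
#' @return data.frame with columns `check`, `pass`, `detail`; attribute
#'   `"pass"` is the overall outcome.  Failures are report content, never
#'   errors.
#' @export
validateCollection <- function(dir, sample = Inf, ctDir = NULL,
                               xmlPath = NULL) {
  checks <- list()
  add <- function(name, pass, detail = "") {
    checks[[length(checks) + 1L]] <<- data.frame(
      check = name, pass = pass, detail = detail, stringsAsFactors = FALSE)
  }
  manifests <- list.files(dir, pattern = "^objects\\.csv$", recursive = TRUE,
                          full.names = TRUE)
  objects <- do.call(rbind, lapply(manifests, function(f) {
    o <- utils::read.csv(f, stringsAsFactors = FALSE,
                         colClasses = c(annotation = "character"))
    if (nrow(o)) {  # resolve object paths relative to their manifest
      o$seg <- file.path(dirname(f), basename(o$seg))
      o$sr <- file.path(dirname(f), basename(o$sr))
    }
    o
  }))
  if (is.null(objects) || nrow(objects) == 0L) {
    add("correspondence", FALSE, "no converted objects found")
    out <- do.call(rbind, checks)
    attr(out, "pass") <- FALSE
    return(out)
  }

  ## (1) 1:1 correspondence
  missSeg <- objects$annotation[!file.exists(objects$seg)]
  missSr <- objects$annotation[!file.exists(objects$sr)]
  segFiles <- list.files(dir, pattern = "^SEG_.*\\.dcm$", recursive = TRUE)
  srFiles <- list.files(dir, pattern = "^SR_.*\\.dcm$", recursive = TRUE)
  ok1 <- length(missSeg) == 0L && length(missSr) == 0L &&
    length(segFiles) == nrow(objects) && length(srFiles) == nrow(objects)
  add("correspondence", ok1, if (ok1) sprintf("%d annotations, %d SEG, %d SR",
                                              nrow(objects), length(segFiles),
                                              length(srFiles))
      else paste("orphan annotations:",
                 paste(unique(c(missSeg, missSr)), collapse = ", ")))

  ## decode all SRs once
  groups <- lapply(objects$sr[file.exists(objects$sr)], function(f)
    tryCatch(decodeSr(f), error = function(e) e))
  bad <- vapply(groups, inherits, logical(1), what = "error")

  ## (2) code dictionary closure
  d <- codeDictionary()
  valid <- new.env(parent = emptyenv())
  for (nm in names(d$attributes)) {
    a <- d$attributes[[nm]]
    for (v in a$values)
      valid[[paste(a$concept$value, v$value, sep = "|")]] <- TRUE
  }
  offenders <- character(0)
  for (g in groups[!bad]) for (ev in g@evaluations) {
    key <- paste(ev$concept@value, ev$value@value, sep = "|")
    if (is.null(valid[[key]]))
      offenders <- c(offenders, sprintf("(%s, %s, \"%s\")", ev$value@value,
                                        ev$value@scheme, ev$value@meaning))
  }
  add("code_dictionary", length(offenders) == 0L && !any(bad),
      if (length(offenders)) paste("codes outside dictionary:",
                                   paste(unique(offenders), collapse = "; "))
      else "")

  ## (3) tracking consistency SEG vs SR and within clusters
  trackOK <- TRUE; trackDetail <- ""
  uidByNodule <- split(objects$tracking_uid,
                       paste(objects$subject, objects$nodule))
  if (any(vapply(uidByNodule, function(u) length(unique(u)) != 1L,
                 logical(1)))) {
    trackOK <- FALSE; trackDetail <- "cluster members with differing UIDs"
  }
  idx <- which(!bad)
  for (ii in idx) {
    segDs <- tryCatch(dcmRead(objects$seg[ii]), error = function(e) NULL)
    if (is.null(segDs)) { trackOK <- FALSE; next }
    seg <- dcmGet(segDs, "0062,0002")[[1L]]
    if (!identical(dcmGet(seg, "0062,0021"), groups[[ii]]@trackingUID) ||
        !identical(dcmGet(seg, "0062,0020"), groups[[ii]]@trackingId)) {
      trackOK <- FALSE
      trackDetail <- paste("tracking mismatch for annotation",
                           objects$annotation[ii])
    }
  }
  add("tracking", trackOK, trackDetail)

  ## (4) SEG round-trip on a sample: structural always; voxel-identical
  ## against a fresh rasterization when the source scan is supplied
  take <- utils::head(seq_len(nrow(objects)), sample)
  rtOK <- TRUE; rtDetail <- ""
  srcMasks <- NULL
  if (!is.null(ctDir) && !is.null(xmlPath)) {
    gsrc <- buildGeometry(ctDir)
    vols <- selectVolumetric(parseAnnotationFile(xmlPath))
    srcMasks <- stats::setNames(
      lapply(vols, function(a) tryCatch(buildMask(a, gsrc),
                                        error = function(e) NULL)),
      vapply(vols, annotationId, character(1)))
  }
  for (ii in take) {
    r <- tryCatch({
      ds <- dcmRead(objects$seg[ii])
      nf <- as.integer(dcmGet(ds, "0028,0008"))
      pf <- dcmGet(ds, "5200,9230")
      stopifnot(length(pf) == nf, nf >= 1L)
      if (!is.null(srcMasks)) {
        orig <- srcMasks[[objects$annotation[ii]]]
        if (!is.null(orig)) {
          dec <- decodeSeg(ds, orig@geometry)
          stopifnot(identical(dec$mask@voxels, orig@voxels))
        }
      }
      TRUE
    }, error = function(e) conditionMessage(e))
    if (!isTRUE(r)) { rtOK <- FALSE; rtDetail <- as.character(r) }
  }
  add("seg_roundtrip", rtOK, rtDetail)

  ## (5) independent structural validator (pydicom)
  pv <- .pyValidator()
  if (is.null(pv)) {
    add("iod_conformance", FALSE, "no python/pydicom available")
  } else {
    files <- c(objects$seg, objects$sr)
    res <- suppressWarnings(system2(pv$py, c(pv$script, files),
                                    stdout = TRUE, stderr = TRUE))
    status <- attr(res, "status") %||% 0L
    add("iod_conformance", status == 0L,
        if (status != 0L) paste(utils::tail(res, 5L), collapse = " | ")
        else sprintf("%d objects validated", length(files)))
  }

  out <- do.call(rbind, checks)
  attr(out, "pass") <- all(out$pass)
  out
}
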