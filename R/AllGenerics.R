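#' Accessor generics
#'
#' Small accessor layer over the S4 containers so user code never touches
#' slots directly.
#'
#' @param object an object of the documented class.
#' @return the slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("annotationId", function(object) standardGeneric("annotationId"))
#' @rdname accessors
#' @export
setMethod("annotationId", "NoduleAnnotation", function(object) object@annotationId)

#' @rdname accessors
#' @export
setGeneric("rois", function(object) standardGeneric("rois"))
#' @rdname accessors
#' @export
setMethod("rois", "NoduleAnnotation", function(object) object@rois)

#' @rdname accessors
#' @export
setGeneric("characteristics", function(object) standardGeneric("characteristics"))
#' @rdname accessors
#' @export
setMethod("characteristics", "NoduleAnnotation",
          function(object) object@characteristics)

#' @rdname accessors
#' @export
setGeneric("pixelSpacing", function(object) standardGeneric("pixelSpacing"))
#' @rdname accessors
#' @export
setMethod("pixelSpacing", "ScanGeometry", function(object) object@pixelSpacing)

#' @rdname accessors
#' @export
setGeneric("slicePositions", function(object) standardGeneric("slicePositions"))
#' @rdname accessors
#' @export
setMethod("slicePositions", "ScanGeometry", function(object) object@slicePositions)

#' @rdname accessors
#' @export
setGeneric("sliceTable", function(object) standardGeneric("sliceTable"))
#' @rdname accessors
#' @export
setMethod("sliceTable", "ScanGeometry", function(object) object@sliceTable)

#' @rdname accessors
#' @export
setGeneric("imageShape", function(object) standardGeneric("imageShape"))
#' @rdname accessors
#' @export
setMethod("imageShape", "ScanGeometry", function(object) object@imageShape)

#' @rdname accessors
#' @export
setGeneric("voxels", function(object) standardGeneric("voxels"))
#' @rdname accessors
#' @export
setMethod("voxels", "MaskVolume", function(object) object@voxels)

#' @rdname accessors
#' @export
setGeneric("geometry", function(object) standardGeneric("geometry"))
#' @rdname accessors
#' @export
setMethod("geometry", "MaskVolume", function(object) object@geometry)

#' @rdname accessors
#' @export
setGeneric("nonemptySlices", function(object) standardGeneric("nonemptySlices"))
#' @rdname accessors
#' @export
setMethod("nonemptySlices", "MaskVolume", function(object) object@nonemptySlices)

#' @rdname accessors
#' @export
setGeneric("members", function(object) standardGeneric("members"))
#' @rdname accessors
#' @export
setMethod("members", "NoduleCluster", function(object) object@members)

#' @rdname accessors
#' @export
setGeneric("noduleNumber", function(object) standardGeneric("noduleNumber"))
#' @rdname accessors
#' @export
setMethod("noduleNumber", "NoduleCluster", function(object) object@noduleNumber)

#' @rdname accessors
#' @export
setGeneric("trackingUID", function(object) standardGeneric("trackingUID"))
#' @rdname accessors
#' @export
setMethod("trackingUID", "NoduleCluster", function(object) object@trackingUID)
#' @rdname accessors
#' @export
setMethod("trackingUID", "MeasurementGroup", function(object) object@trackingUID)
#' @rdname accessors
#' @export
setMethod("trackingUID", "SegConventions", function(object) object@trackingUID)

#' @rdname accessors
#' @export
setGeneric("codeValue", function(object) standardGeneric("codeValue"))
#' @rdname accessors
#' @export
setMethod("codeValue", "CodedConcept", function(object) object@value)

#' @rdname accessors
#' @export
setGeneric("codeScheme", function(object) standardGeneric("codeScheme"))
#' @rdname accessors
#' @export
setMethod("codeScheme", "CodedConcept", function(object) object@scheme)

#' @rdname accessors
#' @export
setGeneric("codeMeaning", function(object) standardGeneric("codeMeaning"))
#' @rdname accessors
#' @export
setMethod("codeMeaning", "CodedConcept", function(object) object@meaning)
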