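## Coding dictionary: concepts, value sets and units for segmentation
## semantics, qualitative evaluations and measurements.
##
## SRT-style identifiers are the default for the SNOMED concepts, matching
## the convention of the published collection (which predates the move to
## numeric SCT codes); `sct = TRUE` emits the numeric SCT form instead.

.codes_env <- new.env(parent = emptyenv())

#' Load the characteristic code dictionary
#'
#' The dictionary is a human-editable JSON file shipped under
#' `inst/extdata/lidc_code_dictionary.json` (schema: per attribute, one
#' concept triplet plus an ordered value set, one entry per rating).  Its
#' private 99LIDCQIICR code values are this package's own synthetic
#' assignments with meanings that follow the documented LIDC rating scales.
#'
#' @param path alternative dictionary file; `NULL` for the shipped one.
#' @return the dictionary as a nested list (cached per path).
#' @export
codeDictionary <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "lidc_code_dictionary.json",
                        package = "noduleSEG", mustWork = TRUE)
  key <- normalizePath(path)
  if (!is.null(.codes_env[[key]])) return(.codes_env[[key]])
  d <- jsonlite::read_json(path)
  need <- setdiff(LIDC_CHARACTERISTICS, names(d$attributes))
  if (length(need))
    stop("code dictionary lacks attribute(s): ", paste(need, collapse = ", "))
  .codes_env[[key]] <- d
  d
}

#' Hash of the active code dictionary (for run manifests)
#' @param path see [codeDictionary()].
#' @return short checksum string identifying the dictionary content.
#' @export
codeDictionaryHash <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "lidc_code_dictionary.json",
                        package = "noduleSEG", mustWork = TRUE)
  sprintf("size%d", file.size(path))
}

#' Segmentation semantics codes
#'
#' The constant category / type / anatomic-region triple carried by every
#' segment: category "Morphologically altered structure" (SCTID 49755003,
#' CID 7150), type "Nodule" (SCTID 27925004, CID 7151) and anatomy "Lung"
#' (SCTID 39607008, CID 4).
#'
#' @param sct emit numeric SCT codes instead of the SRT-style identifiers
#'   used in the published collection.
#' @return named list of [CodedConcept-class]: `category`, `type`, `anatomy`.
#' @export
segmentationSemantics <- function(sct = FALSE) {
  if (sct) {
    list(category = codedConcept("49755003", "SCT",
                                 "Morphologically altered structure"),
         type = codedConcept("27925004", "SCT", "Nodule"),
         anatomy = codedConcept("39607008", "SCT", "Lung"))
  } else {
    list(category = codedConcept("M-01000", "SRT",
                                 "Morphologically Altered Structure"),
         type = codedConcept("M-03010", "SRT", "Nodule"),
         anatomy = codedConcept("T-28000", "SRT", "Lung"))
  }
}

#' Measurement concept and unit codes
#'
#' @param name optional single measurement name (`"diameter"`,
#'   `"surface_area"`, `"volume"`); unknown names are an error.
#' @return for `name = NULL`, the full map; otherwise one
#'   `list(concept =, unit =)` pair of [CodedConcept-class] objects.
#' @export
measurementCodes <- function(name = NULL) {
  m <- list(
    diameter = list(
      concept = codedConcept("M-02550", "SRT", "Diameter"),
      unit = codedConcept("mm", "UCUM", "millimeter")),
    surface_area = list(
      concept = codedConcept("C0JK", "IBSI", "Surface area of mesh"),
      unit = codedConcept("mm2", "UCUM", "square millimeter")),
    volume = list(
      concept = codedConcept("G-D705", "SRT", "Volume"),
      unit = codedConcept("mm3", "UCUM", "cubic millimeter")))
  if (is.null(name)) return(m)
  if (!name %in% names(m))
    stop("unknown measurement '", name, "'; expected one of: ",
         paste(names(m), collapse = ", "), call. = FALSE)
  m[[name]]
}

#' Coded concept/value pair for one qualitative evaluation
#'
#' @param attribute one of the nine characteristic names (XML spelling,
#'   e.g. `"internalStructure"`).
#' @param rating raw rating from the annotation file.
#' @param dictionary dictionary list from [codeDictionary()], or `NULL`.
#' @return `list(concept =, value =)` of [CodedConcept-class] objects.
#' @export
evaluationCode <- function(attribute, rating, dictionary = NULL) {
  d <- dictionary %||% codeDictionary()
  if (!attribute %in% names(d$attributes))
    stop("unknown characteristic '", attribute, "'", call. = FALSE)
  a <- d$attributes[[attribute]]
  ratings <- vapply(a$values, function(v) v$rating, numeric(1))
  hit <- which(ratings == rating)
  if (length(hit) != 1L)
    stop("rating ", rating, " out of range for '", attribute,
         "'; valid: {", paste(ratings, collapse = ", "), "}", call. = FALSE)
  v <- a$values[[hit]]
  list(concept = codedConcept(a$concept$value, a$concept$scheme,
                              a$concept$meaning),
       value = codedConcept(v$value, v$scheme %||% d$scheme, v$meaning))
}
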