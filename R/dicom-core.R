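## Minimal DICOM Part-10 codec (explicit VR little endian only).
##
## A dataset is a named list keyed by tag "GGGG,EEEE" (uppercase hex); each
## element is list(vr = <2-char VR>, value = <R value>).  Values:
##   - SQ            : list of datasets (sequence items)
##   - OB / OW / UN  : raw vector
##   - US SS UL SL   : integer vector
##   - FL FD         : double vector
##   - DS IS         : numeric vector (serialized as decimal / integer strings)
##   - AT            : character vector of tags "GGGG,EEEE"
##   - everything else: character vector (multi-valued joined by backslash)
##
## Only the explicit-VR-little-endian transfer syntax (1.2.840.10008.1.2.1)
## is read or written; anything else is refused, never mis-parsed.

TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
UID_CT_STORAGE <- "1.2.840.10008.5.1.4.1.1.2"
UID_SEG_STORAGE <- "1.2.840.10008.5.1.4.1.1.66.4"
UID_SR_COMPREHENSIVE <- "1.2.840.10008.5.1.4.1.1.88.33"
UID_IMPL_CLASS <- "1.2.826.0.1.3680043.10.1082.1"

.LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")
.STR_VRS <- c("AE", "AS", "CS", "DA", "DT", "LO", "LT", "PN", "SH", "ST",
              "TM", "UI", "UT")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct one DICOM data element
#'
#' @param vr two-letter value representation, e.g. `"UI"`, `"DS"`, `"SQ"`.
#' @param value element value; for `vr = "SQ"` a list of datasets.
#' @return a list with components `vr` and `value`, the element model used
#'   throughout the codec.
#' @keywords internal
dcmEl <- function(vr, value) list(vr = vr, value = value)

.tagRaw <- function(tag) {
  g <- strtoi(substr(tag, 1, 4), 16L)
  e <- strtoi(substr(tag, 6, 9), 16L)
  c(.u16raw(g), .u16raw(e))
}

.u16raw <- function(x) {
  x <- as.integer(x)
  as.raw(c(bitwAnd(x, 255L), bitwAnd(bitwShiftR(x, 8L), 255L)))
}

.u32raw <- function(x) {
  x <- as.numeric(x)
  as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256,
           (x %/% 16777216) %% 256))
}

.fmtDS <- function(x) {
  s <- sprintf("%.10g", x)
  long <- nchar(s) > 16L
  if (any(long)) s[long] <- sprintf("%.8g", x[long])
  s
}

.encodeValue <- function(vr, value) {
  if (vr == "SQ") {
    items <- lapply(value, function(item) {
      body <- dcmEncode(item)
      c(.tagRaw("FFFE,E000"), .u32raw(length(body)), body)
    })
    return(do.call(c, c(list(raw(0)), items)))
  }
  if (vr %in% c("OB", "OW", "UN")) {
    v <- as.raw(value)
    if (length(v) %% 2L == 1L) v <- c(v, as.raw(0L))
    return(v)
  }
  if (vr == "US") return(do.call(c, lapply(as.integer(value), .u16raw)))
  if (vr == "SS") {
    v <- as.integer(value)
    v[v < 0L] <- v[v < 0L] + 65536L
    return(do.call(c, lapply(v, .u16raw)))
  }
  if (vr %in% c("UL", "SL")) {
    v <- as.numeric(value)
    v[v < 0] <- v[v < 0] + 4294967296
    return(do.call(c, lapply(v, .u32raw)))
  }
  if (vr == "FL") return(writeBin(as.numeric(value), raw(), size = 4L,
                                  endian = "little"))
  if (vr == "FD") return(writeBin(as.numeric(value), raw(), size = 8L,
                                  endian = "little"))
  if (vr == "AT") return(do.call(c, lapply(value, .tagRaw)))
  ## string-like
  s <- if (vr == "DS") paste(.fmtDS(value), collapse = "\\")
       else if (vr == "IS") paste(format(as.integer(value)), collapse = "\\")
       else paste(as.character(value), collapse = "\\")
  b <- charToRaw(enc2utf8(s))
  if (length(b) %% 2L == 1L) {
    pad <- if (vr == "UI") as.raw(0L) else charToRaw(" ")
    b <- c(b, pad)
  }
  b
}

#' Serialize a dataset to explicit-VR-little-endian bytes (no meta header)
#' @param ds dataset (named list of elements keyed by "GGGG,EEEE").
#' @return raw vector.
#' @keywords internal
dcmEncode <- function(ds) {
  if (length(ds) == 0L) return(raw(0))
  tags <- names(ds)
  ord <- order(strtoi(substr(tags, 1, 4), 16L), strtoi(substr(tags, 6, 9), 16L))
  parts <- lapply(ord, function(i) {
    tag <- tags[i]; el <- ds[[i]]
    body <- .encodeValue(el$vr, el$value)
    if (el$vr %in% .LONG_VRS) {
      c(.tagRaw(tag), charToRaw(el$vr), as.raw(c(0L, 0L)),
        .u32raw(length(body)), body)
    } else {
      if (length(body) > 65534L)
        stop("element ", tag, " too long for short-form VR ", el$vr)
      c(.tagRaw(tag), charToRaw(el$vr), .u16raw(length(body)), body)
    }
  })
  do.call(c, parts)
}

#' Write a dataset as a DICOM Part-10 file
#'
#' Prepends the 128-byte preamble, "DICM" magic and the group-0002 file meta
#' header (explicit VR little endian) derived from the dataset's SOP class
#' and instance UIDs.
#'
#' @param ds dataset containing at least (0008,0016) and (0008,0018).
#' @param path file path, or `NULL` to return the bytes invisibly.
#' @return raw vector of the full file, invisibly when written to `path`.
#' @export
dcmWrite <- function(ds, path = NULL) {
  sop_class <- dcmGet(ds, "0008,0016")
  sop_inst <- dcmGet(ds, "0008,0018")
  if (is.null(sop_class) || is.null(sop_inst))
    stop("dataset lacks SOPClassUID / SOPInstanceUID")
  meta <- list(
    "0002,0001" = dcmEl("OB", as.raw(c(0L, 1L))),
    "0002,0002" = dcmEl("UI", sop_class),
    "0002,0003" = dcmEl("UI", sop_inst),
    "0002,0010" = dcmEl("UI", TS_EXPLICIT_LE),
    "0002,0012" = dcmEl("UI", UID_IMPL_CLASS),
    "0002,0013" = dcmEl("SH", "NODULESEG_010")
  )
  metaBody <- dcmEncode(meta)
  metaAll <- c(dcmEncode(list("0002,0000" = dcmEl("UL", length(metaBody)))),
               metaBody)
  out <- c(raw(128L), charToRaw("DICM"), metaAll, dcmEncode(ds))
  if (!is.null(path)) {
    writeBin(out, path)
    return(invisible(out))
  }
  out
}

.rdU16 <- function(buf, at) {
  as.integer(buf[at]) + 256L * as.integer(buf[at + 1L])
}

.rdU32 <- function(buf, at) {
  as.numeric(buf[at]) + 256 * as.numeric(buf[at + 1L]) +
    65536 * as.numeric(buf[at + 2L]) + 16777216 * as.numeric(buf[at + 3L])
}

.rdTag <- function(buf, at) {
  sprintf("%04X,%04X", .rdU16(buf, at), .rdU16(buf, at + 2L))
}

.decodeValue <- function(vr, body) {
  n <- length(body)
  if (vr %in% c("OB", "OW", "UN")) return(body)
  if (vr == "US") {
    if (n == 0L) return(integer(0))
    return(readBin(body, "integer", n %/% 2L, size = 2L, signed = FALSE,
                   endian = "little"))
  }
  if (vr == "SS") return(readBin(body, "integer", n %/% 2L, size = 2L,
                                 signed = TRUE, endian = "little"))
  if (vr %in% c("UL", "SL")) {
    v <- readBin(body, "integer", n %/% 4L, size = 4L, endian = "little")
    v <- as.numeric(v)
    if (vr == "UL") v[v < 0] <- v[v < 0] + 4294967296
    return(v)
  }
  if (vr == "FL") return(readBin(body, "double", n %/% 4L, size = 4L,
                                 endian = "little"))
  if (vr == "FD") return(readBin(body, "double", n %/% 8L, size = 8L,
                                 endian = "little"))
  if (vr == "AT") {
    k <- n %/% 4L
    return(vapply(seq_len(k), function(i) .rdTag(body, 4L * (i - 1L) + 1L),
                  character(1)))
  }
  s <- rawToChar(body[body != as.raw(0L)])
  s <- sub("[ ]+$", "", s)
  if (vr %in% c("DS", "IS", "FL")) {
    v <- strsplit(s, "\\", fixed = TRUE)[[1]]
    return(as.numeric(v))
  }
  strsplit(s, "\\", fixed = TRUE)[[1]] %||% character(0)
}

## parse elements from buf starting at pos (1-based) until 'end' (inclusive);
## stopTag, when reached, terminates (used for item/sequence delimiters).
.parseDataset <- function(buf, pos, end, stopTag = NULL) {
  ds <- list()
  while (pos <= end - 7L) {
    tag <- .rdTag(buf, pos)
    if (!is.null(stopTag) && tag == stopTag) {
      pos <- pos + 8L  # delimiter item has 4-byte zero length
      return(list(ds = ds, pos = pos))
    }
    vr <- rawToChar(buf[(pos + 4L):(pos + 5L)])
    if (vr %in% .LONG_VRS) {
      len <- .rdU32(buf, pos + 8L)
      pos <- pos + 12L
    } else {
      len <- .rdU16(buf, pos + 6L)
      pos <- pos + 8L
    }
    if (vr == "SQ") {
      if (len == 4294967295) {
        r <- .parseItems(buf, pos, length(buf), undefined = TRUE)
      } else {
        r <- .parseItems(buf, pos, pos + len - 1L, undefined = FALSE)
      }
      ds[[tag]] <- dcmEl("SQ", r$items)
      pos <- r$pos
    } else {
      if (len == 4294967295)
        stop("undefined length on non-SQ element ", tag, " unsupported")
      body <- if (len > 0) buf[pos:(pos + len - 1L)] else raw(0)
      ds[[tag]] <- dcmEl(vr, .decodeValue(vr, body))
      pos <- pos + len
    }
  }
  list(ds = ds, pos = pos)
}

.parseItems <- function(buf, pos, end, undefined) {
  items <- list()
  repeat {
    if (undefined) {
      tag <- .rdTag(buf, pos)
      if (tag == "FFFE,E0DD") { pos <- pos + 8L; break }
    } else if (pos > end) break
    tag <- .rdTag(buf, pos)
    if (tag != "FFFE,E000") stop("expected sequence item, found ", tag)
    ilen <- .rdU32(buf, pos + 4L)
    pos <- pos + 8L
    if (ilen == 4294967295) {
      r <- .parseDataset(buf, pos, length(buf), stopTag = "FFFE,E00D")
    } else {
      r <- .parseDataset(buf, pos, pos + ilen - 1L)
    }
    items[[length(items) + 1L]] <- r$ds
    pos <- r$pos
  }
  list(items = items, pos = pos)
}

#' Read a DICOM Part-10 file
#'
#' Only the explicit-VR-little-endian transfer syntax is supported; other
#' transfer syntaxes raise an error rather than being silently mis-parsed.
#'
#' @param x file path or raw vector.
#' @return the dataset as a named element list; the file meta header is
#'   attached as attribute `"meta"`.
#' @export
dcmRead <- function(x) {
  buf <- if (is.raw(x)) x else readBin(x, raw(), file.size(x))
  if (length(buf) < 140L || rawToChar(buf[129:132]) != "DICM")
    stop("not a DICOM Part-10 file (missing DICM magic)")
  pos <- 133L
  ## group 0002 is always explicit little endian; its group length bounds it
  tag <- .rdTag(buf, pos)
  if (tag != "0002,0000") stop("file meta group length missing")
  glen <- .rdU16(buf, pos + 6L)   # UL is short-form: 2-byte length (== 4)
  metaLen <- .rdU32(buf, pos + 8L)
  pos <- pos + 8L + glen
  r <- .parseDataset(buf, pos, pos + metaLen - 1L)
  meta <- r$ds
  ts <- dcmGet(meta, "0002,0010")
  if (!identical(ts, TS_EXPLICIT_LE))
    stop("unsupported transfer syntax: ", ts %||% "<missing>")
  r <- .parseDataset(buf, r$pos, length(buf))
  ds <- r$ds
  attr(ds, "meta") <- meta
  ds
}

#' Fetch an element value from a dataset
#' @param ds dataset from [dcmRead()] or built for [dcmWrite()].
#' @param tag `"GGGG,EEEE"` tag string.
#' @param default value returned when the tag is absent.
#' @return the element's value, or `default`.
#' @export
dcmGet <- function(ds, tag, default = NULL) {
  el <- ds[[tag]]
  if (is.null(el)) default else el$value
}

## ---- UID generation ------------------------------------------------------

.uid_state <- new.env(parent = emptyenv())
.uid_state$counter <- 0L

#' Generate a DICOM unique identifier
#'
#' Hierarchical UID under `root`, built from the session RNG plus a process
#' counter, so a fixed seed yields a reproducible UID stream.
#'
#' @param root UID root; defaults to the package option
#'   `noduleSEG.uid_root` or `"2.25"`.
#' @return character UID of at most 64 characters.
#' @export
genUID <- function(root = getOption("noduleSEG.uid_root", "2.25")) {
  .uid_state$counter <- .uid_state$counter + 1L
  digits <- paste(sample(0:9, 30, replace = TRUE), collapse = "")
  digits <- sub("^0+", "", digits)
  if (digits == "") digits <- "1"
  uid <- paste0(root, ".", digits, ".", .uid_state$counter)
  if (nchar(uid) > 64L) stop("UID root too long: ", root)
  uid
}
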