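# Minimal DICOM codec: explicit VR little endian, the subset of the standard
# an RT Plan needs (string VRs, UL, OB, and nested SQ with defined or
# undefined lengths). Internal; the public surface is readRTPlan/writeRTPlan.

.TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
.SOP_RTPLAN <- "1.2.840.10008.5.1.4.1.1.481.5"
# PEN ("Privately Defined") style implementation UID root for files we emit
.IMPL_UID <- "1.2.826.0.1.3680043.10.424.1"

.u16 <- function(x) writeBin(as.integer(x), raw(), size = 2L, endian = "little")
.u32 <- function(x) writeBin(as.integer(x), raw(), size = 4L, endian = "little")

# VRs using the 4-byte length form (2 reserved bytes + 32-bit length)
.LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")

.dcmPad <- function(bytes, padByte = as.raw(0x20)) {
  if (length(bytes) %% 2L == 1L) c(bytes, padByte) else bytes
}

# one data element, explicit VR
.dcmElem <- function(group, elem, vr, valueBytes) {
  head <- c(.u16(group), .u16(elem), charToRaw(vr))
  if (vr %in% .LONG_VRS) {
    c(head, as.raw(c(0, 0)), .u32(length(valueBytes)), valueBytes)
  } else {
    stopifnot(length(valueBytes) < 65536L)
    c(head, .u16(length(valueBytes)), valueBytes)
  }
}

.dcmStrElem <- function(group, elem, vr, values) {
  pad <- if (vr == "UI") as.raw(0x00) else as.raw(0x20)
  bytes <- charToRaw(paste(values, collapse = "\\"))
  .dcmElem(group, elem, vr, .dcmPad(bytes, pad))
}

# decimal string: up to 10 significant digits, well within DS's 16 chars for
# the millimetre magnitudes an RT Plan holds
.dcmDS <- function(group, elem, x) {
  .dcmStrElem(group, elem, "DS", formatC(x, format = "g", digits = 10))
}

.dcmIS <- function(group, elem, x) {
  .dcmStrElem(group, elem, "IS", sprintf("%d", as.integer(x)))
}

# sequence of items, defined lengths throughout
.dcmSeq <- function(group, elem, items) {
  body <- unlist(lapply(items, function(it) {
    c(.u16(0xFFFE), .u16(0xE000), .u32(length(it)), it)
  }))
  if (is.null(body)) body <- raw(0)
  .dcmElem(group, elem, "SQ", body)
}

.dcmFileMeta <- function(sopInstanceUID) {
  body <- c(
    .dcmElem(0x0002, 0x0001, "OB", as.raw(c(0x00, 0x01))),
    .dcmStrElem(0x0002, 0x0002, "UI", .SOP_RTPLAN),
    .dcmStrElem(0x0002, 0x0003, "UI", sopInstanceUID),
    .dcmStrElem(0x0002, 0x0010, "UI", .TS_EXPLICIT_LE),
    .dcmStrElem(0x0002, 0x0012, "UI", .IMPL_UID)
  )
  c(
    raw(128), charToRaw("DICM"),
    .dcmElem(0x0002, 0x0000, "UL", .u32(length(body))),
    body
  )
}

.uidCounter <- new.env(parent = emptyenv())

.newUID <- function() {
  # time + in-session counter; global uniqueness is not needed for fixtures
  k <- get0("k", envir = .uidCounter, ifnotfound = 0L) + 1L
  assign("k", k, envir = .uidCounter)
  paste0(.IMPL_UID, ".", as.integer(Sys.time()) %% 1000000L, ".", k)
}

# ---- parsing ----------------------------------------------------------------

.rd16 <- function(raw, pos) {
  as.integer(raw[pos]) + 256L * as.integer(raw[pos + 1L])
}

.rd32 <- function(raw, pos) {
  # returns NA for the undefined-length marker 0xFFFFFFFF
  b <- as.integer(raw[pos:(pos + 3L)])
  if (all(b == 255L)) return(NA_integer_)
  b[1] + 256 * b[2] + 65536 * b[3] + 16777216 * b[4]
}

.dcmDecode <- function(vr, bytes) {
  if (vr %in% c("DS")) {
    s <- trimws(rawToChar(bytes))
    if (!nzchar(s)) return(numeric(0))
    as.numeric(strsplit(s, "\\", fixed = TRUE)[[1]])
  } else if (vr %in% c("IS", "UL", "US")) {
    if (vr == "UL") return(.rd32(bytes, 1L))
    if (vr == "US") return(.rd16(bytes, 1L))
    s <- trimws(rawToChar(bytes))
    if (!nzchar(s)) return(integer(0))
    as.integer(strsplit(s, "\\", fixed = TRUE)[[1]])
  } else if (vr %in% c("CS", "LO", "SH", "UI", "ST", "LT", "PN", "DA", "TM",
                       "AE", "AS", "UT")) {
    sub(" +$", "", rawToChar(bytes[bytes != as.raw(0)]))
  } else {
    bytes
  }
}

# parse elements of one dataset between pos and end (1-based, inclusive);
# returns list(elements = named list, pos = next position)
.dcmParseDataset <- function(raw, pos, end) {
  out <- list()
  while (pos <= end) {
    group <- .rd16(raw, pos); elem <- .rd16(raw, pos + 2L)
    pos <- pos + 4L
    if (group == 0xFFFE) {
      if (elem == 0xE00D || elem == 0xE0DD) { # item / sequence delimiter
        pos <- pos + 4L
        if (elem == 0xE00D) return(list(elements = out, pos = pos))
        next
      }
      stop("unexpected item tag outside a sequence at offset ", pos - 5L)
    }
    vr <- rawToChar(raw[pos:(pos + 1L)]); pos <- pos + 2L
    if (vr %in% .LONG_VRS) {
      len <- .rd32(raw, pos + 2L); pos <- pos + 6L
    } else {
      len <- .rd16(raw, pos); pos <- pos + 2L
    }
    key <- sprintf("%04X%04X", group, elem)
    if (vr == "SQ") {
      parsed <- .dcmParseSeq(raw, pos, len, end)
      out[[key]] <- parsed$items
      pos <- parsed$pos
    } else {
      if (is.na(len)) stop("undefined length on non-sequence element ", key)
      val <- if (len > 0L) raw[pos:(pos + len - 1L)] else raw(0)
      out[[key]] <- .dcmDecode(vr, val)
      pos <- pos + len
    }
  }
  list(elements = out, pos = pos)
}

.dcmParseSeq <- function(raw, pos, len, fileEnd) {
  items <- list()
  end <- if (is.na(len)) fileEnd else pos + len - 1L
  while (pos <= end) {
    group <- .rd16(raw, pos); elem <- .rd16(raw, pos + 2L)
    ilen <- .rd32(raw, pos + 4L)
    pos <- pos + 8L
    if (group != 0xFFFE) stop("malformed sequence: expected item tag")
    if (elem == 0xE0DD) break               # sequence delimiter
    if (elem != 0xE000) stop("malformed sequence item tag")
    if (is.na(ilen)) {                       # undefined-length item
      parsed <- .dcmParseDataset(raw, pos, end)
    } else {
      parsed <- .dcmParseDataset(raw, pos, pos + ilen - 1L)
    }
    items[[length(items) + 1L]] <- parsed$elements
    pos <- parsed$pos
  }
  list(items = items, pos = pos)
}

# read a DICOM file into a nested named list keyed by "GGGGEEEE"
.dcmRead <- function(path) {
  raw <- readBin(path, what = "raw", n = file.info(path)$size)
  if (length(raw) < 200L || rawToChar(raw[129:132]) != "DICM")
    stop("not a DICOM file (missing DICM magic): ", path)
  pos <- 133L
  meta <- list()
  while (pos <= length(raw) && .rd16(raw, pos) == 0x0002) {
    elem <- .rd16(raw, pos + 2L)
    vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
    if (vr %in% .LONG_VRS) {
      len <- .rd32(raw, pos + 8L); body <- pos + 12L
    } else {
      len <- .rd16(raw, pos + 6L); body <- pos + 8L
    }
    meta[[sprintf("0002%04X", elem)]] <-
      .dcmDecode(vr, if (len > 0) raw[body:(body + len - 1L)] else raw(0))
    pos <- body + len
  }
  ts <- meta[["00020010"]]
  if (!is.null(ts) && !identical(ts, .TS_EXPLICIT_LE))
    stop("unsupported transfer syntax '", ts,
      "'; only explicit VR little endian is supported")
  ds <- .dcmParseDataset(raw, pos, length(raw))$elements
  attr(ds, "fileMeta") <- meta
  ds
}
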