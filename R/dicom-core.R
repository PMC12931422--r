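# Minimal DICOM part-10 I/O, explicit VR little endian only.
# Covers exactly what the CT / RTDOSE / RTPLAN objects written and read by
# this package need: scalar and multi-valued string VRs, US/UL/FD binary
# VRs, OW/OB pixel payloads, and (nested) SQ sequences with defined or
# undefined lengths.

.TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"

# ---- little-endian raw packing -----------------------------------------

raw_u16 <- function(x) {
  x <- as.numeric(x)
  as.raw(rbind(x %% 256, (x %/% 256) %% 256))
}

raw_u32 <- function(x) {
  x <- as.numeric(x)
  as.raw(rbind(x %% 256, (x %/% 256) %% 256,
               (x %/% 65536) %% 256, (x %/% 16777216) %% 256))
}

raw_i16 <- function(x) {
  x <- as.numeric(x)
  raw_u16(ifelse(x < 0, x + 65536, x))
}

rd_u16 <- function(r) {
  v <- as.integer(r)
  v[seq(1, length(v), 2)] + 256L * v[seq(2, length(v), 2)]
}

rd_u32 <- function(r) {
  v <- as.numeric(as.integer(r))
  i <- seq(1, length(v), 4)
  v[i] + 256 * v[i + 1] + 65536 * v[i + 2] + 16777216 * v[i + 3]
}

rd_i16 <- function(r) {
  v <- rd_u16(r)
  ifelse(v > 32767L, v - 65536L, v)
}

.long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
.string_vrs <- c("AE", "AS", "CS", "DA", "DT", "LO", "LT", "PN", "SH",
                 "ST", "TM", "UI", "UT")

# ---- element encoding ---------------------------------------------------

dicom_element <- function(group, element, vr, value) {
  body <- switch(vr,
    DS = {
      s <- paste(vapply(as.numeric(value),
                        function(v) sprintf("%.8g", v), ""),
                 collapse = "\\")
      charToRaw(s)
    },
    IS = charToRaw(paste(sprintf("%d", as.integer(value)), collapse = "\\")),
    US = raw_u16(value),
    UL = raw_u32(value),
    FD = writeBin(as.double(value), raw(), size = 8, endian = "little"),
    SQ = {
      # value: list of raw vectors, one encoded dataset per item
      items <- lapply(value, function(it) {
        c(raw_u16(0xFFFE), raw_u16(0xE000), raw_u32(length(it)), it)
      })
      do.call(c, items)
    },
    OW = as.raw(value),
    OB = as.raw(value),
    {
      if (!vr %in% .string_vrs) stop("unsupported VR for write: ", vr)
      charToRaw(paste(as.character(value), collapse = "\\"))
    }
  )
  if (length(body) %% 2 == 1) {
    pad <- if (vr %in% c("UI", "OB")) as.raw(0) else charToRaw(" ")
    body <- c(body, pad)
  }
  hdr <- c(raw_u16(group), raw_u16(element), charToRaw(vr))
  if (vr %in% .long_vrs) {
    hdr <- c(hdr, raw(2), raw_u32(length(body)))
  } else {
    if (length(body) > 65534) stop("value too long for short VR ", vr)
    hdr <- c(hdr, raw_u16(length(body)))
  }
  c(hdr, body)
}

# elements: list of lists(group, element, vr, value), written in order
encode_dataset <- function(elements) {
  do.call(c, lapply(elements, function(e) {
    dicom_element(e$group, e$element, e$vr, e$value)
  }))
}

el <- function(group, element, vr, value) {
  list(group = group, element = element, vr = vr, value = value)
}

# ---- part-10 file write -------------------------------------------------

write_dicom_file <- function(path, sop_class_uid, sop_instance_uid,
                             dataset_elements) {
  body <- encode_dataset(dataset_elements)
  meta <- encode_dataset(list(
    el(0x0002, 0x0002, "UI", sop_class_uid),
    el(0x0002, 0x0003, "UI", sop_instance_uid),
    el(0x0002, 0x0010, "UI", .TS_EXPLICIT_LE)
  ))
  grouplen <- dicom_element(0x0002, 0x0000, "UL", length(meta))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(grouplen, meta, body), con)
  invisible(path)
}

# ---- parsing ------------------------------------------------------------

# Parse one explicit-VR dataset from raw vector `r` between pos and end
# (1-based, inclusive). Returns list(elements = named list, pos).
parse_dataset <- function(r, pos, end) {
  out <- list()
  while (pos + 7 <= end) {
    group <- rd_u16(r[pos:(pos + 1)])
    element <- rd_u16(r[(pos + 2):(pos + 3)])
    pos <- pos + 4
    if (group == 0xFFFE) {
      # delimiters have implicit structure: 4-byte length only
      len <- rd_u32(r[pos:(pos + 3)]); pos <- pos + 4
      if (element == 0xE00D || element == 0xE0DD) {
        return(list(elements = out, pos = pos, delimiter = element))
      }
      stop("unexpected item tag outside sequence")
    }
    vr <- rawToChar(r[pos:(pos + 1)]); pos <- pos + 2
    if (vr %in% .long_vrs) {
      pos <- pos + 2  # reserved
      len <- rd_u32(r[pos:(pos + 3)]); pos <- pos + 4
    } else {
      len <- rd_u16(r[pos:(pos + 1)]); pos <- pos + 2
    }
    key <- sprintf("%04X,%04X", group, element)
    if (vr == "SQ") {
      parsed <- parse_sequence(r, pos, len, end)
      out[[key]] <- parsed$items
      pos <- parsed$pos
    } else {
      val_raw <- if (len > 0) r[pos:(pos + len - 1)] else raw(0)
      pos <- pos + len
      out[[key]] <- decode_value(vr, val_raw)
    }
  }
  list(elements = out, pos = pos, delimiter = NA_integer_)
}

parse_sequence <- function(r, pos, len, end) {
  items <- list()
  seq_end <- if (len == 4294967295) end else pos + len - 1
  while (pos <= seq_end) {
    group <- rd_u16(r[pos:(pos + 1)])
    element <- rd_u16(r[(pos + 2):(pos + 3)])
    item_len <- rd_u32(r[(pos + 4):(pos + 7)])
    pos <- pos + 8
    if (group == 0xFFFE && element == 0xE0DD) break  # sequence delimiter
    if (!(group == 0xFFFE && element == 0xE000)) {
      stop("malformed sequence: expected item tag")
    }
    if (item_len == 4294967295) {
      # undefined item length: parse_dataset returns at the item delimiter
      parsed <- parse_dataset(r, pos, seq_end)
      items[[length(items) + 1L]] <- parsed$elements
      pos <- parsed$pos
    } else {
      parsed <- parse_dataset(r, pos, pos + item_len - 1)
      items[[length(items) + 1L]] <- parsed$elements
      pos <- pos + item_len
    }
  }
  list(items = items, pos = pos)
}

decode_value <- function(vr, val_raw) {
  if (vr %in% c("OW", "OB", "UN")) return(val_raw)
  if (vr == "US") return(rd_u16(val_raw))
  if (vr == "UL") return(rd_u32(val_raw))
  if (vr == "SS") return(rd_i16(val_raw))
  if (vr == "FL") return(readBin(val_raw, "double", length(val_raw) / 4,
                                 size = 4, endian = "little"))
  if (vr == "FD") return(readBin(val_raw, "double", length(val_raw) / 8,
                                 size = 8, endian = "little"))
  s <- rawToChar(val_raw[val_raw != as.raw(0)])
  parts <- trimws(strsplit(s, "\\", fixed = TRUE)[[1]])
  if (vr %in% c("DS", "FL")) return(as.numeric(parts))
  if (vr == "IS") return(as.integer(parts))
  parts
}

read_dicom_file <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  r <- readBin(path, "raw", file.size(path))
  if (length(r) < 132 || rawToChar(r[129:132]) != "DICM") {
    stop("not a DICOM part-10 file: ", path, call. = FALSE)
  }
  # parse the file meta group first to find where it ends
  pos <- 133
  # group length element
  g <- rd_u16(r[pos:(pos + 1)]); e <- rd_u16(r[(pos + 2):(pos + 3)])
  if (g != 2 || e != 0) stop("missing file meta group length", call. = FALSE)
  len <- rd_u16(r[(pos + 6):(pos + 7)])
  metalen <- rd_u32(r[(pos + 8):(pos + 8 + len - 1)])
  pos <- pos + 8 + len
  meta <- parse_dataset(r, pos, pos + metalen - 1)
  ts <- meta$elements[["0002,0010"]]
  if (!identical(ts, .TS_EXPLICIT_LE)) {
    stop("unsupported transfer syntax: ", ts, call. = FALSE)
  }
  body <- parse_dataset(r, pos + metalen, length(r))
  c(meta$elements, body$elements)
}

# deterministic pseudo-UIDs under a private-style root
make_uid <- function(...) {
  paste0("1.2.826.0.1.3680043.9.7484.",
         paste(gsub("[^0-9]", "", as.character(c(...))), collapse = "."))
}
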