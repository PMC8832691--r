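# Minimal DICOM codec: explicit-VR little-endian read/write of the RT Plan
# and CT elements this package needs. Written in-house because the R stack
# here has no DICOM package; pydicom-compatible output is covered by tests.

.d_u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
.d_u32 <- function(x) {
  # R has no unsigned 32-bit writeBin; handle 0xFFFFFFFF explicitly
  if (x >= 2^31) {
    lo <- x %% 65536; hi <- (x - lo) / 65536
    c(.d_u16(lo), .d_u16(hi))
  } else writeBin(as.integer(x), raw(), size = 4, endian = "little")
}

.d_long_vrs <- c("OB", "OW", "OF", "SQ", "UN", "UT")

# one explicit-VR element as raw bytes; value must already be raw
.d_elem <- function(group, elem, vr, value) {
  if (length(value) %% 2L == 1L)
    value <- c(value, if (vr == "UI") as.raw(0L) else charToRaw(" "))
  hdr <- c(.d_u16(group), .d_u16(elem), charToRaw(vr))
  if (vr %in% .d_long_vrs) {
    len <- if (vr == "SQ") 0xFFFFFFFF else length(value)
    c(hdr, as.raw(c(0, 0)), .d_u32(len), value)
  } else c(hdr, .d_u16(length(value)), value)
}

.d_str_elem <- function(group, elem, vr, s) .d_elem(group, elem, vr, charToRaw(s))

.d_fmt_ds <- function(x) {
  s <- vapply(x, function(v) format(v, trim = TRUE, scientific = FALSE, digits = 10),
              character(1))
  paste(s, collapse = "\\")
}

.d_ds <- function(group, elem, x) .d_str_elem(group, elem, "DS", .d_fmt_ds(x))
.d_is <- function(group, elem, x)
  .d_str_elem(group, elem, "IS", paste(as.integer(x), collapse = "\\"))

# sequence with undefined length; items = list of raw vectors
.d_sq <- function(group, elem, items) {
  body <- raw()
  for (it in items)
    body <- c(body, .d_u16(0xFFFE), .d_u16(0xE000), .d_u32(0xFFFFFFFF), it,
              .d_u16(0xFFFE), .d_u16(0xE00D), .d_u32(0))
  body <- c(body, .d_u16(0xFFFE), .d_u16(0xE0DD), .d_u32(0))
  .d_elem(group, elem, "SQ", body)
}

.d_uid_root <- "1.2.826.0.1.3680043.9.7433."  # generic org root for generated UIDs
.d_new_uid <- function() {
  paste0(.d_uid_root,
         paste0(sample(0:9, 8, replace = TRUE), collapse = ""), ".",
         format(as.integer(Sys.time()) %% 100000000L))
}

.d_file <- function(sop_class_uid, sop_instance_uid, dataset) {
  meta <- c(
    .d_elem(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
    .d_str_elem(0x0002, 0x0002, "UI", sop_class_uid),
    .d_str_elem(0x0002, 0x0003, "UI", sop_instance_uid),
    .d_str_elem(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1"),
    .d_str_elem(0x0002, 0x0012, "UI", paste0(.d_uid_root, "1")))
  c(raw(128), charToRaw("DICM"),
    .d_elem(0x0002, 0x0000, "UL", .d_u32(length(meta))),
    meta, dataset)
}

# ---------------------------------------------------------------------------
# Parser
# ---------------------------------------------------------------------------

.d_read_u16 <- function(raw, pos) {
  as.integer(raw[pos]) + 256L * as.integer(raw[pos + 1L])
}
.d_read_u32 <- function(raw, pos) {
  as.numeric(raw[pos]) + 256 * as.numeric(raw[pos + 1L]) +
    65536 * as.numeric(raw[pos + 2L]) + 16777216 * as.numeric(raw[pos + 3L])
}

# parse an explicit-VR LE dataset between pos and end (1-based, inclusive);
# returns list(elements = named list, pos = position after the dataset)
.d_parse <- function(bytes, pos, end, stop_at_item_delim = FALSE) {
  out <- list()
  while (pos <= end) {
    group <- .d_read_u16(bytes, pos); elem <- .d_read_u16(bytes, pos + 2L)
    if (group == 0xFFFE) {
      len <- .d_read_u32(bytes, pos + 4L)
      pos <- pos + 8L
      if (elem == 0xE00D && stop_at_item_delim) return(list(elements = out, pos = pos))
      if (elem == 0xE0DD) return(list(elements = out, pos = pos))
      stop("unexpected item tag outside a sequence")
    }
    vr <- rawToChar(bytes[(pos + 4L):(pos + 5L)])
    if (vr %in% .d_long_vrs) {
      len <- .d_read_u32(bytes, pos + 8L); pos <- pos + 12L
    } else {
      len <- .d_read_u16(bytes, pos + 6L); pos <- pos + 8L
    }
    key <- sprintf("%04X%04X", group, elem)
    if (vr == "SQ" || (vr == "UN" && len == 0xFFFFFFFF)) {
      items <- list()
      if (len == 0xFFFFFFFF) {
        repeat {
          g2 <- .d_read_u16(bytes, pos); e2 <- .d_read_u16(bytes, pos + 2L)
          l2 <- .d_read_u32(bytes, pos + 4L)
          pos <- pos + 8L
          if (g2 == 0xFFFE && e2 == 0xE0DD) break
          if (!(g2 == 0xFFFE && e2 == 0xE000)) stop("malformed sequence")
          if (l2 == 0xFFFFFFFF) {
            r <- .d_parse(bytes, pos, length(bytes), stop_at_item_delim = TRUE)
          } else {
            r <- .d_parse(bytes, pos, pos + l2 - 1L)
            r$pos <- pos + l2
          }
          items[[length(items) + 1L]] <- r$elements
          pos <- r$pos
        }
      } else {
        sq_end <- pos + len - 1L
        while (pos <= sq_end) {
          e2 <- .d_read_u16(bytes, pos + 2L); l2 <- .d_read_u32(bytes, pos + 4L)
          pos <- pos + 8L
          if (e2 == 0xE0DD) break
          if (l2 == 0xFFFFFFFF) {
            r <- .d_parse(bytes, pos, sq_end, stop_at_item_delim = TRUE)
          } else {
            r <- .d_parse(bytes, pos, pos + l2 - 1L)
            r$pos <- pos + l2
          }
          items[[length(items) + 1L]] <- r$elements
          pos <- r$pos
        }
      }
      out[[key]] <- list(vr = "SQ", items = items)
    } else {
      val <- if (len > 0) bytes[pos:(pos + len - 1L)] else raw(0)
      pos <- pos + len
      out[[key]] <- list(vr = vr, bytes = val)
    }
  }
  list(elements = out, pos = pos)
}

.d_parse_file <- function(path) {
  bytes <- readBin(path, "raw", n = file.info(path)$size)
  if (length(bytes) < 140L || rawToChar(bytes[129:132]) != "DICM")
    stop("not a DICOM file (missing DICM marker): ", path)
  if (!identical(.d_read_u16(bytes, 133L), 0x0002L))
    stop("missing DICOM file meta group")
  glen <- {
    # (0002,0000) UL, explicit: tag(4) VR(2) len16(2) value(4)
    .d_read_u32(bytes, 133L + 8L)
  }
  meta_end <- 133L + 12L + glen - 1L
  meta <- .d_parse(bytes, 133L + 12L, meta_end)$elements
  ts <- .d_el_str(meta, 0x0002, 0x0010)
  if (!is.null(ts) && ts != "1.2.840.10008.1.2.1")
    stop("unsupported transfer syntax (only explicit VR little endian): ", ts)
  .d_parse(bytes, meta_end + 1L, length(bytes))$elements
}

.d_el <- function(els, group, elem) els[[sprintf("%04X%04X", group, elem)]]
.d_el_str <- function(els, group, elem) {
  e <- .d_el(els, group, elem)
  if (is.null(e)) return(NULL)
  b <- e$bytes
  pad <- c(as.raw(0L), charToRaw(" "))
  while (length(b) && b[length(b)] %in% pad) b <- b[-length(b)]
  rawToChar(b)
}
.d_el_num <- function(els, group, elem) {
  s <- .d_el_str(els, group, elem)
  if (is.null(s)) return(NULL)
  as.numeric(strsplit(s, "\\\\")[[1]])
}
.d_el_items <- function(els, group, elem) {
  e <- .d_el(els, group, elem)
  if (is.null(e)) NULL else e$items
}
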