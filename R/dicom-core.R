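# Minimal DICOM PS3.10 codec: Explicit VR Little Endian only, the single
# transfer syntax this package emits (chosen for maximal interoperability and
# simple golden files). Elements are plain lists; datasets are lists of
# elements keyed "ggggeeee". Sequences are written with defined lengths and
# read with defined or undefined lengths.

uid_transfer_syntax_le <- function() "1.2.840.10008.1.2.1"
uid_mrs_storage <- function() "1.2.840.10008.5.1.4.1.1.4.2"
uid_raw_storage <- function() "1.2.840.10008.5.1.4.1.1.66"
uid_enhanced_mr_storage <- function() "1.2.840.10008.5.1.4.1.1.4.1"
uid_sc_storage <- function() "1.2.840.10008.5.1.4.1.1.7"
uid_mr_image_storage <- function() "1.2.840.10008.5.1.4.1.1.4"
uid_implementation <- function() "2.25.190763531953432112550176583739577623307"

#' Deterministic DICOM UID derived from content
#'
#' UIDs are generated under the "2.25" (UUID-derived) root from the SHA1 of a
#' label string, so that identical inputs produce byte-identical files — the
#' package's reproducibility contract extends to its DICOM output.
#'
#' @param label character scalar to hash.
#' @return a valid UID string (<= 64 chars).
#' @export
dicom_uid <- function(label) {
  hex <- digest::digest(label, algo = "sha1", serialize = FALSE)
  chunks <- substring(hex, seq(1, 36, by = 7), pmin(seq(7, 42, by = 7), 40))
  dec <- paste(vapply(chunks, function(ch) as.character(strtoi(ch, 16L)), ""),
               collapse = "")
  paste0("2.25.1", substr(dec, 1, 38))
}

dicom_el <- function(group, element, vr, value) {
  list(group = as.integer(group), element = as.integer(element),
       vr = vr, value = value)
}

tag_key <- function(group, element) sprintf("%04x%04x", group, element)

.vr_long <- c("OB", "OW", "OF", "SQ", "UT", "UN")
.vr_string <- c("AE", "AS", "CS", "DA", "DS", "DT", "IS", "LO", "LT", "PN",
                "SH", "ST", "TM", "UI", "UT")

format_ds <- function(x) {
  s <- vapply(x, function(v) formatC(v, digits = 10, format = "g",
                                     flag = "-"), "")
  gsub(" ", "", s)
}

encode_value <- function(vr, value) {
  if (vr %in% .vr_string) {
    s <- paste(as.character(value), collapse = "\\")
    b <- charToRaw(s)
    if (length(b) %% 2L == 1L)
      b <- c(b, if (vr == "UI") as.raw(0L) else charToRaw(" "))
    return(b)
  }
  con <- rawConnection(raw(0), "wb")
  on.exit(close(con))
  switch(vr,
    US = writeBin(as.integer(value), con, size = 2L, endian = "little"),
    UL = writeBin(as.integer(value), con, size = 4L, endian = "little"),
    SS = writeBin(as.integer(value), con, size = 2L, endian = "little"),
    SL = writeBin(as.integer(value), con, size = 4L, endian = "little"),
    FL = writeBin(as.numeric(value), con, size = 4L, endian = "little"),
    FD = writeBin(as.numeric(value), con, size = 8L, endian = "little"),
    OB = , OW = , OF = , UN = writeBin(as.raw(value), con),
    stop("unsupported VR for encoding: ", vr)
  )
  rawConnectionValue(con)
}

encode_element <- function(el, con) {
  writeBin(as.integer(c(el$group, el$element)), con, size = 2L,
           endian = "little")
  writeChar(el$vr, con, nchars = 2L, eos = NULL)
  if (el$vr == "SQ") {
    body_con <- rawConnection(raw(0), "wb")
    for (item in el$value) {
      item_con <- rawConnection(raw(0), "wb")
      for (sub in item) encode_element(sub, item_con)
      item_bytes <- rawConnectionValue(item_con)
      close(item_con)
      writeBin(as.integer(c(0xFFFE, 0xE000)), body_con, size = 2L,
               endian = "little")
      write_u32(length(item_bytes), body_con)
      writeBin(item_bytes, body_con)
    }
    body <- rawConnectionValue(body_con)
    close(body_con)
    writeBin(as.raw(c(0L, 0L)), con)
    write_u32(length(body), con)
    writeBin(body, con)
    return(invisible())
  }
  bytes <- encode_value(el$vr, el$value)
  if (length(bytes) %% 2L == 1L) stop("odd-length DICOM value")
  if (el$vr %in% .vr_long) {
    writeBin(as.raw(c(0L, 0L)), con)
    write_u32(length(bytes), con)
  } else {
    if (length(bytes) > 65534) stop("value too long for short VR ", el$vr)
    writeBin(length(bytes), con, size = 2L, endian = "little")
  }
  writeBin(bytes, con)
  invisible()
}

write_u32 <- function(n, con) {
  b <- as.raw(c(n %% 256, (n %/% 256) %% 256, (n %/% 65536) %% 256,
                (n %/% 16777216) %% 256))
  writeBin(b, con)
}

sort_elements <- function(elements) {
  keys <- vapply(elements, function(e) e$group * 2^16 + e$element, numeric(1))
  elements[order(keys)]
}

# Write a complete Part-10 file: 128-byte preamble, "DICM", file meta group
# (always Explicit VR LE), then the dataset in Explicit VR LE.
dicom_write_file <- function(path, sop_class, sop_instance, elements) {
  meta <- list(
    dicom_el(0x0002, 0x0001, "OB", as.raw(c(0L, 1L))),
    dicom_el(0x0002, 0x0002, "UI", sop_class),
    dicom_el(0x0002, 0x0003, "UI", sop_instance),
    dicom_el(0x0002, 0x0010, "UI", uid_transfer_syntax_le()),
    dicom_el(0x0002, 0x0012, "UI", uid_implementation())
  )
  meta_con <- rawConnection(raw(0), "wb")
  for (el in meta) encode_element(el, meta_con)
  meta_bytes <- rawConnectionValue(meta_con)
  close(meta_con)

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128L), con)
  writeChar("DICM", con, nchars = 4L, eos = NULL)
  encode_element(dicom_el(0x0002, 0x0000, "UL", length(meta_bytes)), con)
  writeBin(meta_bytes, con)
  for (el in sort_elements(elements)) encode_element(el, con)
  invisible(path)
}

# --- reading ---------------------------------------------------------------

rd_u16 <- function(bytes, pos) {
  as.integer(bytes[pos]) + 256L * as.integer(bytes[pos + 1L])
}

rd_u32 <- function(bytes, pos) {
  as.integer(bytes[pos]) + 256 * as.integer(bytes[pos + 1L]) +
    65536 * as.integer(bytes[pos + 2L]) + 16777216 * as.integer(bytes[pos + 3L])
}

decode_value <- function(vr, bytes) {
  if (vr %in% .vr_string) {
    s <- rawToChar(bytes[bytes != as.raw(0L)])
    s <- sub("[ ]+$", "", s)
    return(strsplit(s, "\\\\")[[1]])
  }
  switch(vr,
    US = readBin(bytes, "integer", length(bytes) / 2, size = 2L,
                 endian = "little", signed = FALSE),
    SS = readBin(bytes, "integer", length(bytes) / 2, size = 2L,
                 endian = "little", signed = TRUE),
    UL = , SL = readBin(bytes, "integer", length(bytes) / 4, size = 4L,
                        endian = "little"),
    FL = readBin(bytes, "numeric", length(bytes) / 4, size = 4L,
                 endian = "little"),
    FD = readBin(bytes, "numeric", length(bytes) / 8, size = 8L,
                 endian = "little"),
    bytes  # OB, OW, OF, UN: raw
  )
}

# Parse a run of data elements from `bytes` starting at `pos` (1-based) up to
# `end`; returns list(dataset = named list of elements, pos = next position).
parse_elements <- function(bytes, pos, end) {
  ds <- list()
  while (pos <= end) {
    group <- rd_u16(bytes, pos); element <- rd_u16(bytes, pos + 2L)
    pos <- pos + 4L
    if (group == 0xFFFE && element == 0xE00D) {  # item delimiter
      pos <- pos + 4L
      return(list(dataset = ds, pos = pos, delimiter = "item_end"))
    }
    if (group == 0xFFFE && element == 0xE0DD) {  # sequence delimiter
      pos <- pos + 4L
      return(list(dataset = ds, pos = pos, delimiter = "seq_end"))
    }
    vr <- rawToChar(bytes[pos:(pos + 1L)]); pos <- pos + 2L
    if (vr %in% .vr_long) {
      len <- rd_u32(bytes, pos + 2L); pos <- pos + 6L
    } else {
      len <- rd_u16(bytes, pos); pos <- pos + 2L
    }
    undefined <- (len == 4294967295)
    if (vr == "SQ") {
      seq_end <- if (undefined) end else pos + len - 1L
      items <- list()
      while (pos <= seq_end) {
        ig <- rd_u16(bytes, pos); ie <- rd_u16(bytes, pos + 2L)
        ilen <- rd_u32(bytes, pos + 4L); pos <- pos + 8L
        if (ig == 0xFFFE && ie == 0xE0DD) break
        if (!(ig == 0xFFFE && ie == 0xE000))
          stop("malformed sequence: expected item tag")
        if (ilen == 4294967295) {
          res <- parse_elements(bytes, pos, end)
          items <- c(items, list(res$dataset)); pos <- res$pos
        } else {
          res <- parse_elements(bytes, pos, pos + ilen - 1L)
          items <- c(items, list(res$dataset)); pos <- pos + ilen
        }
      }
      ds[[tag_key(group, element)]] <- dicom_el(group, element, "SQ", items)
      next
    }
    if (undefined) stop("undefined length outside SQ is not supported")
    value <- if (len > 0L) decode_value(vr, bytes[pos:(pos + len - 1L)])
             else decode_value(vr, raw(0))
    pos <- pos + len
    ds[[tag_key(group, element)]] <- dicom_el(group, element, vr, value)
  }
  list(dataset = ds, pos = pos, delimiter = "end")
}

#' Read a DICOM file written with Explicit VR Little Endian
#'
#' Low-level access to this package's DICOM products: returns the parsed file
#' meta group and dataset as lists of elements keyed by `"ggggeeee"`.
#'
#' @param path DICOM file path.
#' @return list with `meta` and `dataset`.
#' @export
read_dicom_file <- function(path) {
  bytes <- readBin(path, "raw", file.info(path)$size)
  if (length(bytes) < 140 || rawToChar(bytes[129:132]) != "DICM")
    stop("not a DICOM Part-10 file: ", path)
  pos <- 133L
  # file meta: group-length element tells how far the meta group extends
  if (rd_u16(bytes, pos) != 0x0002)
    stop("missing DICOM file meta group")
  res0 <- parse_one_meta <- NULL
  # parse (0002,0000) UL group length
  vr <- rawToChar(bytes[(pos + 4L):(pos + 5L)])
  len <- rd_u16(bytes, pos + 6L)
  glen <- rd_u32(bytes, pos + 8L)
  pos <- pos + 8L + len
  meta <- parse_elements(bytes, pos, pos + glen - 1L)
  pos <- meta$pos
  ts <- meta$dataset[[tag_key(0x0002, 0x0010)]]
  if (is.null(ts) || !identical(ts$value, uid_transfer_syntax_le()))
    stop("unsupported transfer syntax (only Explicit VR Little Endian): ",
         if (is.null(ts)) "<missing>" else ts$value)
  body <- parse_elements(bytes, pos, length(bytes))
  list(meta = meta$dataset, dataset = body$dataset)
}

dicom_peek_sop_class <- function(path) {
  n <- min(file.info(path)$size, 4096)
  bytes <- readBin(path, "raw", n)
  pos <- 133L
  vr <- rawToChar(bytes[(pos + 4L):(pos + 5L)])
  len <- rd_u16(bytes, pos + 6L)
  glen <- rd_u32(bytes, pos + 8L)
  pos <- pos + 8L + len
  meta <- parse_elements(bytes, pos, min(pos + glen - 1L, length(bytes)))
  el <- meta$dataset[[tag_key(0x0002, 0x0002)]]
  if (is.null(el)) stop("no media storage SOP class UID")
  el$value
}

dicom_get <- function(dataset, group, element, default = NULL) {
  el <- dataset[[tag_key(group, element)]]
  if (is.null(el)) default else el$value
}

dicom_require <- function(dataset, group, element, what) {
  el <- dataset[[tag_key(group, element)]]
  if (is.null(el)) stop("missing required DICOM attribute ", what,
                        sprintf(" (%04X,%04X)", group, element))
  el$value
}

# Shared patient/study boilerplate for every instance this package writes.
# Dates are fixed constants so outputs are byte-reproducible.
dicom_common_elements <- function(sop_class, sop_instance, study_uid,
                                  series_uid, modality, instance_number = 1L,
                                  series_number = 1L) {
  list(
    dicom_el(0x0008, 0x0016, "UI", sop_class),
    dicom_el(0x0008, 0x0018, "UI", sop_instance),
    dicom_el(0x0008, 0x0020, "DA", "20240101"),
    dicom_el(0x0008, 0x0030, "TM", "000000"),
    dicom_el(0x0008, 0x0060, "CS", modality),
    dicom_el(0x0010, 0x0010, "PN", "PHANTOM^MRSI"),
    dicom_el(0x0010, 0x0020, "LO", "MRSIKIT"),
    dicom_el(0x0020, 0x000D, "UI", study_uid),
    dicom_el(0x0020, 0x000E, "UI", series_uid),
    dicom_el(0x0020, 0x0011, "IS", as.character(series_number)),
    dicom_el(0x0020, 0x0013, "IS", as.character(instance_number))
  )
}
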