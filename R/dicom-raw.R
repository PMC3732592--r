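#' Encapsulate files in a DICOM Raw Data Storage instance
#'
#' Stores arbitrary files (typically scanner raw acquisitions) inside a DICOM
#' Raw Data Storage instance (SOP class `1.2.840.10008.5.1.4.1.1.66`) so the
#' raw data travels with the rest of the exam in the archive. Each file
#' becomes one item of a private sequence under the reserved creator block
#' `"MRSIKIT RAW 1.0"`: original filename (LO), lowercase SHA1 hex digest of
#' the payload (LO), the payload itself (OB, even-padded), and the pad length
#' (US). The digest is verified on extraction.
#'
#' @param paths character vector of readable input files.
#' @param out output DICOM file.
#' @return invisibly, a data frame with `filename` and `sha1` per member.
#' @export
encapsulate_raw <- function(paths, out) {
  if (length(paths) == 0L) stop("no input files to encapsulate")
  for (p in paths) if (!file.exists(p) || dir.exists(p))
    stop("cannot read input file: ", p)
  items <- list()
  manifest <- data.frame(filename = character(), sha1 = character())
  for (p in paths) {
    payload <- readBin(p, "raw", file.info(p)$size)
    sha <- digest::digest(payload, algo = "sha1", serialize = FALSE)
    pad <- length(payload) %% 2L
    items <- c(items, list(list(
      dicom_el(PRIV_GROUP, 0x1010, "LO", basename(p)),
      dicom_el(PRIV_GROUP, 0x1011, "LO", sha),
      dicom_el(PRIV_GROUP, 0x1012, "OB", c(payload, raw(pad))),
      dicom_el(PRIV_GROUP, 0x1013, "US", pad)
    )))
    manifest <- rbind(manifest, data.frame(filename = basename(p), sha1 = sha))
  }
  sop_instance <- dicom_uid(paste0("raw-", paste(manifest$sha1, collapse = "")))
  els <- c(
    dicom_common_elements(uid_raw_storage(), sop_instance,
                          dicom_uid("mrsikit-study"),
                          dicom_uid(paste0("raw-series-", sop_instance)),
                          "OT"),
    list(dicom_el(PRIV_GROUP, 0x0010, "LO", "MRSIKIT RAW 1.0"),
         dicom_el(PRIV_GROUP, 0x1001, "SQ", items))
  )
  dicom_write_file(out, uid_raw_storage(), sop_instance, els)
  invisible(manifest)
}

#' Extract files from a DICOM Raw Data Storage instance
#'
#' Restores every encapsulated payload to `outdir` and verifies each SHA1
#' digest, failing loudly on any mismatch (single-bit corruption anywhere in
#' a payload is detected).
#'
#' @param path a Raw Data Storage file written by [encapsulate_raw()].
#' @param outdir output directory (created if missing).
#' @return character vector of restored file paths.
#' @export
unencapsulate_raw <- function(path, outdir) {
  f <- read_dicom_file(path)
  sop <- dicom_require(f$dataset, 0x0008, 0x0016, "SOPClassUID")
  if (!identical(sop, uid_raw_storage()))
    stop("not a Raw Data Storage instance; found SOP class ", sop)
  seq_el <- f$dataset[[tag_key(PRIV_GROUP, 0x1001)]]
  if (is.null(seq_el)) stop("no encapsulated file sequence found")
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  out <- character()
  for (item in seq_el$value) {
    fname <- item[[tag_key(PRIV_GROUP, 0x1010)]]$value
    sha_stored <- item[[tag_key(PRIV_GROUP, 0x1011)]]$value
    payload <- item[[tag_key(PRIV_GROUP, 0x1012)]]$value
    pad <- item[[tag_key(PRIV_GROUP, 0x1013)]]$value
    if (pad > 0L) payload <- payload[seq_len(length(payload) - pad)]
    sha_actual <- digest::digest(payload, algo = "sha1", serialize = FALSE)
    if (!identical(sha_actual, sha_stored))
      stop(sprintf(
        "integrity error for '%s': stored SHA1 %s but payload digests to %s",
        fname, sha_stored, sha_actual))
    dest <- file.path(outdir, fname)
    writeBin(payload, dest)
    out <- c(out, dest)
  }
  out
}
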