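#' @name mrsraw-format
#' @title The MRSRAW1 raw acquisition container
#' @description
#' A documented stand-in for proprietary scanner raw formats, exercising the
#' same reader/mapper contract. Layout, byte-exact:
#'
#' 1. magic bytes `"MRSRAW1"` (7 bytes, ASCII);
#' 2. a little-endian unsigned 32-bit JSON header length;
#' 3. the UTF-8 JSON header: `dims` (3 ints), `n_points`, `channels`,
#'    `dwell` (s), `f0` (MHz), `ppm_ref`, `geometry` (origin/spacing mm,
#'    six orientation cosines), optional `selection` (center/size mm),
#'    `sat_bands` (normal/distance/thickness), and `ordering`
#'    (`type` = `"cartesian"` or `"epsi"`, `readout_axis`, `epsi_tau` s),
#'    plus `payload_bytes`;
#' 4. the payload: little-endian complex64 (float32 real, float32 imaginary)
#'    samples in acquisition order — cartesian: spectral point fastest, then
#'    kx, ky, kz, channel slowest; epsi: readout k fastest, then spectral
#'    point, then the remaining spatial axes, then channel.
#'
#' `payload_bytes` must equal `8 * prod(dims) * n_points * channels`.
NULL

#' Write an MRSRAW1 raw acquisition file
#'
#' Readers must expose these bytes verbatim; the writer performs no
#' reordering or scaling. See [mrsraw-format] for the container layout.
#'
#' @param samples complex vector in acquisition order.
#' @param header header list (see [mrsraw-format]); `payload_bytes` is filled
#'   in automatically.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_mrsraw <- function(samples, header, path) {
  header$payload_bytes <- 8L * length(samples)
  json <- charToRaw(as.character(jsonlite::toJSON(
    header, auto_unbox = TRUE, digits = NA, null = "null")))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("MRSRAW1"), con)
  writeBin(length(json), con, size = 4L, endian = "little")
  writeBin(json, con)
  inter <- numeric(2L * length(samples))
  inter[c(TRUE, FALSE)] <- Re(samples)
  inter[c(FALSE, TRUE)] <- Im(samples)
  writeBin(inter, con, size = 4L, endian = "little")
  invisible(path)
}

#' Read an MRSRAW1 file into an acquisition object
#'
#' The reader parses the container without interpreting its content: samples
#' stay in acquisition order, the header is exposed verbatim. Interpretation
#' (reshaping onto the regular grid) is the mapper's job, see
#' [map_acquisition()].
#'
#' @param path an MRSRAW1 file.
#' @return an object of class `mrs_acquisition` with `samples` (complex,
#'   acquisition order), `header` (parsed key/value metadata) and `ordering`.
#' @export
read_mrsraw <- function(path) {
  if (!file.exists(path) || dir.exists(path))
    stop("cannot read raw file: ", path)
  sz <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 7L)
  if (length(magic) < 7L || rawToChar(magic) != "MRSRAW1")
    stop("not an MRSRAW1 file (bad magic): ", path)
  hlen <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  hdr_raw <- readBin(con, "raw", hlen)
  header <- tryCatch(
    jsonlite::fromJSON(rawToChar(hdr_raw), simplifyVector = TRUE),
    error = function(e) stop("malformed MRSRAW1 JSON header: ",
                             conditionMessage(e)))
  n_samples <- prod(header$dims) * header$n_points * header$channels
  expected <- 8 * n_samples
  actual <- sz - 7 - 4 - hlen
  if (header$payload_bytes != expected)
    stop(sprintf("header validation error: dims imply %d payload bytes but header declares %d",
                 expected, header$payload_bytes))
  if (actual != expected)
    stop(sprintf("corrupt MRSRAW1 payload: expected %d bytes, found %d",
                 expected, actual))
  inter <- readBin(con, "numeric", 2L * n_samples, size = 4L,
                   endian = "little")
  samples <- complex(real = inter[c(TRUE, FALSE)],
                     imaginary = inter[c(FALSE, TRUE)])
  structure(list(samples = samples, header = header,
                 ordering = header$ordering),
            class = "mrs_acquisition")
}

#' @export
print.mrs_acquisition <- function(x, ...) {
  cat(sprintf("<mrs_acquisition> %d samples, dims %s, %d pts, %d ch, ordering %s\n",
              length(x$samples), paste(x$header$dims, collapse = "x"),
              x$header$n_points, x$header$channels, x$ordering$type))
  invisible(x)
}

#' Identify the format of a file
#'
#' Factory-style sniffing by magic bytes: `"MRSRAW1"` at offset 0 for the raw
#' container; `"DICM"` at offset 128 plus the Media Storage SOP Class UID for
#' DICOM files (MR Spectroscopy Storage instances are distinguished from
#' image-type instances).
#'
#' @param path a readable file.
#' @return one of `"mrsraw"`, `"dicom_mrs"`, `"dicom_mri"`, `"unknown"`.
#' @export
sniff_format <- function(path) {
  if (!file.exists(path) || dir.exists(path))
    stop("cannot read file: ", path)
  sz <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  head7 <- readBin(con, "raw", 7L)
  if (length(head7) == 7L && rawToChar(head7) == "MRSRAW1") return("mrsraw")
  if (sz >= 132) {
    seek(con, 128)
    dicm <- readBin(con, "raw", 4L)
    if (rawToChar(dicm) == "DICM") {
      sop <- tryCatch(dicom_peek_sop_class(path), error = function(e) "")
      return(if (identical(sop, uid_mrs_storage())) "dicom_mrs" else "dicom_mri")
    }
  }
  "unknown"
}

#' Map an acquisition onto the regular spectroscopic grid
#'
#' The interpretation half of the reader/mapper split: resamples (here, a
#' pure permutation — no sample value may change) the acquisition-ordered
#' samples into the `(x, y, z, spectral, channel)` layout, spatial domain
#' k-space, spectral domain time, and transfers all header metadata into the
#' spectral axis and geometry. Echo-planar per-k delays are recorded in
#' provenance for [epsi_phase_correct()] to consume, not applied here.
#'
#' @param acq an `mrs_acquisition` from [read_mrsraw()].
#' @return an [mrs_dataset()].
#' @export
map_acquisition <- function(acq) {
  h <- acq$header
  ord <- acq$ordering$type
  if (!ord %in% c("cartesian", "epsi"))
    stop("unsupported acquisition ordering: ", ord)
  dims5 <- c(h$dims, h$n_points, h$channels)
  perm <- acquisition_perm(ord, as.integer(acq$ordering$readout_axis))
  arr <- array(acq$samples, dim = dims5[perm])
  arr <- aperm(arr, order(perm))
  axis <- spectral_axis(h$n_points, h$dwell, h$f0, h$ppm_ref, domain = "time")
  geom <- mrs_geometry(origin = h$geometry$origin,
                       spacing = h$geometry$spacing, dims = h$dims,
                       orientation = h$geometry$orientation)
  sel <- if (!is.null(h$selection))
    selection_box(h$selection$center, h$selection$size) else NULL
  sbs <- list()
  if (!is.null(h$sat_bands) && length(h$sat_bands)) {
    sb_list <- if (is.data.frame(h$sat_bands))
      lapply(seq_len(nrow(h$sat_bands)), function(i) as.list(h$sat_bands[i, ]))
    else h$sat_bands
    sbs <- lapply(sb_list, function(sb)
      sat_band(unlist(sb$normal), sb$distance, sb$thickness))
  }
  ds <- mrs_dataset(arr, axis, geom,
                    spatial_domain = c("kspace", "kspace", "kspace"),
                    selection = sel, sat_bands = sbs)
  params <- list(ordering = ord)
  if (ord == "epsi") {
    params$readout_axis <- as.integer(acq$ordering$readout_axis)
    params$epsi_tau <- acq$ordering$epsi_tau
  }
  prov_append(ds, "map_acquisition", params)
}

#' Read any supported spectroscopy file into a dataset
#'
#' Factory dispatch: sniffs the format, then routes to the matching
#' reader/mapper pair (MRSRAW1 via [read_mrsraw()] + [map_acquisition()],
#' DICOM MR Spectroscopy via [read_dicom_mrs()]).
#'
#' @param path file path.
#' @return an [mrs_dataset()].
#' @export
read_mrs_any <- function(path) {
  fmt <- sniff_format(path)
  switch(fmt,
    mrsraw = map_acquisition(read_mrsraw(path)),
    dicom_mrs = read_dicom_mrs(path),
    dicom_mri = stop("file is a DICOM image, not spectroscopy: ", path),
    stop("unknown format for ", path,
         "; supported formats: mrsraw (MRSRAW1), dicom_mrs (DICOM MR Spectroscopy)")
  )
}
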