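#' Export a metabolite map as a DICOM Enhanced MR Image instance
#'
#' Writes the 3-D map as a multiframe Enhanced MR Image Storage instance
#' (SOP class `1.2.840.10008.5.1.4.1.1.4.1`). Floating-point values are
#' scaled to unsigned 16-bit with Rescale Slope/Intercept chosen so that
#' `slope * pixel + intercept` reproduces each voxel within one quantization
#' step of `(max - min)/65535`; the geometry of the source dataset is
#' preserved. The reliability mask travels in the package's private block so
#' maps round-trip losslessly.
#'
#' @param map a [metabolite_map()] with finite values in unmasked voxels.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_metabolite_map_dicom <- function(map, path) {
  vals <- map$values
  if (any(!is.finite(vals[map$mask])))
    stop("metabolite map contains non-finite values in unmasked voxels")
  vals[!map$mask & !is.finite(vals)] <- 0
  d <- dim(vals)
  lo <- min(vals); hi <- max(vals)
  slope <- if (hi > lo) (hi - lo) / 65535 else 1
  pix <- as.integer(round((vals - lo) / slope))
  # frame(z) -> row(y) -> column(x), column fastest
  ordered <- as.vector(aperm(array(pix, dim = d), c(1, 2, 3)))
  payload <- writeBin(ordered, raw(), size = 2L, endian = "little")
  sop_instance <- dicom_uid(paste0("emri-", map$label, "-",
                                   digest::digest(payload, algo = "sha1")))
  els <- c(
    dicom_common_elements(uid_enhanced_mr_storage(), sop_instance,
                          dicom_uid("mrsikit-study"),
                          dicom_uid(paste0("emri-series-", sop_instance)),
                          "MR"),
    list(
      dicom_el(0x0008, 0x103E, "LO", map$label),
      dicom_el(0x0028, 0x0002, "US", 1L),
      dicom_el(0x0028, 0x0004, "CS", "MONOCHROME2"),
      dicom_el(0x0028, 0x0008, "IS", as.character(d[3])),
      dicom_el(0x0028, 0x0010, "US", d[2]),
      dicom_el(0x0028, 0x0011, "US", d[1]),
      dicom_el(0x0028, 0x0100, "US", 16L),
      dicom_el(0x0028, 0x0101, "US", 16L),
      dicom_el(0x0028, 0x0102, "US", 15L),
      dicom_el(0x0028, 0x0103, "US", 0L),
      dicom_el(0x0028, 0x1052, "DS", format_ds(lo)),
      dicom_el(0x0028, 0x1053, "DS", format_ds(slope)),
      dicom_el(0x0028, 0x1054, "LO", "US"),
      dicom_el(PRIV_GROUP, 0x0010, "LO", "MRSIKIT RAW 1.0"),
      dicom_el(PRIV_GROUP, 0x1030, "OB", pad_even(as.raw(as.integer(map$mask)))),
      dicom_el(PRIV_GROUP, 0x1052, "FD", lo),
      dicom_el(PRIV_GROUP, 0x1053, "FD", slope),
      dicom_el(0x7FE0, 0x0010, "OW", payload)
    ),
    geometry_elements(map$geometry)
  )
  dicom_write_file(path, uid_enhanced_mr_storage(), sop_instance, els)
}

pad_even <- function(b) if (length(b) %% 2L == 1L) c(b, raw(1L)) else b

#' Read a metabolite map from an Enhanced MR Image instance
#'
#' Inverse of [write_metabolite_map_dicom()]: reconstructs voxel values as
#' `slope * pixel + intercept` (using the full-precision private copies of
#' slope/intercept when present) and restores the mask and geometry.
#'
#' @param path an Enhanced MR Image Storage file.
#' @return a [metabolite_map()].
#' @export
read_metabolite_map_dicom <- function(path) {
  f <- read_dicom_file(path)
  sop <- dicom_require(f$dataset, 0x0008, 0x0016, "SOPClassUID")
  if (!identical(sop, uid_enhanced_mr_storage()))
    stop("not an Enhanced MR Image Storage instance; found SOP class ", sop)
  rows <- dicom_require(f$dataset, 0x0028, 0x0010, "Rows")
  cols <- dicom_require(f$dataset, 0x0028, 0x0011, "Columns")
  frames <- as.integer(dicom_get(f$dataset, 0x0028, 0x0008, "1"))
  lo <- dicom_get(f$dataset, PRIV_GROUP, 0x1052,
                  as.numeric(dicom_require(f$dataset, 0x0028, 0x1052,
                                           "RescaleIntercept")))
  slope <- dicom_get(f$dataset, PRIV_GROUP, 0x1053,
                     as.numeric(dicom_require(f$dataset, 0x0028, 0x1053,
                                              "RescaleSlope")))
  payload <- dicom_require(f$dataset, 0x7FE0, 0x0010, "PixelData")
  pix <- readBin(payload, "integer", cols * rows * frames, size = 2L,
                 endian = "little", signed = FALSE)
  vals <- array(pix * slope + lo, dim = c(cols, rows, frames))
  geom <- geometry_from_elements(f$dataset, c(cols, rows, frames))
  mask_raw <- dicom_get(f$dataset, PRIV_GROUP, 0x1030)
  mask <- if (!is.null(mask_raw))
    array(as.integer(mask_raw[seq_len(cols * rows * frames)]) > 0L,
          dim = c(cols, rows, frames))
  else array(TRUE, dim = c(cols, rows, frames))
  label <- dicom_get(f$dataset, 0x0008, 0x103E, "map")
  metabolite_map(vals, geom, label, mask)
}

# One single-frame MR Image Storage file per slice; used for the synthetic
# anatomical reference series.
write_dicom_mri_series <- function(values, geometry, dir, seed_label = "mri") {
  d <- dim(values)
  lo <- min(values); hi <- max(values)
  slope <- if (hi > lo) (hi - lo) / 65535 else 1
  series_uid <- dicom_uid(paste0("mri-series-", seed_label,
                                 paste(d, collapse = "x")))
  paths <- character(d[3])
  for (k in seq_len(d[3])) {
    pix <- as.integer(round((values[, , k] - lo) / slope))
    payload <- writeBin(pix, raw(), size = 2L, endian = "little")
    sop_instance <- dicom_uid(paste0(seed_label, "-slice-", k, "-",
                                     digest::digest(payload, algo = "sha1")))
    pos <- voxel_center(geometry, 0L, 0L, k - 1L)
    els <- c(
      dicom_common_elements(uid_mr_image_storage(), sop_instance,
                            dicom_uid("mrsikit-study"), series_uid, "MR",
                            instance_number = k),
      list(
        dicom_el(0x0008, 0x103E, "LO", "synthetic anatomical reference"),
        dicom_el(0x0028, 0x0002, "US", 1L),
        dicom_el(0x0028, 0x0004, "CS", "MONOCHROME2"),
        dicom_el(0x0028, 0x0010, "US", d[2]),
        dicom_el(0x0028, 0x0011, "US", d[1]),
        dicom_el(0x0028, 0x0100, "US", 16L),
        dicom_el(0x0028, 0x0101, "US", 16L),
        dicom_el(0x0028, 0x0102, "US", 15L),
        dicom_el(0x0028, 0x0103, "US", 0L),
        dicom_el(0x0028, 0x1052, "DS", format_ds(lo)),
        dicom_el(0x0028, 0x1053, "DS", format_ds(slope)),
        dicom_el(0x0020, 0x0032, "DS", format_ds(pos)),
        dicom_el(0x0020, 0x0037, "DS", format_ds(geometry$orientation)),
        dicom_el(0x0028, 0x0030, "DS",
                 format_ds(c(geometry$spacing[2], geometry$spacing[1]))),
        dicom_el(0x0018, 0x0050, "DS", format_ds(geometry$spacing[3])),
        dicom_el(0x7FE0, 0x0010, "OW", payload)
      )
    )
    paths[k] <- file.path(dir, sprintf("slice_%03d.dcm", k))
    dicom_write_file(paths[k], uid_mr_image_storage(), sop_instance, els)
  }
  invisible(paths)
}

#' Read a single-frame DICOM MR Image series from a directory
#'
#' Reads the slices written by [generate_anatomical()] (or any Explicit VR
#' Little Endian single-frame MR Image series with the named attributes),
#' sorts them by instance number, and rebuilds the 3-D volume and geometry.
#'
#' @param dir directory of `.dcm` files of one series.
#' @return list with `values` (3-D array, rescaled) and `geometry`.
#' @export
read_dicom_mri_series <- function(dir) {
  files <- list.files(dir, pattern = "\\.dcm$", full.names = TRUE)
  if (length(files) == 0L) stop("no DICOM files in ", dir)
  parsed <- lapply(files, read_dicom_file)
  inst <- vapply(parsed, function(f)
    as.integer(dicom_get(f$dataset, 0x0020, 0x0013, "0")), integer(1))
  parsed <- parsed[order(inst)]
  f1 <- parsed[[1]]$dataset
  rows <- dicom_require(f1, 0x0028, 0x0010, "Rows")
  cols <- dicom_require(f1, 0x0028, 0x0011, "Columns")
  nz <- length(parsed)
  vals <- array(0, dim = c(cols, rows, nz))
  for (k in seq_len(nz)) {
    dsk <- parsed[[k]]$dataset
    slope <- as.numeric(dicom_get(dsk, 0x0028, 0x1053, "1"))
    inter <- as.numeric(dicom_get(dsk, 0x0028, 0x1052, "0"))
    pix <- readBin(dicom_require(dsk, 0x7FE0, 0x0010, "PixelData"),
                   "integer", cols * rows, size = 2L, endian = "little",
                   signed = FALSE)
    vals[, , k] <- array(pix * slope + inter, dim = c(cols, rows))
  }
  orient <- as.numeric(dicom_require(f1, 0x0020, 0x0037,
                                     "ImageOrientationPatient"))
  px <- as.numeric(dicom_require(f1, 0x0028, 0x0030, "PixelSpacing"))
  dz <- as.numeric(dicom_get(f1, 0x0018, 0x0050, "1"))
  pos0 <- as.numeric(dicom_require(f1, 0x0020, 0x0032,
                                   "ImagePositionPatient"))
  geom <- mrs_geometry(origin = pos0, spacing = c(px[2], px[1], dz),
                       dims = c(cols, rows, nz), orientation = orient)
  list(values = vals, geometry = geom)
}

#' Write RGB rasters as a DICOM Secondary Capture series
#'
#' One Secondary Capture Image Storage instance (SOP class
#' `1.2.840.10008.5.1.4.1.1.7`) per raster, sharing a single Series Instance
#' UID, instance numbers `1..n`. Pixels are 8-bit interleaved RGB and
#' round-trip bit-exactly.
#'
#' @param images list of equal-size 8-bit RGB rasters, each an integer array
#'   `(height, width, 3)` with values 0..255.
#' @param path output path; for multiple rasters, files are named
#'   `<path minus extension>_NNN.dcm`.
#' @return character vector of file paths written.
#' @export
write_secondary_capture <- function(images, path) {
  if (length(images) == 0L) stop("empty image list")
  dims <- lapply(images, dim)
  if (any(vapply(dims, length, 0L) != 3L) ||
      length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L)
    stop("all rasters must be equal-size (height, width, 3) arrays")
  n <- length(images)
  stem <- sub("\\.dcm$", "", path)
  paths <- if (n == 1L) path else sprintf("%s_%03d.dcm", stem, seq_len(n))
  series_uid <- dicom_uid(paste0(
    "sc-series-", digest::digest(images[[1]], algo = "sha1")))
  for (i in seq_len(n)) {
    img <- images[[i]]
    h <- dim(img)[1]; w <- dim(img)[2]
    # row-major, interleaved R,G,B per pixel
    inter <- as.integer(aperm(img, c(3, 2, 1)))
    payload <- pad_even(as.raw(inter))
    sop_instance <- dicom_uid(paste0("sc-", i, "-",
                                     digest::digest(payload, algo = "sha1")))
    els <- c(
      dicom_common_elements(uid_sc_storage(), sop_instance,
                            dicom_uid("mrsikit-study"), series_uid, "OT",
                            instance_number = i),
      list(
        dicom_el(0x0008, 0x0064, "CS", "WSD"),
        dicom_el(0x0028, 0x0002, "US", 3L),
        dicom_el(0x0028, 0x0004, "CS", "RGB"),
        dicom_el(0x0028, 0x0006, "US", 0L),
        dicom_el(0x0028, 0x0010, "US", h),
        dicom_el(0x0028, 0x0011, "US", w),
        dicom_el(0x0028, 0x0100, "US", 8L),
        dicom_el(0x0028, 0x0101, "US", 8L),
        dicom_el(0x0028, 0x0102, "US", 7L),
        dicom_el(0x0028, 0x0103, "US", 0L),
        dicom_el(0x7FE0, 0x0010, "OB", payload)
      )
    )
    dicom_write_file(paths[i], uid_sc_storage(), sop_instance, els)
  }
  paths
}

#' Read one Secondary Capture instance back as an RGB raster
#'
#' @param path a Secondary Capture file written by
#'   [write_secondary_capture()].
#' @return list with `image` (integer array `(h, w, 3)`), `instance_number`,
#'   and `series_uid`.
#' @export
read_secondary_capture <- function(path) {
  f <- read_dicom_file(path)
  sop <- dicom_require(f$dataset, 0x0008, 0x0016, "SOPClassUID")
  if (!identical(sop, uid_sc_storage()))
    stop("not a Secondary Capture instance; found SOP class ", sop)
  h <- dicom_require(f$dataset, 0x0028, 0x0010, "Rows")
  w <- dicom_require(f$dataset, 0x0028, 0x0011, "Columns")
  payload <- dicom_require(f$dataset, 0x7FE0, 0x0010, "PixelData")
  inter <- as.integer(payload[seq_len(h * w * 3L)])
  img <- aperm(array(inter, dim = c(3L, w, h)), c(3, 2, 1))
  list(image = img,
       instance_number = as.integer(dicom_get(f$dataset, 0x0020, 0x0013, "0")),
       series_uid = dicom_get(f$dataset, 0x0020, 0x000E, ""))
}
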