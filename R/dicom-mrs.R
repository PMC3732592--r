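PRIV_GROUP <- 0x7777

geometry_elements <- function(g) {
  els <- list(
    dicom_el(0x0020, 0x0037, "DS", format_ds(g$orientation)),
    dicom_el(0x0028, 0x0030, "DS", format_ds(c(g$spacing[2], g$spacing[1]))),
    dicom_el(0x0018, 0x0050, "DS", format_ds(g$spacing[3])),
    dicom_el(0x0018, 0x0088, "DS", format_ds(g$spacing[3]))
  )
  frames <- lapply(seq_len(g$dims[3]), function(k) {
    pos <- voxel_center(g, 0L, 0L, k - 1L)
    list(dicom_el(0x0020, 0x9113, "SQ", list(list(
      dicom_el(0x0020, 0x0032, "DS", format_ds(pos))))))
  })
  c(els, list(dicom_el(0x5200, 0x9230, "SQ", frames)))
}

geometry_from_elements <- function(dataset, dims) {
  orient <- as.numeric(dicom_require(dataset, 0x0020, 0x0037,
                                     "ImageOrientationPatient"))
  px <- as.numeric(dicom_require(dataset, 0x0028, 0x0030, "PixelSpacing"))
  dz <- as.numeric(dicom_get(dataset, 0x0018, 0x0088,
                             dicom_get(dataset, 0x0018, 0x0050, "1")))
  pf <- dicom_require(dataset, 0x5200, 0x9230, "PerFrameFunctionalGroups")
  pos0 <- as.numeric(pf[[1]][[tag_key(0x0020, 0x9113)]]$value[[1]][[
    tag_key(0x0020, 0x0032)]]$value)
  mrs_geometry(origin = pos0, spacing = c(px[2], px[1], dz), dims = dims,
               orientation = orient)
}

slab_item <- function(thickness, orientation, mid) {
  list(dicom_el(0x0018, 0x9104, "FD", thickness),
       dicom_el(0x0018, 0x9105, "FD", orientation),
       dicom_el(0x0018, 0x9106, "FD", mid))
}

localization_elements <- function(ds) {
  items <- list()
  n_sel <- 0L
  if (!is.null(ds$selection)) {
    g <- ds$geometry
    axes <- list(g$orientation[1:3], g$orientation[4:6], slice_direction(g))
    for (a in 1:3)
      items <- c(items, list(slab_item(ds$selection$size[a], axes[[a]],
                                       ds$selection$center)))
    n_sel <- 3L
  }
  for (sb in ds$sat_bands)
    items <- c(items, list(slab_item(sb$thickness, sb$normal,
                                     sb$normal * sb$distance)))
  els <- list(dicom_el(PRIV_GROUP, 0x1041, "US", n_sel))
  if (length(items))
    els <- c(els, list(dicom_el(0x0018, 0x9126, "SQ", items)))
  els
}

localization_from_elements <- function(dataset) {
  n_sel <- dicom_get(dataset, PRIV_GROUP, 0x1041, 0L)
  seq_el <- dicom_get(dataset, 0x0018, 0x9126)
  selection <- NULL
  sat_bands <- list()
  if (!is.null(seq_el)) {
    get_slab <- function(item) list(
      thickness = item[[tag_key(0x0018, 0x9104)]]$value,
      orientation = item[[tag_key(0x0018, 0x9105)]]$value,
      mid = item[[tag_key(0x0018, 0x9106)]]$value)
    slabs <- lapply(seq_el, get_slab)
    if (n_sel == 3L && length(slabs) >= 3L) {
      selection <- selection_box(center = slabs[[1]]$mid,
                                 size = vapply(slabs[1:3], `[[`,
                                               numeric(1), "thickness"))
      slabs <- slabs[-(1:3)]
    }
    sat_bands <- lapply(slabs, function(s) {
      d <- sum(s$mid * s$orientation)
      sat_band(s$orientation, d, s$thickness)
    })
  }
  list(selection = selection, sat_bands = sat_bands)
}

#' Write a dataset as a DICOM MR Spectroscopy Storage instance
#'
#' Encodes a reconstructed (image-domain, single-channel) dataset in the
#' standard MR Spectroscopy SOP class (`1.2.840.10008.5.1.4.1.1.4.2`),
#' Explicit VR Little Endian. The spectral payload goes into Spectroscopy
#' Data (5600,0020) as 32-bit float interleaved real/imaginary values ordered
#' frame (z), then row (y), then column (x), then spectral point (fastest);
#' axis metadata in Spectral Width (0018,9052), Transmitter Frequency
#' (0018,9098), Chemical Shift Reference (0018,9053) and Resonant Nucleus
#' (0018,9100); geometry in the per-frame plane positions; the selection box
#' and sat bands in the Volume Localization Sequence (0018,9126).
#'
#' @param ds a single-channel, image-domain [mrs_dataset()]; the spectral
#'   domain may be time or frequency (recorded in Signal Domain Columns).
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_dicom_mrs <- function(ds, path) {
  if (ds$channel_count != 1L)
    stop("write_dicom_mrs requires single-channel data (", ds$channel_count,
         " channels found): run combine_coils() first")
  if (!all(ds$spatial_domain == "image"))
    stop("write_dicom_mrs requires image-domain spatial data: run spatial_recon() first")
  d <- dim(ds$data)
  ax <- ds$spectral_axis
  # frame(z) -> row(y) -> column(x) -> spectral point, point fastest
  ordered <- as.vector(aperm(ds$data[, , , , 1, drop = FALSE][, , , , 1],
                             c(4, 1, 2, 3)))
  inter <- numeric(2L * length(ordered))
  inter[c(TRUE, FALSE)] <- Re(ordered)
  inter[c(FALSE, TRUE)] <- Im(ordered)
  payload <- writeBin(inter, raw(), size = 4L, endian = "little")
  sop_instance <- dicom_uid(paste0("mrs-instance-",
                                   digest::digest(payload, algo = "sha1")))
  els <- c(
    dicom_common_elements(uid_mrs_storage(), sop_instance,
                          dicom_uid("mrsikit-study"),
                          dicom_uid(paste0("mrs-series-", sop_instance)),
                          "MR"),
    list(
      dicom_el(0x0028, 0x0010, "US", d[2]),
      dicom_el(0x0028, 0x0011, "US", d[1]),
      dicom_el(0x0028, 0x0008, "IS", as.character(d[3])),
      dicom_el(0x0028, 0x9001, "UL", 1L),
      dicom_el(0x0028, 0x9002, "UL", d[4]),
      dicom_el(0x0028, 0x9003, "CS",
               if (ax$domain == "time") "TIME" else "FREQUENCY"),
      dicom_el(0x0028, 0x9108, "CS", "COMPLEX"),
      dicom_el(0x0018, 0x9052, "FD", ax$sweep_width),
      dicom_el(0x0018, 0x9053, "FD", ax$ppm_ref),
      dicom_el(0x0018, 0x9098, "FD", ax$f0),
      dicom_el(0x0018, 0x9100, "CS", "1H"),
      dicom_el(PRIV_GROUP, 0x0010, "LO", "MRSIKIT RAW 1.0"),
      dicom_el(0x5600, 0x0020, "OF", payload)
    ),
    geometry_elements(ds$geometry),
    localization_elements(ds)
  )
  dicom_write_file(path, uid_mrs_storage(), sop_instance, els)
}

#' Read a DICOM MR Spectroscopy Storage instance
#'
#' Inverse of [write_dicom_mrs()] on files this package wrote; a tolerant
#' reader for the named attributes on compliant Explicit VR Little Endian
#' MRS instances generally.
#'
#' @param path an MRS Storage file.
#' @return an [mrs_dataset()] (single channel, image domain).
#' @export
read_dicom_mrs <- function(path) {
  f <- read_dicom_file(path)
  sop <- dicom_require(f$dataset, 0x0008, 0x0016, "SOPClassUID")
  if (!identical(sop, uid_mrs_storage()))
    stop("not an MR Spectroscopy Storage instance; found SOP class ", sop)
  rows <- dicom_require(f$dataset, 0x0028, 0x0010, "Rows")
  cols <- dicom_require(f$dataset, 0x0028, 0x0011, "Columns")
  frames <- as.integer(dicom_get(f$dataset, 0x0028, 0x0008, "1"))
  npts <- dicom_require(f$dataset, 0x0028, 0x9002, "DataPointColumns")
  domain <- if (identical(dicom_get(f$dataset, 0x0028, 0x9003, "TIME"),
                          "FREQUENCY")) "frequency" else "time"
  sw <- dicom_require(f$dataset, 0x0018, 0x9052, "SpectralWidth")
  f0 <- dicom_require(f$dataset, 0x0018, 0x9098, "TransmitterFrequency")
  ppm_ref <- dicom_get(f$dataset, 0x0018, 0x9053, 4.7)
  payload <- f$dataset[[tag_key(0x5600, 0x0020)]]
  if (is.null(payload))
    stop("corrupt MRS instance: missing Spectroscopy Data (5600,0020)")
  expected <- 8 * rows * cols * frames * npts
  if (length(payload$value) != expected)
    stop(sprintf("corrupt MRS instance: Spectroscopy Data has %d bytes, expected %d",
                 length(payload$value), expected))
  inter <- readBin(payload$value, "numeric", 2 * rows * cols * frames * npts,
                   size = 4L, endian = "little")
  z <- complex(real = inter[c(TRUE, FALSE)], imaginary = inter[c(FALSE, TRUE)])
  arr <- aperm(array(z, dim = c(npts, cols, rows, frames)), c(2, 3, 4, 1))
  dims <- c(cols, rows, frames)
  geom <- geometry_from_elements(f$dataset, dims)
  loc <- localization_from_elements(f$dataset)
  axis <- spectral_axis(npts, 1 / sw, f0, ppm_ref, sweep_width = sw,
                        domain = domain)
  ds <- mrs_dataset(array(arr, dim = c(dims, npts, 1L)), axis, geom,
                    spatial_domain = c("image", "image", "image"),
                    selection = loc$selection, sat_bands = loc$sat_bands)
  prov_append(ds, "read_dicom_mrs", list(path = path))
}
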