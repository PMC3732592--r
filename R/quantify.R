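#' A metabolite peak-quantification window
#'
#' @param name metabolite name (becomes the map label prefix).
#' @param ppm_lo,ppm_hi window bounds in ppm (`ppm_lo < ppm_hi`).
#' @param mode quantify the `"real"` part (phased spectra, default) or the
#'   `"magnitude"` (unphased or sum-of-squares-combined data).
#' @return an object of class `peak_window`.
#' @export
peak_window <- function(name, ppm_lo, ppm_hi, mode = c("real", "magnitude")) {
  mode <- match.arg(mode)
  if (ppm_lo >= ppm_hi) stop("ppm_lo must be < ppm_hi")
  structure(list(name = name, ppm_lo = ppm_lo, ppm_hi = ppm_hi, mode = mode),
            class = "peak_window")
}

#' Default quantification windows for brain 1H MRSI
#'
#' Choline 3.12-3.32 ppm, creatine 2.93-3.13 ppm, N-acetylaspartate
#' 1.91-2.11 ppm.
#'
#' @param mode `"real"` or `"magnitude"`, applied to all three windows.
#' @return named list of [peak_window()] objects.
#' @export
default_windows <- function(mode = "real") {
  list(cho = peak_window("cho", 3.12, 3.32, mode),
       cr  = peak_window("cr", 2.93, 3.13, mode),
       naa = peak_window("naa", 1.91, 2.11, mode))
}

window_part <- function(ds, w) {
  require_spectral_domain(ds, "frequency", "quantification")
  if (ds$channel_count != 1L)
    stop("quantification requires single-channel data: run combine_coils() first")
  bins <- window_bins(ds$spectral_axis, c(w$ppm_lo, w$ppm_hi))
  if (length(bins) < 2L)
    stop("window '", w$name, "' maps to fewer than 2 spectral bins")
  s <- ds$data[, , , bins, 1, drop = FALSE]
  if (w$mode == "real") Re(s) else Mod(s)
}

#' Peak-height metabolite map
#'
#' Per voxel, the maximum of the selected spectral part (real or magnitude)
#' over the window's bins.
#'
#' @param ds a frequency-domain, single-channel [mrs_dataset()].
#' @param w a [peak_window()].
#' @return a [metabolite_map()] labelled `<name>_height`, sharing the
#'   dataset's geometry.
#' @export
peak_height_map <- function(ds, w) {
  part <- window_part(ds, w)
  vals <- apply(part, 1:3, max)
  metabolite_map(vals, ds$geometry, paste0(w$name, "_height"))
}

#' Integrated-area metabolite map
#'
#' Per voxel, the Riemann sum of the selected spectral part over the window's
#' bins times the bin width in Hz.
#'
#' @inheritParams peak_height_map
#' @return a [metabolite_map()] labelled `<name>_area`.
#' @export
peak_area_map <- function(ds, w) {
  part <- window_part(ds, w)
  df <- hz_per_bin(ds$spectral_axis)
  vals <- apply(part, 1:3, sum) * df
  metabolite_map(vals, ds$geometry, paste0(w$name, "_area"))
}

#' Per-voxel spectral noise estimate
#'
#' Standard deviation of the real part of the spectrum over a signal-free ppm
#' region.
#'
#' @param ds a frequency-domain, single-channel [mrs_dataset()].
#' @param region_ppm `c(lo, hi)` ppm interval containing no metabolite
#'   signal.
#' @param windows list of configured [peak_window()]s; the region must not
#'   overlap any of them.
#' @return a [metabolite_map()] labelled `noise_sigma`.
#' @export
estimate_noise <- function(ds, region_ppm = c(6.5, 8.0),
                           windows = default_windows()) {
  for (w in windows)
    if (region_ppm[1] < w$ppm_hi && region_ppm[2] > w$ppm_lo)
      stop("noise region overlaps metabolite window '", w$name, "'")
  require_spectral_domain(ds, "frequency", "estimate_noise")
  bins <- window_bins(ds$spectral_axis, region_ppm)
  s <- Re(ds$data[, , , bins, 1, drop = FALSE])
  vals <- apply(s, 1:3, stats::sd)
  metabolite_map(vals, ds$geometry, "noise_sigma")
}

#' Masked metabolite ratio map
#'
#' Voxelwise `numerator / denominator`, masked where the denominator does not
#' clear `k_mask` times the noise level (default 4), so that ratios are only
#' reported where the denominator carries real signal — voxels outside the
#' excitation volume come out masked. Labelled `"cho_naa_index"` when the
#' inputs are choline and N-acetylaspartate maps.
#'
#' @param numerator,denominator [metabolite_map()]s on the same geometry.
#' @param noise_sigma scalar noise level or a `noise_sigma` map.
#' @param k_mask denominator threshold in noise multiples (default 4).
#' @return a [metabolite_map()]; masked voxels hold `NA`.
#' @export
ratio_map <- function(numerator, denominator, noise_sigma = 0, k_mask = 4) {
  g1 <- numerator$geometry; g2 <- denominator$geometry
  if (!isTRUE(all.equal(g1$origin, g2$origin)) ||
      !isTRUE(all.equal(g1$spacing, g2$spacing)) ||
      !all(g1$dims == g2$dims) ||
      !isTRUE(all.equal(g1$orientation, g2$orientation)))
    stop("numerator and denominator geometries do not match")
  sig <- if (inherits(noise_sigma, "metabolite_map")) noise_sigma$values
         else array(noise_sigma, dim = g1$dims)
  ok <- numerator$mask & denominator$mask & denominator$values > k_mask * sig
  vals <- array(NA_real_, dim = g1$dims)
  vals[ok] <- numerator$values[ok] / denominator$values[ok]
  label <- if (grepl("^cho", numerator$label) && grepl("^naa", denominator$label))
    "cho_naa_index" else paste0(numerator$label, "_over_", denominator$label)
  metabolite_map(vals, g1, label, mask = ok)
}

#' Export a metabolite map as NIfTI
#'
#' Writes the map as a NIfTI-1 volume (geometry carried in the sform) for
#' cross-tool analysis alongside the DICOM export. Masked voxels are written
#' as 0.
#'
#' @param map a [metabolite_map()].
#' @param path output `.nii` / `.nii.gz` path.
#' @return invisibly, the path written.
#' @export
write_map_nifti <- function(map, path) {
  vals <- map$values
  vals[!map$mask] <- 0
  g <- map$geometry
  r <- g$orientation[1:3]; cc <- g$orientation[4:6]; s <- slice_direction(g)
  # LPS (DICOM) to RAS (NIfTI): negate the first two coordinates
  flip <- c(-1, -1, 1)
  m <- cbind(r * g$spacing[1] * flip, cc * g$spacing[2] * flip,
             s * g$spacing[3] * flip, g$origin * flip)
  xform <- rbind(m, c(0, 0, 0, 1))
  img <- RNifti::asNifti(vals)
  img <- RNifti::`sform<-`(img, structure(xform, code = 1L))
  RNifti::writeNifti(img, path)
  invisible(path)
}
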