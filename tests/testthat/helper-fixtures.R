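# Fixture builders shared across the suite. Everything is generated in code
# at test time; nothing is read from disk except files the tests write.

# A small, fast phantom configuration (spectral and spatial content identical
# in kind to the default, just smaller); regions are rescaled to the grid.
small_cfg <- function(...) {
  regions <- list(
    phantom_region("normal", center = c(2.2, 3.5, 0.5),
                   semi_axes = c(1.4, 1.9, 0.9),
                   scales = c(naa = 1.0, cr = 1.0, cho = 0.5, water = 1.0)),
    phantom_region("tumor", center = c(5.2, 3.5, 0.5),
                   semi_axes = c(1.4, 1.9, 0.9),
                   scales = c(naa = 0.6, cr = 1.0, cho = 1.2, water = 1.0)))
  phantom_config(dims = c(8L, 8L, 2L), n_points = 256L, regions = regions, ...)
}

# Generate a phantom into a temp file and return paths + objects.
make_phantom <- function(cfg = small_cfg()) {
  path <- tempfile(fileext = ".raw")
  res <- generate_phantom(cfg, path)
  list(cfg = cfg, path = path, truth_path = res$truth_path,
       truth = read_phantom_truth(res$truth_path))
}

# One-voxel dataset around a list of metabolite specs.
voxel_ds <- function(metabolites, n = 512L, dwell = 1e-3, f0 = 127.7,
                     ppm_ref = 4.7) {
  ax <- spectral_axis(n, dwell, f0, ppm_ref, domain = "time")
  fid <- simulate_voxel_fid(metabolites, ax)
  mrs_dataset(array(fid, dim = c(1, 1, 1, n, 1)), ax)
}

# A frequency-domain singlet whose peak sits exactly on a spectral bin
# (offset = bins_off * SW/N from the carrier), so lineshape sampling is
# symmetric and closed-form checks are clean.
on_grid_ppm <- function(bins_off, n = 512L, sw = 1000, f0 = 127.7,
                        ppm_ref = 4.7) {
  ppm_ref - (bins_off * sw / n) / f0
}

# Parse files with an independent DICOM implementation (pydicom); returns a
# character vector "OK <sop-class>" / "FAIL <message>" per file.
pydicom_check <- function(paths) {
  script <- paste(
    "import sys, pydicom",
    "for p in sys.argv[1:]:",
    "    try:",
    "        d = pydicom.dcmread(p)",
    "        print('OK', d.SOPClassUID)",
    "    except Exception as e:",
    "        print('FAIL', e)",
    sep = "\n")
  sf <- tempfile(fileext = ".py")
  writeLines(script, sf)
  system2("python", c(sf, paths), stdout = TRUE)
}

# Region-wise median Cho/NAA ratio recovered from height maps, one value per
# phantom region.
recovered_region_ratios <- function(cho, naa, truth) {
  nreg <- dim(truth$region_masks)[4]
  vapply(seq_len(nreg), function(r) {
    m <- truth$region_masks[, , , r]
    stats::median(cho$values[m] / naa$values[m])
  }, numeric(1))
}

# The reconstruction pipeline used for end-to-end recovery checks.
recon_pipeline <- function(path, broadening = 4, zf = 2,
                           first_point_half = TRUE) {
  ds <- map_acquisition(read_mrsraw(path))
  ds <- apodize(ds, broadening)
  ds <- zero_fill(ds, dim(ds$data)[4] * zf)
  ds <- spatial_recon(ds)
  spectral_fft(ds, first_point_half = first_point_half)
}
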