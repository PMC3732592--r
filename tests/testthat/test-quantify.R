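freq_phantom <- function(cfg = small_cfg(), fph = TRUE) {
  ph <- make_phantom(cfg)
  list(ds = recon_pipeline(ph$path, broadening = 4, zf = 2,
                           first_point_half = fph),
       truth = ph$truth, cfg = cfg)
}

test_that("zero spectra give zero maps; bad windows error", {
  n <- 128L
  ax <- spectral_axis(n, 1e-3, 127.7, domain = "frequency")
  ds <- mrs_dataset(array(0i, dim = c(2, 2, 1, n, 1)), ax)
  w <- peak_window("cho", 3.12, 3.32)
  expect_true(all(peak_height_map(ds, w)$values == 0))
  expect_true(all(peak_area_map(ds, w)$values == 0))
  expect_error(peak_height_map(ds, peak_window("x", 30, 31)),
               "outside axis range")
  expect_error(peak_window("x", 3.32, 3.12), "ppm_lo")
})

test_that("peak area approaches the analytic Lorentzian total and is additive", {
  # on-grid absorptive singlet; window spans 20 FWHM around the peak
  d <- 2; a <- 3
  ppm <- on_grid_ppm(150)
  ds <- spectral_fft(voxel_ds(list(metabolite_spec("s", ppm, d, a))),
                     first_point_half = TRUE)
  half_w <- 10 * d / 127.7
  w <- peak_window("s", ppm - half_w, ppm + half_w)
  area <- peak_area_map(ds, w)$values[1]
  # analytic absorption-mode total in package units (unscaled DFT, bin-width
  # Riemann sum): a * SW / 2 for the one-sided FID
  expect_equal(area, a * 1000 / 2, tolerance = 0.05)

  # additivity over adjacent disjoint windows
  wl <- peak_window("l", ppm - half_w, ppm)
  wr <- peak_window("r", ppm, ppm + half_w)
  al <- peak_area_map(ds, wl)$values[1]
  ar <- peak_area_map(ds, wr)$values[1]
  bins_l <- mrsikit:::window_bins(ds$spectral_axis, c(ppm - half_w, ppm))
  bins_r <- mrsikit:::window_bins(ds$spectral_axis, c(ppm, ppm + half_w))
  if (length(intersect(bins_l, bins_r)) == 0) {
    expect_equal(al + ar, area, tolerance = 1e-12)
  }
})

test_that("peak heights recover ground-truth region ratios within 2%", {
  fp <- freq_phantom()
  cho <- peak_height_map(fp$ds, peak_window("cho", 3.12, 3.32))
  naa <- peak_height_map(fp$ds, peak_window("naa", 1.91, 2.11))
  ratios <- recovered_region_ratios(cho, naa, fp$truth)
  expect_equal(ratios, fp$truth$region_cho_naa_ratio, tolerance = 0.02)
  # all maps share the source geometry
  expect_identical(cho$geometry, fp$ds$geometry)
  expect_identical(cho$label, "cho_height")
})

test_that("peak height is stable under zero-filling (interpolation)", {
  ppm <- on_grid_ppm(150.25)  # quarter-bin off-grid
  mets <- list(metabolite_spec("s", ppm, 6, 1))
  base <- apodize(voxel_ds(mets), 4)
  h1 <- peak_height_map(spectral_fft(base, first_point_half = TRUE),
                        peak_window("s", ppm - 0.1, ppm + 0.1))$values[1]
  h2 <- peak_height_map(spectral_fft(zero_fill(base, 1024L),
                                     first_point_half = TRUE),
                        peak_window("s", ppm - 0.1, ppm + 0.1))$values[1]
  expect_equal(h2, h1, tolerance = 0.01)
})

test_that("noise estimates propagate the injected sigma", {
  # noiseless, in memory: signal-free voxels give exactly zero sigma, and
  # in-region sigma (Lorentzian tails and truncation ringing only) stays far
  # below the peak scale
  cfg0 <- small_cfg(noise_sigma = 0)
  vox <- mrsikit:::phantom_voxel_data(cfg0)
  ds0 <- spectral_fft(mrs_dataset(vox, mrsikit:::phantom_axis(cfg0),
                                  mrsikit:::phantom_geometry(cfg0)))
  sig0 <- estimate_noise(ds0)$values
  truth0 <- mrsikit:::phantom_amplitudes(cfg0)
  outside <- truth0[, , , "naa"] == 0
  expect_lt(max(sig0[outside]), 1e-10)
  naa_h <- peak_height_map(ds0, peak_window("naa", 1.91, 2.11))$values
  expect_lt(max(sig0[!outside] / naa_h[!outside]), 0.01)

  # known sigma: plain FFT pipeline so the propagation is analytic:
  # sigma_spec = sigma * sqrt(N_spec) / sqrt(N_spatial)
  sigma <- 2
  cfg <- small_cfg(noise_sigma = sigma, seed = 7)
  ph <- make_phantom(cfg)
  ds <- spectral_fft(spatial_recon(map_acquisition(read_mrsraw(ph$path))))
  est <- median(estimate_noise(ds)$values)
  pred <- sigma * sqrt(cfg$n_points) / sqrt(prod(cfg$dims))
  expect_equal(est, pred, tolerance = 0.15)

  # linear scaling with injected sigma (x10)
  cfg10 <- small_cfg(noise_sigma = 10 * sigma, seed = 7)
  ph10 <- make_phantom(cfg10)
  ds10 <- spectral_fft(spatial_recon(map_acquisition(read_mrsraw(ph10$path))))
  est10 <- median(estimate_noise(ds10)$values)
  expect_equal(est10 / est, 10, tolerance = 0.05)

  expect_error(estimate_noise(ds, c(3.0, 3.5)), "overlaps")
})

test_that("ratio maps mask unreliable voxels and are scale-invariant", {
  fp <- freq_phantom(small_cfg(noise_sigma = 1e-4, seed = 12))
  cho <- peak_height_map(fp$ds, peak_window("cho", 3.12, 3.32))
  naa <- peak_height_map(fp$ds, peak_window("naa", 1.91, 2.11))
  noise <- estimate_noise(fp$ds)
  r <- ratio_map(cho, naa, noise)
  expect_identical(r$label, "cho_naa_index")

  # identical maps give ratio 1 wherever unmasked
  r1 <- ratio_map(naa, naa, noise)
  expect_true(all(abs(r1$values[r1$mask] - 1) < 1e-12))

  # voxels with no metabolite signal (outside the regions) are masked
  outside <- fp$truth$amplitudes[, , , "naa"] == 0
  expect_false(any(r$mask[outside]))
  in_regions <- fp$truth$amplitudes[, , , "naa"] > 0
  expect_true(mean(r$mask[in_regions]) > 0.9)

  # scale invariance: scaling the dataset leaves unmasked ratios unchanged
  scaled <- fp$ds; scaled$data <- scaled$data * 5
  cho5 <- peak_height_map(scaled, peak_window("cho", 3.12, 3.32))
  naa5 <- peak_height_map(scaled, peak_window("naa", 1.91, 2.11))
  r5 <- ratio_map(cho5, naa5, estimate_noise(scaled))
  expect_equal(r5$values[r5$mask & r$mask], r$values[r5$mask & r$mask],
               tolerance = 1e-9)

  other <- metabolite_map(naa$values, mrs_geometry(dims = dim(naa$values)),
                          "naa_height")
  expect_error(ratio_map(cho, other, noise), "geometries do not match")
})

test_that("maps survive the NIfTI export with geometry", {
  fp <- freq_phantom()
  naa <- peak_height_map(fp$ds, peak_window("naa", 1.91, 2.11))
  f <- tempfile(fileext = ".nii.gz")
  write_map_nifti(naa, f)
  img <- RNifti::readNifti(f)
  expect_equal(dim(img), dim(naa$values))
  expect_equal(as.numeric(max(img)), max(naa$values), tolerance = 1e-6)
})
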