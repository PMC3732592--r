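reconstructed_ds <- function(cfg = small_cfg()) {
  ph <- make_phantom(cfg)
  combine_coils(spatial_recon(map_acquisition(read_mrsraw(ph$path))))
}

test_that("MR Spectroscopy instances carry the standard SOP class and payload layout", {
  ds <- reconstructed_ds()
  f <- tempfile(fileext = ".dcm")
  write_dicom_mrs(ds, f)
  parsed <- read_dicom_file(f)
  expect_identical(mrsikit:::dicom_get(parsed$dataset, 0x0008, 0x0016),
                   "1.2.840.10008.5.1.4.1.1.4.2")
  # (5600,0020) byte length = 8 * n_voxels * n_points
  payload <- parsed$dataset[[mrsikit:::tag_key(0x5600, 0x0020)]]
  expect_identical(length(payload$value), 8L * 8L * 8L * 2L * 256L)
})

test_that("MRS write/read is float32-lossless on data and exact on metadata", {
  ds <- reconstructed_ds()
  f <- tempfile(fileext = ".dcm")
  write_dicom_mrs(ds, f)
  back <- read_dicom_mrs(f)
  expect_lt(max(Mod(back$data - ds$data)) / max(Mod(ds$data)), 1e-6)
  expect_identical(back$geometry$origin, ds$geometry$origin)
  expect_identical(back$geometry$spacing, ds$geometry$spacing)
  expect_identical(back$geometry$orientation, ds$geometry$orientation)
  expect_equal(back$selection, ds$selection)
  expect_equal(back$sat_bands, ds$sat_bands)
  expect_equal(back$spectral_axis$sweep_width, ds$spectral_axis$sweep_width)
  expect_equal(back$spectral_axis$f0, ds$spectral_axis$f0)
  expect_equal(back$spectral_axis$ppm_ref, ds$spectral_axis$ppm_ref)
  expect_identical(back$spectral_axis$domain, ds$spectral_axis$domain)
})

test_that("MRS writer and reader enforce their preconditions", {
  ph <- make_phantom(small_cfg(channels = 2L))
  multi <- spatial_recon(map_acquisition(read_mrsraw(ph$path)))
  expect_error(write_dicom_mrs(multi, tempfile()), "combine_coils")

  kspace <- map_acquisition(read_mrsraw(make_phantom()$path))
  expect_error(write_dicom_mrs(combine_coils(kspace), tempfile()),
               "spatial_recon")

  # wrong SOP class names the offending UID
  m <- metabolite_map(array(1, dim = c(2, 2, 1)),
                      mrs_geometry(dims = c(2, 2, 1)), "x")
  f <- tempfile(fileext = ".dcm")
  write_metabolite_map_dicom(m, f)
  expect_error(read_dicom_mrs(f), "1.2.840.10008.5.1.4.1.1.4.1")
})

test_that("raw encapsulation round-trips bytes with verified SHA1", {
  f1 <- tempfile(); f2 <- tempfile()
  set.seed(13)
  writeBin(as.raw(sample(0:255, 4097, replace = TRUE)), f1)  # odd length
  writeBin(charToRaw("small payload"), f2)
  out <- tempfile(fileext = ".dcm")
  manifest <- encapsulate_raw(c(f1, f2), out)
  expect_identical(mrsikit:::dicom_get(read_dicom_file(out)$dataset,
                                       0x0008, 0x0016),
                   "1.2.840.10008.5.1.4.1.1.66")
  # digest equals an independent SHA1 implementation's
  expect_true(manifest$sha1[1] == as.character(openssl::sha1(file(f1))))

  outdir <- tempfile()
  restored <- unencapsulate_raw(out, outdir)
  for (i in 1:2) {
    orig <- readBin(c(f1, f2)[i], "raw", file.info(c(f1, f2)[i])$size)
    got <- readBin(restored[i], "raw", file.info(restored[i])$size)
    expect_identical(got, orig)
  }
})

test_that("empty payload restores as empty file with the known SHA1 of nothing", {
  f <- tempfile(); file.create(f)
  out <- tempfile(fileext = ".dcm")
  manifest <- encapsulate_raw(f, out)
  expect_identical(manifest$sha1,
                   "da39a3ee5e6b4b0d3255bfef95601890afd80709")
  restored <- unencapsulate_raw(out, tempfile())
  expect_identical(file.info(restored)$size, 0)
})

test_that("any single-bit payload corruption is detected (100 seeded flips)", {
  f1 <- tempfile()
  set.seed(13)
  payload <- as.raw(sample(0:255, 4096, replace = TRUE))
  writeBin(payload, f1)
  out <- tempfile(fileext = ".dcm")
  encapsulate_raw(f1, out)
  bytes <- readBin(out, "raw", file.info(out)$size)
  # locate the payload inside the DICOM stream by its leading bytes
  start <- NA_integer_
  for (i in seq_len(length(bytes) - 16L)) {
    if (all(bytes[i:(i + 15L)] == payload[1:16])) { start <- i; break }
  }
  expect_false(is.na(start))
  set.seed(1)
  offs <- sample(4096L, 100L, replace = TRUE)
  bits <- sample(0:7, 100L, replace = TRUE)
  for (j in 1:100) {
    corrupted <- bytes
    pos <- start + offs[j] - 1L
    corrupted[pos] <- xor(corrupted[pos], as.raw(bitwShiftL(1L, bits[j])))
    cf <- tempfile(fileext = ".dcm")
    writeBin(corrupted, cf)
    expect_error(unencapsulate_raw(cf, tempfile()),
                 "integrity error.*digests to")
  }
})

test_that("Enhanced MR map export quantizes within one 16-bit step", {
  g <- mrs_geometry(origin = c(-35, -35, -5), spacing = c(10, 10, 10),
                    dims = c(8, 8, 2))
  set.seed(21)
  vals <- array(rnorm(128, 50, 20), dim = c(8, 8, 2))
  mask <- array(runif(128) > 0.2, dim = c(8, 8, 2))
  m <- metabolite_map(vals, g, "cho_height", mask)
  f <- tempfile(fileext = ".dcm")
  write_metabolite_map_dicom(m, f)
  back <- read_metabolite_map_dicom(f)
  step <- (max(vals) - min(vals)) / 65535
  expect_lte(max(abs(back$values - vals)), step)
  expect_identical(back$mask, mask)
  expect_identical(back$label, "cho_height")
  expect_identical(back$geometry$origin, g$origin)

  # constant map reproduces the constant exactly
  cm <- metabolite_map(array(7.5, dim = c(8, 8, 2)), g, "const")
  fc <- tempfile(fileext = ".dcm")
  write_metabolite_map_dicom(cm, fc)
  expect_equal(read_metabolite_map_dicom(fc)$values,
               array(7.5, dim = c(8, 8, 2)))

  # NaN in an unmasked voxel is an error; in a masked voxel it is not
  bad <- m; bad$values[1] <- NaN; bad$mask[1] <- TRUE
  expect_error(write_metabolite_map_dicom(bad, tempfile()), "non-finite")
  okm <- m; okm$values[1] <- NaN; okm$mask[1] <- FALSE
  expect_silent(write_metabolite_map_dicom(okm, tempfile(fileext = ".dcm")))
})

test_that("secondary capture series numbers instances and round-trips pixels", {
  set.seed(5)
  imgs <- lapply(1:3, function(i)
    array(as.integer(sample(0:255, 32 * 48 * 3, replace = TRUE)),
          dim = c(32, 48, 3)))
  paths <- write_secondary_capture(imgs, tempfile(fileext = ".dcm"))
  expect_length(paths, 3)
  got <- lapply(paths, read_secondary_capture)
  expect_identical(vapply(got, `[[`, 0L, "instance_number"), 1:3)
  expect_length(unique(vapply(got, `[[`, "", "series_uid")), 1)
  for (i in 1:3) expect_identical(got[[i]]$image, imgs[[i]])
  expect_error(write_secondary_capture(list(), tempfile()), "empty")
  expect_error(write_secondary_capture(list(imgs[[1]],
                                            array(0L, c(2, 2, 3))),
                                       tempfile()), "equal-size")
})

test_that("all DICOM writers produce files an independent parser opens", {
  ds <- reconstructed_ds()
  mrsf <- tempfile(fileext = ".dcm"); write_dicom_mrs(ds, mrsf)
  rawf <- tempfile(fileext = ".dcm"); encapsulate_raw(mrsf, rawf)
  mapf <- tempfile(fileext = ".dcm")
  write_metabolite_map_dicom(
    metabolite_map(array(1:128, dim = c(8, 8, 2)), ds$geometry, "x"), mapf)
  scf <- write_secondary_capture(list(array(0L, c(16, 16, 3))),
                                 tempfile(fileext = ".dcm"))
  res <- pydicom_check(c(mrsf, rawf, mapf, scf))
  expect_identical(sum(grepl("^OK", res)), 4L)
})
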