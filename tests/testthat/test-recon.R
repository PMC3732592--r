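singlet_time <- function(d = 6, bins_off = 180, n = 512L, a = 1, phase = 0) {
  voxel_ds(list(metabolite_spec("s", on_grid_ppm(bins_off, n), d, a, phase)),
           n = n)
}

test_that("apodization windows match their closed forms and broaden as stated", {
  ds <- singlet_time()
  # L = 0 is the identity
  expect_identical(apodize(ds, 0)$data, ds$data)
  # lorentzian window value at n = 100, dt = 1 ms, L = 10: exp(-pi)
  one <- mrs_dataset(array(1 + 0i, dim = c(1, 1, 1, 512, 1)),
                     spectral_axis(512, 1e-3, 127.7, domain = "time"))
  w <- apodize(one, 10)$data[1, 1, 1, 101, 1]
  expect_equal(Re(w), exp(-pi), tolerance = 1e-12)

  # FWHM of a d-Hz singlet grows to d + L within 5%
  fwhm <- function(ds_t, L) {
    dsa <- if (L > 0) apodize(ds_t, L) else ds_t
    dsa <- zero_fill(dsa, 4096L)
    spec <- Re(spectral_fft(dsa, first_point_half = TRUE)$data[1, 1, 1, , 1])
    pk <- which.max(spec)
    half <- spec[pk] / 2
    lo <- max(which(spec[1:pk] <= half))
    hi <- pk + min(which(spec[(pk + 1):length(spec)] <= half))
    interp <- function(i0, i1) i0 + (half - spec[i0]) / (spec[i1] - spec[i0])
    dfbin <- 1000 / 4096
    (interp(hi - 1, hi) - interp(lo + 1, lo)) * dfbin
  }
  expect_equal(fwhm(ds, 0), 6, tolerance = 0.05)
  expect_equal(fwhm(ds, 10), 16, tolerance = 0.05)
  expect_error(apodize(spectral_fft(ds), 4), "time-domain")
})

test_that("zero filling extends FIDs without touching existing samples", {
  ds <- singlet_time()
  expect_identical(zero_fill(ds, 512L)$data, ds$data)
  zf <- zero_fill(ds, 1024L)
  expect_identical(zf$data[, , , 1:512, , drop = FALSE], ds$data)
  expect_true(all(zf$data[, , , 513:1024, ] == 0))
  expect_identical(zf$spectral_axis$n_points, 1024L)
  expect_equal(zf$spectral_axis$sweep_width, ds$spectral_axis$sweep_width)
  expect_error(zero_fill(ds, 256L), ">=")

  # DFT interpolation: filled spectrum at original bin centres is unchanged
  s0 <- spectral_fft(ds)$data[1, 1, 1, , 1]
  s1 <- spectral_fft(zf)$data[1, 1, 1, , 1]
  expect_equal(s1[seq(1, 1024, by = 2)], s0, tolerance = 1e-12)
})

test_that("spatial recon inverts the centred forward DFT", {
  # uniform image <- k-space delta at the centred origin
  n <- c(8L, 8L, 2L)
  k <- array(0i, dim = c(n, 4L, 1L))
  k[n[1] %/% 2 + 1, n[2] %/% 2 + 1, n[3] %/% 2 + 1, , 1] <- 128 + 0i
  ds <- mrs_dataset(k, spectral_axis(4, 1e-3, 127.7),
                    spatial_domain = "kspace")
  img <- spatial_recon(ds)
  expect_equal(max(Mod(img$data - 1)), 0, tolerance = 1e-12)
  expect_identical(img$spatial_domain, rep("image", 3))
  expect_error(spatial_recon(img), "k-space")
})

test_that("spectral fft/ifft are exact inverses with the carrier centred", {
  ds <- voxel_ds(list(metabolite_spec("w", 4.7, 5, 2),
                      metabolite_spec("n", 2.01, 5, 1, 0.3)))
  f <- spectral_fft(ds)
  b <- spectral_ifft(f)
  expect_lt(max(Mod(b$data - ds$data)) / max(Mod(ds$data)), 1e-12)
  expect_identical(b$spectral_axis$domain, "time")

  # undamped on-carrier exponential: magnitude spectrum is a delta at floor(N/2)
  n <- 512L
  pure <- mrs_dataset(array(exp(1i * 0 * (0:(n - 1))), dim = c(1, 1, 1, n, 1)),
                      spectral_axis(n, 1e-3, 127.7, domain = "time"))
  spec <- Mod(spectral_fft(pure)$data[1, 1, 1, , 1])
  expect_identical(which.max(spec) - 1L, n %/% 2L)
  expect_lt(max(spec[-(n %/% 2L + 1L)]) / spec[n %/% 2L + 1L], 1e-12)

  expect_error(spectral_fft(f), "time-domain")
  expect_error(spectral_ifft(ds), "frequency-domain")
})

test_that("epsi phase correction compensates per-k sampling delays", {
  tau <- 5e-4
  cfg_c <- small_cfg(seed = 5)
  cfg_e <- small_cfg(seed = 5, ordering = "epsi", epsi_tau = tau)
  pc <- tempfile(); pe <- tempfile()
  generate_phantom(cfg_c, pc); generate_phantom(cfg_e, pe)
  dc <- spectral_fft(spatial_recon(map_acquisition(read_mrsraw(pc))))
  de <- spectral_fft(map_acquisition(read_mrsraw(pe)))
  expect_warning(de <- epsi_phase_correct(de, 1, tau), "wraparound")
  de <- spatial_recon(spectral_ifft(de))
  de <- spectral_fft(de)
  expect_lt(max(Mod(de$data - dc$data)) / max(Mod(dc$data)), 1e-6)
})

test_that("epsi correction identities hold", {
  ph <- make_phantom()
  ds <- spectral_fft(map_acquisition(read_mrsraw(ph$path)))
  expect_identical(epsi_phase_correct(ds, 1, 0)$data, ds$data)
  fwd <- suppressWarnings(epsi_phase_correct(ds, 1, 3e-4))
  back <- suppressWarnings(epsi_phase_correct(fwd, 1, -3e-4))
  expect_lt(max(Mod(back$data - ds$data)) / max(Mod(ds$data)), 1e-12)
})

test_that("sum-of-squares combination is magnitude-correct and phase-invariant", {
  ph <- make_phantom()
  single <- spatial_recon(map_acquisition(read_mrsraw(ph$path)))
  comb1 <- combine_coils(single)
  expect_equal(Re(comb1$data), array(Mod(single$data), dim = dim(single$data)),
               tolerance = 1e-14)
  expect_true(all(Im(comb1$data) == 0))

  # two identical channels of amplitude a give sqrt(2) * a
  two <- mrs_dataset(array(rep(single$data, 2),
                           dim = c(dim(single$data)[1:4], 2)),
                     single$spectral_axis, single$geometry)
  comb2 <- combine_coils(two)
  expect_equal(Re(comb2$data[, , , , 1]), sqrt(2) * Mod(single$data[, , , , 1]),
               tolerance = 1e-12)

  # invariance under per-channel phase rotations, 20 seeded draws
  phm <- make_phantom(small_cfg(channels = 4L, seed = 6))
  multi <- spatial_recon(map_acquisition(read_mrsraw(phm$path)))
  base <- combine_coils(multi)$data
  set.seed(2)
  for (r in 1:20) {
    rot <- multi
    th <- runif(4, -pi, pi)
    for (ch in 1:4) rot$data[, , , , ch] <- rot$data[, , , , ch] * exp(1i * th[ch])
    expect_lt(max(Mod(combine_coils(rot)$data - base)),
              1e-12 * max(Mod(base)))
  }
  expect_identical(comb1$channel_count, 1L)
})

test_that("phase correction applies phi0/phi1 about the pivot", {
  ds <- spectral_fft(singlet_time())
  expect_identical(phase_correct(ds, phase_params(0, 0, 0))$data, ds$data)
  neg <- phase_correct(ds, phase_params(pi, 0, 0))
  expect_equal(Re(neg$data), -Re(ds$data), tolerance = 1e-12)

  # dispersive singlet phased back to absorptive: imaginary part vanishes at peak
  disp <- spectral_fft(singlet_time(phase = pi / 2), first_point_half = TRUE)
  fixed <- phase_correct(disp, phase_params(-pi / 2, 0, 0))
  pk <- which.max(Mod(fixed$data[1, 1, 1, , 1]))
  expect_lt(abs(Im(fixed$data[1, 1, 1, pk, 1])),
            1e-9 * Mod(fixed$data[1, 1, 1, pk, 1]))

  # first-order term is zero at the pivot and linear across the width
  p <- phase_params(0, pi, pivot = 256L)
  ph1 <- phase_correct(ds, p)
  expect_equal(ph1$data[1, 1, 1, 257, 1], ds$data[1, 1, 1, 257, 1])
  expect_error(phase_correct(spectral_ifft(ds), phase_params()), "frequency")
})

test_that("auto_phase0 recovers simulated zero-order phase", {
  ppm <- on_grid_ppm(180)
  win <- c(ppm - 0.3, ppm + 0.3)
  for (phi in c(0, 0.8, -2.4)) {
    ds <- spectral_fft(singlet_time(phase = phi), first_point_half = TRUE)
    est <- auto_phase0(ds, win)
    expect_lt(abs(Arg(exp(1i * (est$phi0 + phi)))) * 180 / pi, 0.1)
    # invariant to overall amplitude scaling
    ds10 <- ds; ds10$data <- ds10$data * 37
    expect_equal(auto_phase0(ds10, win)$phi0, est$phi0)
  }
  ds <- spectral_fft(singlet_time())
  expect_error(auto_phase0(ds, c(9.5, 9.6)), "outside axis range|empty")
})

test_that("recon operations are value-linear, pure, and append one record each", {
  ph <- make_phantom()
  ds <- map_acquisition(read_mrsraw(ph$path))
  snapshot <- ds
  ops <- list(function(d) apodize(d, 4),
              function(d) zero_fill(d, 512L),
              function(d) spatial_recon(d),
              function(d) spectral_fft(d))
  for (op in ops) {
    out1 <- op(ds)
    expect_length(out1$provenance, length(ds$provenance) + 1L)
    # linearity: op(2x) = 2 op(x)
    dbl <- ds; dbl$data <- dbl$data * 2
    expect_equal(op(dbl)$data, out1$data * 2, tolerance = 1e-12)
  }
  expect_identical(ds, snapshot)
})
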