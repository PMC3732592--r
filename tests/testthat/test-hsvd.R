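time_axis <- function(n = 256L) spectral_axis(n, 1e-3, 127.7, domain = "time")

damped_exp <- function(t, a, f, d, phi = 0) {
  a * exp(1i * phi) * exp((1i * 2 * pi * f - d) * t)
}

test_that("hsvd_fit handles degenerate inputs per contract", {
  ax <- time_axis()
  expect_identical(hsvd_fit(complex(256), ax, hsvd_options(order = 8)), list())
  expect_error(hsvd_fit(complex(20), ax, hsvd_options(order = 15)),
               "too large")
})

test_that("hsvd_fit recovers a single noiseless component to 1e-6", {
  ax <- time_axis()
  t <- (0:255) * 1e-3
  x <- damped_exp(t, a = 2, f = 100, d = 10)
  comps <- hsvd_fit(x, ax, hsvd_options(order = 8))
  expect_gte(length(comps), 1)
  c1 <- comps[[1]]
  expect_equal(c1$amplitude, 2, tolerance = 1e-6)
  expect_equal(c1$frequency, 100, tolerance = 1e-6)
  expect_equal(c1$damping, 10, tolerance = 1e-6)
  expect_lt(abs(c1$phase), 1e-6)
})

test_that("hsvd_fit matches a nonlinear least-squares oracle on two components", {
  ax <- time_axis()
  t <- (0:255) * 1e-3
  truth <- list(c(a = 1, f = 50, d = 8, phi = 0.5),
                c(a = 3, f = 100, d = 12, phi = 0))
  x <- damped_exp(t, 1, 50, 8, 0.5) + damped_exp(t, 3, 100, 12, 0)

  comps <- hsvd_fit(x, ax, hsvd_options(order = 8))
  expect_gte(length(comps), 2)
  got <- comps[1:2]  # sorted by descending amplitude: 3 then 1

  # independent oracle: Levenberg-Marquardt on the same model, initialized
  # at truth
  resid_fun <- function(p) {
    model <- damped_exp(t, p[1], p[2], p[3], p[4]) +
      damped_exp(t, p[5], p[6], p[7], p[8])
    c(Re(x - model), Im(x - model))
  }
  nls <- minpack.lm::nls.lm(par = c(3, 100, 12, 0, 1, 50, 8, 0.5),
                            fn = resid_fun)
  p <- nls$par
  expect_equal(got[[1]]$amplitude, p[1], tolerance = 1e-6)
  expect_equal(got[[1]]$frequency, p[2], tolerance = 1e-6)
  expect_equal(got[[1]]$damping, p[3], tolerance = 1e-6)
  expect_equal(got[[2]]$amplitude, p[5], tolerance = 1e-6)
  expect_equal(got[[2]]$frequency, p[6], tolerance = 1e-6)
  expect_equal(got[[2]]$damping, p[7], tolerance = 1e-6)
  expect_lt(abs(Arg(exp(1i * (got[[2]]$phase - 0.5)))), 1e-6)

  # fitted model reproduces the FID
  model <- hsvd_model(got, ax)
  expect_lt(sqrt(mean(Mod(x - model)^2)) / sqrt(mean(Mod(x)^2)), 1e-8)
})

test_that("fit is scale-equivariant and reproduces <= K/2 component signals", {
  ax <- time_axis()
  t <- (0:255) * 1e-3
  x <- damped_exp(t, 1, -80, 6, 1.1) + damped_exp(t, 2, 40, 9, -0.7) +
    damped_exp(t, 0.5, 120, 15, 2.0)
  opts <- hsvd_options(order = 10)
  base <- hsvd_fit(x, ax, opts)
  model <- hsvd_model(base, ax)
  expect_lt(sqrt(mean(Mod(x - model)^2)) / sqrt(mean(Mod(x)^2)), 1e-8)

  scaled <- hsvd_fit(10 * x, ax, opts)
  expect_equal(vapply(scaled, `[[`, 0, "amplitude"),
               10 * vapply(base, `[[`, 0, "amplitude"), tolerance = 1e-8)
  expect_equal(vapply(scaled, `[[`, 0, "frequency"),
               vapply(base, `[[`, 0, "frequency"), tolerance = 1e-8)
  expect_equal(vapply(scaled, `[[`, 0, "damping"),
               vapply(base, `[[`, 0, "damping"), tolerance = 1e-8)
})

test_that("frequency recovery improves monotonically as noise shrinks", {
  ax <- time_axis()
  t <- (0:255) * 1e-3
  x <- damped_exp(t, 1, 100, 10)
  set.seed(3)
  noise <- complex(real = rnorm(256), imaginary = rnorm(256))
  errs <- vapply(c(0.1, 0.01, 0.001), function(s) {
    comps <- hsvd_fit(x + s * noise, ax, hsvd_options(order = 8))
    abs(comps[[1]]$frequency - 100)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("hsvd_filter removes the water band and preserves the metabolite", {
  n <- 512L
  ax <- spectral_axis(n, 1e-3, 127.7, domain = "time")
  mets <- default_metabolites()
  mets$water$base_amplitude <- 1000  # unsuppressed water
  with_water <- voxel_ds(list(mets$water, mets$naa), n = n)
  naa_only <- voxel_ds(list(mets$naa), n = n)

  filt <- hsvd_filter(with_water, c(4.2, 5.2), hsvd_options(order = 10))
  f_w <- spectral_fft(with_water)
  f_f <- spectral_fft(filt)
  f_n <- spectral_fft(naa_only)
  bins <- mrsikit:::window_bins(f_w$spectral_axis, c(4.2, 5.2))
  resid_energy <- sum(Mod(f_f$data[1, 1, 1, bins, 1])^2) /
    sum(Mod(f_w$data[1, 1, 1, bins, 1])^2)
  expect_lt(resid_energy, 1e-6)

  w <- peak_window("naa", 1.91, 2.11)
  area_f <- peak_area_map(f_f, w)$values[1]
  area_ref <- peak_area_map(f_n, w)$values[1]
  expect_lt(abs(area_f - area_ref) / area_ref, 1e-3)

  # provenance records the removed component count
  rec <- filt$provenance[[length(filt$provenance)]]
  expect_identical(rec$op, "hsvd_filter")
  expect_identical(rec$params$removed_total, 1L)
})

test_that("hsvd_filter identity and whole-band edge cases", {
  ds <- voxel_ds(list(default_metabolites()$naa))
  expect_identical(hsvd_filter(ds, c(3.0, 3.0))$data, ds$data)
  expect_error(hsvd_filter(ds, c(20, 30)), "outside axis range")

  # band covering the whole axis removes (nearly) everything
  span <- ppm_range(mrsikit:::axis_as_domain(ds$spectral_axis, "frequency"))
  all_gone <- hsvd_filter(ds, span, hsvd_options(order = 10))
  expect_lt(sum(Mod(all_gone$data)^2) / sum(Mod(ds$data)^2), 1e-6)
})
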