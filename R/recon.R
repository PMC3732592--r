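#' Zero- and first-order phase parameters
#'
#' First-order phase is expressed in radians across the full spectral width,
#' applied about an explicit pivot bin: bin `i` (0-based) receives phase
#' `phi0 + phi1 * (i - pivot) / N`, so the pivot bin sees `phi0` only.
#'
#' @param phi0 zero-order phase, radians.
#' @param phi1 first-order phase across the full width, radians.
#' @param pivot 0-based spectral index about which `phi1` is applied.
#' @return an object of class `phase_params`.
#' @export
phase_params <- function(phi0 = 0, phi1 = 0, pivot = 0L) {
  if (pivot < 0) stop("pivot must be >= 0")
  structure(list(phi0 = phi0, phi1 = phi1, pivot = as.integer(pivot)),
            class = "phase_params")
}

#' Apodize the free induction decays
#'
#' Time-domain windowing trading signal-to-noise for linewidth. The
#' Lorentzian window `exp(-pi * L * t)` adds exactly `L` Hz to the Lorentzian
#' FWHM of each resonance; the Gaussian window
#' `exp(-(pi * L * t)^2 / (4 ln 2))` has a Gaussian spectral FWHM of `L` Hz.
#'
#' @param ds a time-domain [mrs_dataset()].
#' @param broadening line broadening `L` in Hz (>= 0; 0 is the identity).
#' @param shape `"lorentzian"` (default) or `"gaussian"`.
#' @return the apodized dataset.
#' @export
apodize <- function(ds, broadening, shape = c("lorentzian", "gaussian")) {
  shape <- match.arg(shape)
  require_spectral_domain(ds, "time", "apodize")
  if (broadening < 0) stop("broadening must be >= 0")
  ax <- ds$spectral_axis
  t <- (seq_len(ax$n_points) - 1L) * ax$dwell
  w <- if (shape == "lorentzian") exp(-pi * broadening * t)
       else exp(-(pi * broadening * t)^2 / (4 * log(2)))
  ds$data <- map_spectral(ds$data, function(m) m * w)
  prov_append(ds, "apodize", list(shape = shape, broadening = broadening))
}

#' Zero-fill the free induction decays
#'
#' Extends each FID with trailing zeros to `target_points`, interpolating the
#' spectrum on a finer grid. Sweep width and dwell time are unchanged; only
#' the number of spectral points grows.
#'
#' @param ds a time-domain [mrs_dataset()].
#' @param target_points new spectral length (>= current).
#' @return the zero-filled dataset.
#' @export
zero_fill <- function(ds, target_points) {
  require_spectral_domain(ds, "time", "zero_fill")
  target_points <- as.integer(target_points)
  d <- dim(ds$data)
  if (target_points < d[4])
    stop("target_points (", target_points, ") must be >= current n_points (",
         d[4], ")")
  if (target_points > d[4]) {
    out <- array(0i, dim = c(d[1:3], target_points, d[5]))
    out[, , , seq_len(d[4]), ] <- ds$data
    ds$data <- out
    ds$spectral_axis$n_points <- target_points
  }
  prov_append(ds, "zero_fill", list(target_points = target_points))
}

#' Spatial Fourier reconstruction (k-space to image)
#'
#' Per spectral sample and channel, a centred inverse DFT along each spatial
#' axis: ifftshift, then inverse FFT with 1/N scaling, no further shift. The
#' forward model (the phantom generator) uses the matching unscaled forward
#' DFT followed by fftshift, so the pair round-trips exactly and Parseval
#' holds as `sum|image|^2 * N_spatial = sum|kspace|^2`.
#'
#' @param ds an [mrs_dataset()] with all spatial axes in k-space.
#' @return the image-domain dataset.
#' @export
spatial_recon <- function(ds) {
  if (!all(ds$spatial_domain == "kspace"))
    stop("spatial_recon requires k-space data on all spatial axes (found ",
         paste(ds$spatial_domain, collapse = "/"), ")")
  for (a in 1:3) {
    ds$data <- fft_axis(fftshift_axis(ds$data, a, inverse = TRUE), a,
                        inverse = TRUE, scale = TRUE)
  }
  ds$spatial_domain <- rep("image", 3L)
  prov_append(ds, "spatial_recon", list())
}

#' Spectral Fourier transform (time to frequency)
#'
#' Forward FFT along the spectral axis followed by fftshift, so the carrier
#' (0 Hz offset) lands at index `floor(N/2)` and ppm decreases with index.
#'
#' With `first_point_half = TRUE` the first time-domain sample is halved
#' before the transform, removing the constant real-part baseline offset
#' (`amplitude/2` per component) that a truncated decaying exponential
#' otherwise leaves across the whole spectrum. Off by default; recommended
#' before baseline-sensitive quantification.
#'
#' @param ds a time-domain [mrs_dataset()].
#' @param first_point_half halve the first FID point before transforming
#'   (default `FALSE`).
#' @return the frequency-domain dataset.
#' @export
spectral_fft <- function(ds, first_point_half = FALSE) {
  require_spectral_domain(ds, "time", "spectral_fft")
  if (isTRUE(first_point_half))
    ds$data[, , , 1L, ] <- ds$data[, , , 1L, , drop = FALSE] * 0.5
  ds$data <- fftshift_axis(fft_axis(ds$data, 4L), 4L)
  ds$spectral_axis$domain <- "frequency"
  prov_append(ds, "spectral_fft", list(first_point_half = isTRUE(first_point_half)))
}

#' Inverse spectral Fourier transform (frequency to time)
#'
#' Exactly undoes [spectral_fft()]: ifftshift, then inverse FFT with 1/N.
#'
#' @param ds a frequency-domain [mrs_dataset()].
#' @return the time-domain dataset.
#' @export
spectral_ifft <- function(ds) {
  require_spectral_domain(ds, "frequency", "spectral_ifft")
  ds$data <- fft_axis(fftshift_axis(ds$data, 4L, inverse = TRUE), 4L,
                      inverse = TRUE, scale = TRUE)
  ds$spectral_axis$domain <- "time"
  prov_append(ds, "spectral_ifft", list())
}

#' Correct echo-planar per-k sampling delays
#'
#' Echo-planar spectroscopic readouts acquire successive k-space positions
#' along the readout axis at staggered times `k * tau`. In the spectral
#' frequency domain this is a k-dependent linear phase; the correction
#' multiplies the spectrum at k-index `k` (0-based) and bin offset frequency
#' `f` by `exp(-i 2 pi f k tau)`, compensating the acquisition shift.
#'
#' @param ds a spectral-frequency-domain [mrs_dataset()] still in k-space
#'   along the readout axis.
#' @param axis readout (EPSI) spatial axis, 1..3.
#' @param tau sampling delay per k-step, seconds. `tau = 0` is the identity.
#' @return the corrected dataset.
#' @export
epsi_phase_correct <- function(ds, axis, tau) {
  require_spectral_domain(ds, "frequency", "epsi_phase_correct")
  axis <- as.integer(axis)
  if (ds$spatial_domain[axis] != "kspace")
    stop("epsi_phase_correct requires k-space data on the readout axis")
  d <- dim(ds$data)
  params <- list(axis = axis, tau = tau)
  if (abs(tau) * ds$spectral_axis$sweep_width * (d[axis] - 1L) >= 1) {
    warning("EPSI delay reaches the wraparound regime (tau * SW * k_max >= 1)")
    params$wraparound_warning <- TRUE
  }
  if (tau != 0) {
    f <- bin_offset_hz(ds$spectral_axis)
    for (k in seq_len(d[axis])) {
      ramp <- exp(-1i * 2 * pi * f * (k - 1L) * tau)
      idx <- rep(list(quote(expr = )), 5L)
      idx[[axis]] <- k
      plane <- do.call(`[`, c(list(ds$data), idx, list(drop = FALSE)))
      pd <- dim(plane)
      # expand the ramp along the spectral axis (dim 4) of the plane
      ramp_full <- array(rep(ramp, each = prod(pd[1:3])), dim = pd)
      ds$data <- do.call(`[<-`, c(list(ds$data), idx,
                                  list(plane * ramp_full)))
    }
  }
  prov_append(ds, "epsi_phase_correct", params)
}

#' Sum-of-squares coil combination
#'
#' Combines channels pointwise as `sqrt(sum_c |v_c|^2)` in whatever domain
#' the data currently occupies. The output is stored as complex with zero
#' imaginary part and is invariant to arbitrary per-channel phase rotations;
#' phase information is lost, so phase-sensitive steps must run before
#' combination (recorded in provenance).
#'
#' @param ds an [mrs_dataset()] with any number of channels.
#' @return a single-channel dataset.
#' @export
combine_coils <- function(ds) {
  d <- dim(ds$data)
  m <- matrix(ds$data, ncol = d[5])
  sos <- sqrt(rowSums(Mod(m)^2))
  ds$data <- array(complex(real = sos), dim = c(d[1:4], 1L))
  ds$channel_count <- 1L
  prov_append(ds, "combine_coils",
              list(channels_in = d[5], note = "magnitude only; phase lost"))
}

#' Zero- and first-order phase correction
#'
#' Multiplies spectrum bin `i` (0-based) by
#' `exp(i * (phi0 + phi1 * (i - pivot)/N))`.
#'
#' @param ds a frequency-domain [mrs_dataset()].
#' @param p a [phase_params()].
#' @return the phased dataset.
#' @export
phase_correct <- function(ds, p) {
  require_spectral_domain(ds, "frequency", "phase_correct")
  n <- ds$spectral_axis$n_points
  if (p$pivot >= n) stop("pivot must be < n_points")
  ph <- exp(1i * (p$phi0 + p$phi1 * ((seq_len(n) - 1L) - p$pivot) / n))
  ds$data <- map_spectral(ds$data, function(m) m * ph)
  prov_append(ds, "phase_correct",
              list(phi0 = p$phi0, phi1 = p$phi1, pivot = p$pivot))
}

#' Automatic zero-order phasing
#'
#' Finds the zero-order phase maximizing the summed real part over a ppm
#' window (summed over all voxels and channels): a 1-degree grid search
#' followed by golden-section refinement to 0.01 degree. Scale-invariant; no
#' first-order term is fitted.
#'
#' @param ds a frequency-domain [mrs_dataset()].
#' @param window_ppm `c(lo, hi)` ppm window containing the peak(s) to phase.
#' @return a [phase_params()] with the fitted `phi0` (`phi1 = 0`).
#' @export
auto_phase0 <- function(ds, window_ppm) {
  require_spectral_domain(ds, "frequency", "auto_phase0")
  bins <- window_bins(ds$spectral_axis, window_ppm)
  if (length(bins) == 0L) stop("empty phasing window")
  s <- ds$data[, , , bins, , drop = FALSE]
  total <- sum(s)  # sum of real part of e^{i phi} * total is what we maximize
  score <- function(phi) Re(exp(1i * phi) * total)
  grid <- seq(-pi, pi, by = pi / 180)
  best <- grid[which.max(vapply(grid, score, 0))]
  lo <- best - pi / 180; hi <- best + pi / 180
  gr <- (sqrt(5) - 1) / 2
  tol <- 0.01 * pi / 180
  a <- lo; b <- hi
  x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
  f1 <- score(x1); f2 <- score(x2)
  while (b - a > tol) {
    if (f1 < f2) {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + gr * (b - a); f2 <- score(x2)
    } else {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - gr * (b - a); f1 <- score(x1)
    }
  }
  phi <- (a + b) / 2
  phase_params(phi0 = ((phi + pi) %% (2 * pi)) - pi, phi1 = 0, pivot = 0L)
}

# 1-based bin indices covered by a ppm window on a frequency-domain axis.
window_bins <- function(axis, window_ppm) {
  if (length(window_ppm) != 2L || window_ppm[1] >= window_ppm[2])
    stop("window must be c(lo, hi) ppm with lo < hi")
  span <- ppm_range(axis)
  if (window_ppm[2] < span[1] || window_ppm[1] > span[2])
    stop(sprintf("window [%g, %g] ppm outside axis range [%g, %g] ppm",
                 window_ppm[1], window_ppm[2], span[1], span[2]))
  i_hi <- ppm_to_index(axis, max(window_ppm[1], span[1]))
  i_lo <- ppm_to_index(axis, min(window_ppm[2], span[2]))
  seq.int(max(1L, ceiling(i_lo) + 1L), min(axis$n_points, floor(i_hi) + 1L))
}
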