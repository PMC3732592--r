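#' A single resonance in the phantom's forward model
#'
#' Each metabolite contributes one damped complex exponential to every voxel
#' FID. The damping is parameterized so that `damping` equals the Lorentzian
#' full width at half maximum (FWHM, Hz) of the resonance after Fourier
#' transform (time-domain decay `exp(-pi * damping * t)`), which keeps
#' apodization and quantification tests analytic.
#'
#' @param name metabolite name (e.g. `"naa"`, `"cho"`).
#' @param ppm chemical shift.
#' @param damping Lorentzian FWHM in Hz (> 0).
#' @param base_amplitude amplitude in arbitrary units before region scaling.
#' @param phase phase in radians.
#' @return an object of class `metabolite_spec`.
#' @export
metabolite_spec <- function(name, ppm, damping, base_amplitude = 1, phase = 0) {
  if (damping <= 0) stop("damping must be > 0")
  structure(list(name = name, ppm = ppm, damping = damping,
                 base_amplitude = base_amplitude, phase = phase),
            class = "metabolite_spec")
}

#' Default 1H metabolite set of the phantom
#'
#' Textbook chemical shifts for the singlets quantified in brain MRSI:
#' N-acetylaspartate 2.01 ppm, creatine 3.03 ppm, choline 3.22 ppm, and water
#' at the 4.7 ppm reference. Linewidths model a well-shimmed solution
#' phantom (2 Hz metabolite FWHM, 5 Hz water); the water amplitude models
#' the residual after water suppression (8x the NAA amplitude). Simulating
#' an unsuppressed acquisition just means raising the water amplitude
#' (in vivo, roughly 1000x).
#'
#' @return named list of [metabolite_spec()] objects.
#' @export
default_metabolites <- function() {
  list(
    naa   = metabolite_spec("naa",   2.01, damping = 2, base_amplitude = 1.0),
    cr    = metabolite_spec("cr",    3.03, damping = 2, base_amplitude = 0.6),
    cho   = metabolite_spec("cho",   3.22, damping = 2, base_amplitude = 1.0),
    water = metabolite_spec("water", 4.70, damping = 5, base_amplitude = 8.0)
  )
}

#' An ellipsoidal phantom region with per-metabolite scaling
#'
#' @param name region name.
#' @param center ellipsoid centre in (0-based, fractional) voxel coordinates.
#' @param semi_axes ellipsoid semi-axes in voxels.
#' @param scales named numeric: multiplier applied to each metabolite's base
#'   amplitude inside the region (metabolites absent from `scales` get 0).
#' @return an object of class `phantom_region`.
#' @export
phantom_region <- function(name, center, semi_axes, scales) {
  structure(list(name = name, center = as.numeric(center),
                 semi_axes = as.numeric(semi_axes), scales = scales),
            class = "phantom_region")
}

default_regions <- function() {
  list(
    phantom_region("normal", center = c(4.5, 7.5, 1.5),
                   semi_axes = c(2.4, 3.4, 1.4),
                   scales = c(naa = 1.0, cr = 1.0, cho = 0.5, water = 1.0)),
    phantom_region("tumor", center = c(10.5, 7.5, 1.5),
                   semi_axes = c(2.4, 3.4, 1.4),
                   scales = c(naa = 0.6, cr = 1.0, cho = 1.2, water = 1.0))
  )
}

#' Configuration of the synthetic MRSI phantom
#'
#' Defines the whole simulated acquisition: grid and spectral sampling,
#' metabolite content by ellipsoidal region, coil channels, noise, sample
#' ordering (cartesian or echo-planar with a per-k sampling delay), and the
#' random seed. Identical configurations and seeds yield byte-identical raw
#' files.
#'
#' @param dims spatial grid size, default `c(16, 16, 4)`.
#' @param n_points spectral samples per FID, default 512.
#' @param dwell dwell time in seconds (default 1 ms, i.e. 1000 Hz sweep width).
#' @param f0 transmitter frequency in MHz (default 127.7, 3 T 1H).
#' @param ppm_ref ppm at the carrier (default 4.7, water).
#' @param metabolites named list of [metabolite_spec()].
#' @param regions list of [phantom_region()].
#' @param channels number of receive channels (default 1; multi-channel adds
#'   smooth complex coil sensitivities).
#' @param channel_floor,channel_sigma_frac coil profile parameters: constant
#'   floor added to each Gaussian sensitivity, and Gaussian width as a
#'   fraction of the grid size.
#' @param noise_sigma standard deviation of the real and of the imaginary
#'   part of the complex Gaussian noise added to every k-space sample.
#' @param ordering `"cartesian"` or `"epsi"`.
#' @param epsi_axis readout axis (1..3) for epsi ordering.
#' @param epsi_tau sampling delay per k-step along the readout axis, seconds.
#' @param seed integer RNG seed driving the noise.
#' @param spacing,origin,orientation voxel geometry (mm, LPS).
#' @param selection a [selection_box()] (default covers the central voxels).
#' @param sat_bands list of [sat_band()] annotations.
#' @return an object of class `phantom_config`.
#' @export
phantom_config <- function(dims = c(16L, 16L, 4L), n_points = 512L,
                           dwell = 1e-3, f0 = 127.7, ppm_ref = 4.7,
                           metabolites = default_metabolites(),
                           regions = default_regions(),
                           channels = 1L, channel_floor = 0.3,
                           channel_sigma_frac = 0.5,
                           noise_sigma = 0,
                           ordering = c("cartesian", "epsi"),
                           epsi_axis = 1L, epsi_tau = 0,
                           seed = 1L,
                           spacing = c(10, 10, 10),
                           origin = NULL,
                           orientation = c(1, 0, 0, 0, 1, 0),
                           selection = NULL,
                           sat_bands = default_sat_bands()) {
  dims <- as.integer(dims)
  stopifnot(all(dims >= 1L), n_points >= 1L, noise_sigma >= 0, channels >= 1L)
  ordering <- match.arg(ordering)
  if (is.null(origin)) origin <- -spacing * (dims - 1) / 2
  if (is.null(selection)) {
    extent <- spacing * dims
    selection <- selection_box(center = origin + spacing * (dims - 1) / 2,
                               size = pmax(extent * 0.75, spacing))
  }
  structure(
    list(dims = dims, n_points = as.integer(n_points), dwell = dwell, f0 = f0,
         ppm_ref = ppm_ref, metabolites = metabolites, regions = regions,
         channels = as.integer(channels), channel_floor = channel_floor,
         channel_sigma_frac = channel_sigma_frac, noise_sigma = noise_sigma,
         ordering = ordering, epsi_axis = as.integer(epsi_axis),
         epsi_tau = epsi_tau, seed = as.integer(seed),
         spacing = as.numeric(spacing), origin = as.numeric(origin),
         orientation = as.numeric(orientation), selection = selection,
         sat_bands = sat_bands),
    class = "phantom_config"
  )
}

default_sat_bands <- function() {
  list(sat_band(c(1, 0, 0), distance = 85, thickness = 20),
       sat_band(c(0, 1, 0), distance = 85, thickness = 20))
}

phantom_geometry <- function(cfg) {
  mrs_geometry(origin = cfg$origin, spacing = cfg$spacing, dims = cfg$dims,
               orientation = cfg$orientation)
}

phantom_axis <- function(cfg, domain = "time") {
  spectral_axis(cfg$n_points, cfg$dwell, cfg$f0, cfg$ppm_ref, domain = domain)
}

#' Simulate one voxel's free induction decay
#'
#' Forward model: a sum of damped complex exponentials,
#' \deqn{x[n] = \sum_m a_m e^{i\phi_m} e^{(i 2\pi f_m - \pi d_m) n \Delta t}}
#' with offset frequency `f_m = (ppm_ref - ppm_m) * f0` (Hz from the carrier;
#' resonances upfield of the reference have positive offset under the
#' package's index convention) and `d_m` the Lorentzian FWHM in Hz.
#'
#' @param metabolites list of [metabolite_spec()]; amplitudes are taken as
#'   given (already region-scaled). An empty list yields a zero FID.
#' @param axis a time-domain [spectral_axis()].
#' @param amplitudes optional numeric vector overriding each spec's
#'   `base_amplitude`.
#' @return complex vector of length `axis$n_points`.
#' @export
simulate_voxel_fid <- function(metabolites, axis, amplitudes = NULL) {
  if (axis$domain != "time")
    stop("simulate_voxel_fid requires a time-domain axis")
  n <- axis$n_points
  x <- complex(n)
  if (length(metabolites) == 0L) return(x)
  t <- (seq_len(n) - 1L) * axis$dwell
  for (m in seq_along(metabolites)) {
    ms <- metabolites[[m]]
    a <- if (is.null(amplitudes)) ms$base_amplitude else amplitudes[m]
    if (a == 0) next
    f <- (axis$ppm_ref - ms$ppm) * axis$f0
    x <- x + a * exp(1i * ms$phase) *
      exp((1i * 2 * pi * f - pi * ms$damping) * t)
  }
  x
}

# Logical membership array (nx, ny, nz, n_regions): voxel centres inside
# each region's ellipsoid.
phantom_region_masks <- function(cfg) {
  d <- cfg$dims
  ii <- slice.index(array(0, d), 1) - 1L
  jj <- slice.index(array(0, d), 2) - 1L
  kk <- slice.index(array(0, d), 3) - 1L
  masks <- array(FALSE, dim = c(d, length(cfg$regions)))
  for (r in seq_along(cfg$regions)) {
    reg <- cfg$regions[[r]]
    masks[, , , r] <- ((ii - reg$center[1]) / reg$semi_axes[1])^2 +
      ((jj - reg$center[2]) / reg$semi_axes[2])^2 +
      ((kk - reg$center[3]) / reg$semi_axes[3])^2 <= 1
  }
  masks
}

# Per-voxel, per-metabolite amplitude array (nx, ny, nz, n_met): base
# amplitude times the sum of region scales of the regions containing the
# voxel centre (ellipsoid test in voxel coordinates).
phantom_amplitudes <- function(cfg) {
  d <- cfg$dims
  met_names <- names(cfg$metabolites)
  amp <- array(0, dim = c(d, length(met_names)))
  ii <- slice.index(array(0, d), 1) - 1L
  jj <- slice.index(array(0, d), 2) - 1L
  kk <- slice.index(array(0, d), 3) - 1L
  for (reg in cfg$regions) {
    inside <- ((ii - reg$center[1]) / reg$semi_axes[1])^2 +
      ((jj - reg$center[2]) / reg$semi_axes[2])^2 +
      ((kk - reg$center[3]) / reg$semi_axes[3])^2 <= 1
    for (m in seq_along(met_names)) {
      s <- reg$scales[met_names[m]]
      if (is.na(s)) s <- 0
      amp[, , , m] <- as.vector(amp[, , , m]) +
        as.vector(inside) * cfg$metabolites[[m]]$base_amplitude * s
    }
  }
  dimnames(amp) <- list(NULL, NULL, NULL, met_names)
  amp
}

# Complex coil sensitivity maps (nx, ny, nz, channels): positive smooth
# in-plane Gaussians plus a constant floor, one distinct global phase offset
# per channel (exercises phase invariance of sum-of-squares combination).
# A single channel gets unit sensitivity.
phantom_sensitivities <- function(cfg) {
  d <- cfg$dims; nc <- cfg$channels
  sens <- array(complex(real = 1), dim = c(d, nc))
  if (nc == 1L) return(sens)
  ii <- slice.index(array(0, d), 1) - 1L
  jj <- slice.index(array(0, d), 2) - 1L
  sigma <- cfg$channel_sigma_frac * max(d[1:2])
  r <- 0.35 * min(d[1:2])
  for (ch in seq_len(nc)) {
    ang <- 2 * pi * (ch - 1) / nc
    ci <- (d[1] - 1) / 2 + r * cos(ang)
    cj <- (d[2] - 1) / 2 + r * sin(ang)
    mag <- cfg$channel_floor + exp(-((ii - ci)^2 + (jj - cj)^2) / (2 * sigma^2))
    sens[, , , ch] <- mag * exp(1i * (ang + 0.37))
  }
  sens
}

# Voxel-domain 5-D array of noiseless FIDs (x, y, z, s, c).
phantom_voxel_data <- function(cfg) {
  d <- cfg$dims; n <- cfg$n_points
  axis <- phantom_axis(cfg)
  amp <- phantom_amplitudes(cfg)
  nm <- length(cfg$metabolites)
  t <- (seq_len(n) - 1L) * cfg$dwell
  basis <- matrix(0i, nrow = nm, ncol = n)
  for (m in seq_len(nm)) {
    ms <- cfg$metabolites[[m]]
    f <- (cfg$ppm_ref - ms$ppm) * cfg$f0
    basis[m, ] <- exp(1i * ms$phase) * exp((1i * 2 * pi * f - pi * ms$damping) * t)
  }
  fids <- matrix(amp, ncol = nm) %*% basis            # (nvox, n)
  sens <- phantom_sensitivities(cfg)
  data <- array(0i, dim = c(d, n, cfg$channels))
  for (ch in seq_len(cfg$channels)) {
    data[, , , , ch] <- array(as.vector(fids) *
                                rep(as.vector(sens[, , , ch]), times = n),
                              dim = c(d, n))
  }
  data
}

# Frequency-proportional phase ramp implementing a per-k sampling delay of
# k*tau seconds along one spatial axis (first-order echo-planar delay model;
# sign = +1 applies the delay, -1 compensates it). Operates on the 5-D array
# in the spectral time domain.
apply_epsi_delay <- function(data, axis_obj, spatial_axis, tau, sign = +1) {
  if (tau == 0) return(data)
  d <- dim(data)
  f <- bin_offset_hz(axis_obj)
  spec <- fftshift_axis(fft_axis(data, 4L), 4L)
  for (k in seq_len(d[spatial_axis])) {
    ramp <- exp(sign * 1i * 2 * pi * f * (k - 1L) * tau)
    idx <- rep(list(quote(expr = )), 5L)
    idx[[spatial_axis]] <- k
    plane <- do.call(`[`, c(list(spec), idx, list(drop = FALSE)))
    pd <- dim(plane)
    ramp_full <- array(rep(ramp, each = prod(pd[1:3])), dim = pd)
    spec <- do.call(`[<-`, c(list(spec), idx, list(plane * ramp_full)))
  }
  fft_axis(fftshift_axis(spec, 4L, inverse = TRUE), 4L,
           inverse = TRUE, scale = TRUE)
}

# Acquisition-order permutation of array dims for serialization: cartesian
# writes spectral fastest, then kx, ky, kz, channel slowest; epsi interleaves
# the readout axis inside the spectral loop (readout fastest, then spectral,
# then the remaining spatial axes, then channel).
acquisition_perm <- function(ordering, epsi_axis) {
  if (ordering == "cartesian") c(4L, 1L, 2L, 3L, 5L)
  else c(epsi_axis, 4L, setdiff(1:3, epsi_axis), 5L)
}

# Build the acquisition-order complex sample vector plus header for a config.
phantom_acquisition_samples <- function(cfg) {
  voxel <- phantom_voxel_data(cfg)
  axis <- phantom_axis(cfg)
  k <- voxel
  for (a in 1:3) k <- fftshift_axis(fft_axis(k, a), a)
  if (cfg$ordering == "epsi" && cfg$epsi_tau != 0)
    k <- apply_epsi_delay(k, axis, cfg$epsi_axis, cfg$epsi_tau, sign = +1)
  if (cfg$noise_sigma > 0) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
    set.seed(cfg$seed)
    nt <- length(k)
    k <- k + complex(real = stats::rnorm(nt, 0, cfg$noise_sigma),
                     imaginary = stats::rnorm(nt, 0, cfg$noise_sigma))
  }
  as.vector(aperm(k, acquisition_perm(cfg$ordering, cfg$epsi_axis)))
}

phantom_header <- function(cfg) {
  list(
    format = "MRSRAW1",
    dims = cfg$dims, n_points = cfg$n_points, channels = cfg$channels,
    dwell = cfg$dwell, f0 = cfg$f0, ppm_ref = cfg$ppm_ref,
    geometry = list(origin = cfg$origin, spacing = cfg$spacing,
                    orientation = cfg$orientation),
    selection = if (is.null(cfg$selection)) NULL else
      list(center = cfg$selection$center, size = cfg$selection$size),
    sat_bands = lapply(cfg$sat_bands, function(sb)
      list(normal = sb$normal, distance = sb$distance,
           thickness = sb$thickness)),
    ordering = list(type = cfg$ordering, readout_axis = cfg$epsi_axis,
                    epsi_tau = cfg$epsi_tau)
  )
}

#' Generate a raw phantom acquisition with ground-truth sidecar
#'
#' Builds voxel FIDs from the region-scaled metabolite model, applies coil
#' sensitivities, forward-DFTs each spectral sample to k-space, optionally
#' applies echo-planar per-k sampling delays and reorders samples, adds
#' seeded complex Gaussian noise, and writes the result in the documented
#' MRSRAW1 container together with a JSON ground-truth sidecar (per-voxel
#' metabolite amplitudes, coil sensitivities, region amplitude ratios, and
#' the full configuration echo). Output is deterministic: identical `cfg`
#' (including seed) gives byte-identical files.
#'
#' @param cfg a [phantom_config()].
#' @param path output path for the raw file.
#' @param truth_path output path for the sidecar (default `<path>.truth.json`).
#' @return invisibly, a list with `path`, `truth_path`, and the ground truth
#'   list.
#' @export
generate_phantom <- function(cfg, path,
                             truth_path = paste0(path, ".truth.json")) {
  samples <- phantom_acquisition_samples(cfg)
  header <- phantom_header(cfg)
  write_mrsraw(samples, header, path)

  amp <- phantom_amplitudes(cfg)
  sens <- phantom_sensitivities(cfg)
  met_names <- names(cfg$metabolites)
  ratios <- vapply(cfg$regions, function(reg) {
    ch <- cfg$metabolites$cho$base_amplitude * unname(reg$scales["cho"])
    na <- cfg$metabolites$naa$base_amplitude * unname(reg$scales["naa"])
    if (is.na(ch) || is.na(na) || na == 0) NA_real_ else ch / na
  }, numeric(1))
  masks <- phantom_region_masks(cfg)
  truth <- list(
    metabolites = met_names,
    amplitude_dims = dim(amp), amplitudes = as.vector(amp),
    region_mask_dims = dim(masks), region_masks = as.vector(masks),
    sensitivity_dims = dim(sens),
    sensitivity_re = as.vector(Re(sens)), sensitivity_im = as.vector(Im(sens)),
    region_names = vapply(cfg$regions, `[[`, "", "name"),
    region_cho_naa_ratio = ratios,
    config = c(phantom_header(cfg),
               list(noise_sigma = cfg$noise_sigma, seed = cfg$seed))
  )
  writeLines(jsonlite::toJSON(truth, auto_unbox = TRUE, digits = NA,
                              null = "null"), truth_path)
  invisible(list(path = path, truth_path = truth_path, truth = truth))
}

#' Read a phantom ground-truth sidecar
#'
#' @param truth_path path written by [generate_phantom()].
#' @return list with the per-voxel amplitude array (`amplitudes`, dims
#'   `(x, y, z, metabolite)`), complex `sensitivities`, region ratios, and
#'   the configuration echo.
#' @export
read_phantom_truth <- function(truth_path) {
  tr <- jsonlite::fromJSON(truth_path, simplifyVector = TRUE)
  amp <- array(tr$amplitudes, dim = tr$amplitude_dims)
  dimnames(amp) <- list(NULL, NULL, NULL, tr$metabolites)
  sens <- array(complex(real = tr$sensitivity_re, imaginary = tr$sensitivity_im),
                dim = tr$sensitivity_dims)
  masks <- array(tr$region_masks, dim = tr$region_mask_dims)
  list(metabolites = tr$metabolites, amplitudes = amp, sensitivities = sens,
       region_masks = masks, region_names = tr$region_names,
       region_cho_naa_ratio = tr$region_cho_naa_ratio, config = tr$config)
}

#' Generate a matched synthetic anatomical DICOM series
#'
#' Writes a standard single-frame-per-slice DICOM MR Image Storage series
#' whose volume covers the phantom grid exactly. Pixel content is a smooth
#' synthetic head-like ellipsoid with brighter blobs at the phantom regions,
#' sufficient for spatial referencing and report underlays.
#'
#' @param cfg a [phantom_config()].
#' @param dir output directory (created if missing).
#' @param upsample in-plane upsampling factor relative to the spectroscopic
#'   grid (default 8); slice count is `4 * cfg$dims[3]`.
#' @return invisibly, character vector of file paths (one per slice).
#' @export
generate_anatomical <- function(cfg, dir, upsample = 8L) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  d <- cfg$dims
  ad <- c(d[1] * upsample, d[2] * upsample, d[3] * 4L)
  aspacing <- cfg$spacing * d / ad
  corner <- cfg$origin - cfg$spacing / 2
  aorigin <- corner + aspacing / 2
  ii <- (slice.index(array(0, ad), 1) - 1) / upsample - 0.5
  jj <- (slice.index(array(0, ad), 2) - 1) / upsample - 0.5
  kk <- (slice.index(array(0, ad), 3) - 1) / 4 - 0.5
  cx <- (d[1] - 1) / 2; cy <- (d[2] - 1) / 2; cz <- (d[3] - 1) / 2
  head_r <- ((ii - cx) / (0.48 * d[1]))^2 + ((jj - cy) / (0.48 * d[2]))^2 +
    ((kk - cz) / (0.55 * d[3]))^2
  img <- 700 * exp(-head_r^2) * (head_r <= 1)
  for (reg in cfg$regions) {
    rr <- ((ii - reg$center[1]) / reg$semi_axes[1])^2 +
      ((jj - reg$center[2]) / reg$semi_axes[2])^2 +
      ((kk - reg$center[3]) / reg$semi_axes[3])^2
    img <- img + 250 * exp(-rr)
  }
  geom <- mrs_geometry(origin = aorigin, spacing = aspacing, dims = ad,
                       orientation = cfg$orientation)
  write_dicom_mri_series(round(img), geom, dir, seed_label = "anat")
}
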