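#' Registered pipeline stage names
#'
#' Stage registry for config-driven reconstruction: each name maps to one
#' package operation with the listed parameters.
#'
#' @return character vector of valid stage names.
#' @export
pipeline_stages <- function() {
  c("apodize", "zero_fill", "epsi_correct", "spatial_recon", "spectral_fft",
    "hsvd_filter", "combine", "phase")
}

stage_param_names <- list(
  apodize = c("broadening", "shape"),
  zero_fill = c("target_points", "factor"),
  epsi_correct = c("axis", "tau"),
  spatial_recon = character(),
  spectral_fft = "first_point_half",
  hsvd_filter = c("band_ppm", "order"),
  combine = character(),
  phase = c("phi0", "phi1", "pivot", "auto", "window")
)

# EPSI parameters recorded by the mapper, if any.
epsi_prov_params <- function(ds) {
  for (rec in ds$provenance)
    if (rec$op == "map_acquisition" &&
        identical(rec$params$ordering, "epsi"))
      return(list(axis = rec$params$readout_axis, tau = rec$params$epsi_tau))
  NULL
}

apply_stage <- function(ds, stage) {
  name <- stage$name
  if (is.null(name) || !name %in% pipeline_stages())
    stop("unknown pipeline stage: ", if (is.null(name)) "<missing name>" else name,
         " (registered: ", paste(pipeline_stages(), collapse = ", "), ")")
  extra <- setdiff(names(stage), c("name", stage_param_names[[name]]))
  if (length(extra))
    stop("unknown parameter(s) for stage '", name, "': ",
         paste(extra, collapse = ", "))
  switch(name,
    apodize = apodize(ds, broadening = stage$broadening %||% 0,
                      shape = stage$shape %||% "lorentzian"),
    zero_fill = {
      tp <- stage$target_points %||%
        (dim(ds$data)[4] * (stage$factor %||% 2))
      zero_fill(ds, tp)
    },
    epsi_correct = {
      p <- epsi_prov_params(ds)
      ax <- stage$axis %||% (if (!is.null(p)) p$axis else 1L)
      tau <- stage$tau %||% (if (!is.null(p)) p$tau else 0)
      was_time <- ds$spectral_axis$domain == "time"
      if (was_time) ds <- spectral_fft(ds)
      ds <- epsi_phase_correct(ds, ax, tau)
      if (was_time) ds <- spectral_ifft(ds)
      ds
    },
    spatial_recon = spatial_recon(ds),
    spectral_fft = spectral_fft(ds, isTRUE(stage$first_point_half)),
    hsvd_filter = hsvd_filter(ds, stage$band_ppm %||% c(4.2, 5.2),
                              hsvd_options(order = stage$order %||% 25L)),
    combine = combine_coils(ds),
    phase = {
      if (isTRUE(stage$auto)) {
        p <- auto_phase0(ds, unlist(stage$window %||% c(1.8, 3.5)))
        phase_correct(ds, p)
      } else {
        phase_correct(ds, phase_params(stage$phi0 %||% 0, stage$phi1 %||% 0,
                                       stage$pivot %||% 0L))
      }
    })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a configured reconstruction pipeline
#'
#' Applies an ordered list of registered stages (see [pipeline_stages()]) to
#' a dataset. Stage names or parameters outside the registry are rejected.
#'
#' @param ds an [mrs_dataset()].
#' @param stages list of stage descriptors, each a named list with `name` and
#'   stage parameters, e.g. `list(list(name = "apodize", broadening = 4))`.
#' @return the processed dataset.
#' @export
run_pipeline <- function(ds, stages) {
  for (stage in stages) ds <- apply_stage(ds, stage)
  ds
}

#' Quantify standard metabolite maps from a reconstructed dataset
#'
#' Computes peak-height and integrated-area maps for each window, a noise
#' map, and the masked choline/NAA ratio map.
#'
#' @param ds a frequency-domain single-channel [mrs_dataset()].
#' @param windows named list of [peak_window()]s (default [default_windows()]).
#' @param noise_region signal-free ppm interval for [estimate_noise()].
#' @param k_mask denominator threshold for [ratio_map()].
#' @return named list of [metabolite_map()]s (`<name>_height`,
#'   `<name>_area`, `noise_sigma`, `cho_naa_index` when cho and naa windows
#'   are present).
#' @export
quantify_maps <- function(ds, windows = default_windows(),
                          noise_region = c(6.5, 8.0), k_mask = 4) {
  maps <- list()
  for (w in windows) {
    maps[[paste0(w$name, "_height")]] <- peak_height_map(ds, w)
    maps[[paste0(w$name, "_area")]] <- peak_area_map(ds, w)
  }
  noise <- estimate_noise(ds, noise_region, windows)
  maps$noise_sigma <- noise
  if (!is.null(maps$cho_height) && !is.null(maps$naa_height))
    maps$cho_naa_index <- ratio_map(maps$cho_height, maps$naa_height,
                                    noise, k_mask)
  maps
}

# SHA1 digests of files, for run manifests.
file_digests <- function(paths) {
  vapply(paths, function(p) digest::digest(file = p, algo = "sha1"), "")
}
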