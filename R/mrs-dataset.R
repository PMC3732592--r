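#' The regular-grid spectroscopic dataset
#'
#' The central container every pipeline stage consumes and returns: a complex
#' 5-D array indexed `(x, y, z, spectral, channel)` plus the spectral axis,
#' voxel geometry, per-spatial-axis domain flags, optional selection box and
#' sat bands, and an ordered provenance trail. Every pipeline operation
#' returns a modified copy (never mutates its input) and appends exactly one
#' provenance record.
#'
#' @param data complex array; dimensions `(x, y, z, s, c)`. Lower-dimensional
#'   arrays are promoted by appending unit axes.
#' @param spectral_axis a [spectral_axis()].
#' @param geometry an [mrs_geometry()]; defaults to a unit grid matching the
#'   spatial dims.
#' @param spatial_domain character of length 3, each `"kspace"` or `"image"`.
#' @param selection optional [selection_box()].
#' @param sat_bands list of [sat_band()] objects.
#' @param provenance list of prior processing records (normally empty).
#' @return an object of class `mrs_dataset`.
#' @export
mrs_dataset <- function(data, spectral_axis, geometry = NULL,
                        spatial_domain = c("image", "image", "image"),
                        selection = NULL, sat_bands = list(),
                        provenance = list()) {
  d <- dim(data)
  if (is.null(d)) d <- length(data)
  if (length(d) < 5L) d <- c(d, rep(1L, 5L - length(d)))
  if (length(d) != 5L) stop("data must have at most 5 dimensions (x, y, z, s, c)")
  data <- array(as.complex(data), dim = d)
  if (is.null(geometry)) geometry <- mrs_geometry(dims = d[1:3])
  spatial_domain <- match.arg(spatial_domain, c("kspace", "image"),
                              several.ok = TRUE)
  if (length(spatial_domain) == 1L) spatial_domain <- rep(spatial_domain, 3L)
  ds <- structure(
    list(data = data, spectral_axis = spectral_axis, geometry = geometry,
         spatial_domain = spatial_domain, channel_count = d[5],
         selection = selection, sat_bands = sat_bands,
         provenance = provenance),
    class = "mrs_dataset"
  )
  ds
}

#' @export
print.mrs_dataset <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<mrs_dataset> %dx%dx%d voxels, %d spectral pts (%s domain), %d channel(s)\n",
              d[1], d[2], d[3], d[4], x$spectral_axis$domain, d[5]))
  cat(sprintf("  spatial domain: %s | provenance: %d step(s)\n",
              paste(x$spatial_domain, collapse = "/"), length(x$provenance)))
  invisible(x)
}

#' Append a provenance record to a dataset
#'
#' Each record is a plain list with the operation name and its parameters
#' (plain key/value pairs), so that processing history is inspectable and
#' serializable.
#'
#' @param ds an [mrs_dataset()].
#' @param op operation name.
#' @param params named list of parameters.
#' @return the dataset with one record appended.
#' @export
prov_append <- function(ds, op, params = list()) {
  ds$provenance <- c(ds$provenance, list(list(op = op, params = params)))
  ds
}

#' Validate a dataset against the model invariants
#'
#' Pure check: violations are returned as data, not raised. An empty
#' character vector means the dataset satisfies every invariant of the data
#' model (shape consistency, axis consistency, geometry validity).
#'
#' @param ds an [mrs_dataset()].
#' @return character vector of human-readable violations; empty when valid.
#' @export
validate_mrs <- function(ds) {
  v <- character()
  d <- dim(ds$data)
  if (length(d) != 5L) {
    v <- c(v, "shape: data must be a 5-D array (x, y, z, s, c)")
    return(v)
  }
  if (!all(d[1:3] == ds$geometry$dims))
    v <- c(v, sprintf("shape: data spatial dims (%s) do not match geometry$dims (%s)",
                      paste(d[1:3], collapse = "x"),
                      paste(ds$geometry$dims, collapse = "x")))
  if (d[4] != ds$spectral_axis$n_points)
    v <- c(v, sprintf("shape: spectral dim %d does not match axis n_points %d",
                      d[4], ds$spectral_axis$n_points))
  if (d[5] != ds$channel_count)
    v <- c(v, sprintf("shape: channel dim %d does not match channel_count %d",
                      d[5], ds$channel_count))
  ax <- ds$spectral_axis
  if (abs(ax$sweep_width * ax$dwell - 1) > 1e-9)
    v <- c(v, "axis: sweep_width * dwell must equal 1 (tol 1e-9)")
  if (!ax$domain %in% c("time", "frequency"))
    v <- c(v, "axis: domain must be 'time' or 'frequency'")
  if (!all(ds$spatial_domain %in% c("kspace", "image")))
    v <- c(v, "spatial_domain: entries must be 'kspace' or 'image'")
  v <- c(v, geometry_violations(ds$geometry))
  if (!is.null(ds$selection) && any(ds$selection$size <= 0))
    v <- c(v, "selection: size components must be > 0")
  for (sb in ds$sat_bands) {
    if (abs(sqrt(sum(sb$normal^2)) - 1) > 1e-6)
      v <- c(v, "sat_band: normal must be unit length")
    if (sb$thickness <= 0) v <- c(v, "sat_band: thickness must be > 0")
  }
  v
}

require_spectral_domain <- function(ds, domain, op) {
  if (ds$spectral_axis$domain != domain)
    stop(op, " requires ", domain, "-domain spectral data (found ",
         ds$spectral_axis$domain, ")")
  invisible(TRUE)
}

#' A 3-D metabolite map tied to a dataset's geometry
#'
#' Real-valued per-voxel quantity (peak height, integrated area, ratio, noise
#' estimate) sharing the source dataset's spatial geometry, so the map can be
#' exported as a standard 3-D image and overlaid on anatomy.
#'
#' @param values real 3-D array.
#' @param geometry the source dataset's [mrs_geometry()].
#' @param label map label, e.g. `"cho_height"`.
#' @param mask logical 3-D array of reliable voxels; defaults to all `TRUE`.
#' @return an object of class `metabolite_map`.
#' @export
metabolite_map <- function(values, geometry, label,
                           mask = array(TRUE, dim = dim(values))) {
  values <- array(as.numeric(values), dim = dim(values))
  if (!all(dim(values) == geometry$dims))
    stop("values shape must equal geometry$dims")
  if (!all(dim(mask) == geometry$dims))
    stop("mask shape must equal geometry$dims")
  structure(list(values = values, geometry = geometry, label = label,
                 mask = array(as.logical(mask), dim = dim(mask))),
            class = "metabolite_map")
}

#' @export
print.metabolite_map <- function(x, ...) {
  cat(sprintf("<metabolite_map> '%s' %s, %d/%d voxels unmasked\n", x$label,
              paste(dim(x$values), collapse = "x"), sum(x$mask),
              length(x$mask)))
  invisible(x)
}
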