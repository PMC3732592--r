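#' Regular-grid voxel geometry in patient (LPS) coordinates
#'
#' Describes where a voxel grid sits in space, DICOM-style: the position of
#' the centre of voxel (0,0,0), the voxel spacing, and six direction cosines
#' (row and column unit vectors). The slice direction is their cross product.
#' All processing in this package assumes axis-aligned sampling; oblique
#' orientations are stored and round-tripped but not resampled.
#'
#' @param origin length-3 numeric, mm, LPS position of the centre of voxel
#'   (0,0,0).
#' @param spacing length-3 numeric, mm per voxel along each axis (> 0).
#' @param dims length-3 positive integers, grid size.
#' @param orientation length-6 numeric: row then column direction cosines.
#' @return an object of class `mrs_geometry`.
#' @export
mrs_geometry <- function(origin = c(0, 0, 0), spacing = c(10, 10, 10),
                         dims = c(1L, 1L, 1L),
                         orientation = c(1, 0, 0, 0, 1, 0)) {
  dims <- as.integer(dims)
  stopifnot(length(origin) == 3L, length(spacing) == 3L,
            length(dims) == 3L, length(orientation) == 6L)
  structure(list(origin = as.numeric(origin), spacing = as.numeric(spacing),
                 dims = dims, orientation = as.numeric(orientation)),
            class = "mrs_geometry")
}

geometry_violations <- function(g) {
  v <- character()
  if (any(g$spacing <= 0)) v <- c(v, "spacing: all components must be > 0")
  if (any(g$dims < 1L)) v <- c(v, "dims: all components must be >= 1")
  r <- g$orientation[1:3]; c_ <- g$orientation[4:6]
  if (abs(sqrt(sum(r^2)) - 1) > 1e-6 || abs(sqrt(sum(c_^2)) - 1) > 1e-6)
    v <- c(v, "orientation: direction cosines must be unit length (tol 1e-6)")
  else if (abs(sum(r * c_)) > 1e-6)
    v <- c(v, "orientation: row/column direction cosines must be orthogonal (tol 1e-6)")
  v
}

#' Slice (through-plane) direction cosines of a geometry
#' @param g an [mrs_geometry()].
#' @return unit length-3 numeric vector (row x column).
#' @export
slice_direction <- function(g) {
  r <- g$orientation[1:3]; c_ <- g$orientation[4:6]
  c(r[2] * c_[3] - r[3] * c_[2],
    r[3] * c_[1] - r[1] * c_[3],
    r[1] * c_[2] - r[2] * c_[1])
}

#' Patient-space position of a voxel centre
#' @param g an [mrs_geometry()].
#' @param i,j,k 0-based voxel indices along the three axes.
#' @return length-3 numeric, mm LPS.
#' @export
voxel_center <- function(g, i, j, k) {
  r <- g$orientation[1:3]; c_ <- g$orientation[4:6]; s <- slice_direction(g)
  g$origin + i * g$spacing[1] * r + j * g$spacing[2] * c_ + k * g$spacing[3] * s
}

#' PRESS-style selection box
#'
#' The rectangular excitation volume of the acquisition; spectra outside it
#' are unreliable and are typically masked.
#'
#' @param center length-3 numeric, mm LPS.
#' @param size length-3 numeric, mm along the three axes (> 0).
#' @return an object of class `selection_box`.
#' @export
selection_box <- function(center, size) {
  stopifnot(length(center) == 3L, length(size) == 3L)
  if (any(size <= 0)) stop("selection box size components must be > 0")
  structure(list(center = as.numeric(center), size = as.numeric(size)),
            class = "selection_box")
}

#' Spatial saturation band
#'
#' A plane-plus-thickness slab in which signal is suppressed (e.g. scalp
#' lipid). Stored for annotation and DICOM export; not applied to data.
#'
#' @param normal length-3 unit vector.
#' @param distance mm from the patient origin along `normal` to the slab
#'   centre plane.
#' @param thickness slab thickness in mm (> 0).
#' @return an object of class `sat_band`.
#' @export
sat_band <- function(normal, distance, thickness) {
  stopifnot(length(normal) == 3L)
  if (abs(sqrt(sum(normal^2)) - 1) > 1e-6) stop("sat band normal must be unit length")
  if (thickness <= 0) stop("sat band thickness must be > 0")
  structure(list(normal = as.numeric(normal), distance = as.numeric(distance),
                 thickness = as.numeric(thickness)),
            class = "sat_band")
}

#' Logical mask of voxels whose centres lie inside the selection box
#'
#' @param geometry an [mrs_geometry()].
#' @param selection a [selection_box()] or `NULL`.
#' @return logical 3-D array of `geometry$dims`; all-`TRUE` when `selection`
#'   is `NULL`.
#' @export
selection_mask <- function(geometry, selection) {
  d <- geometry$dims
  if (is.null(selection)) return(array(TRUE, dim = d))
  m <- array(FALSE, dim = d)
  lo <- selection$center - selection$size / 2
  hi <- selection$center + selection$size / 2
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    p <- voxel_center(geometry, i - 1L, j - 1L, k - 1L)
    m[i, j, k] <- all(p >= lo - 1e-9) && all(p <= hi + 1e-9)
  }
  m
}
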