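# Deterministic pure-R rasterization for secondary-capture reports: all
# drawing is plain integer arithmetic on an (h, w, 3) 8-bit RGB array, so
# identical inputs give byte-identical rasters (no graphics device, no fonts).

raster_new <- function(size = 1024L, bg = c(0L, 0L, 0L)) {
  r <- array(0L, dim = c(size, size, 3L))
  for (ch in 1:3) r[, , ch] <- bg[ch]
  r
}

raster_blend_rect <- function(img, r0, r1, c0, c1, color, alpha = 1) {
  h <- dim(img)[1]; w <- dim(img)[2]
  r0 <- max(1L, r0); r1 <- min(h, r1); c0 <- max(1L, c0); c1 <- min(w, c1)
  if (r0 > r1 || c0 > c1) return(img)
  for (ch in 1:3) {
    img[r0:r1, c0:c1, ch] <-
      as.integer(round((1 - alpha) * img[r0:r1, c0:c1, ch] + alpha * color[ch]))
  }
  img
}

raster_line <- function(img, r0, c0, r1, c1, color) {
  h <- dim(img)[1]; w <- dim(img)[2]
  n <- max(abs(r1 - r0), abs(c1 - c0)) + 1L
  rr <- as.integer(round(seq(r0, r1, length.out = n)))
  cc <- as.integer(round(seq(c0, c1, length.out = n)))
  ok <- rr >= 1L & rr <= h & cc >= 1L & cc <= w
  for (ch in 1:3) img[cbind(rr[ok], cc[ok], ch)] <- color[ch]
  img
}

heat_color <- function(v) {
  # v in [0,1] -> black-red-yellow-white heat ramp
  v <- pmin(pmax(v, 0), 1)
  r <- pmin(1, 3 * v)
  g <- pmin(1, pmax(0, 3 * v - 1))
  b <- pmin(1, pmax(0, 3 * v - 2))
  cbind(r, g, b) * 255
}

#' Layout of a secondary-capture report
#'
#' @param slices spectroscopic slice indices (1-based) to render.
#' @param grid_window optional voxel sub-rectangle `c(i0, i1, j0, j1)`
#'   (1-based, inclusive) in which per-voxel spectra are plotted; default is
#'   the full grid.
#' @param overlay optional [metabolite_map()] rendered as a semi-transparent
#'   heat colormap.
#' @param overlay_range color scale bounds `c(lo, hi)`; default is the
#'   overlay's finite range.
#' @param show_selection draw the selection box outline in yellow.
#' @param show_sat_bands shade sat bands in purple.
#' @param size raster size in pixels (square, default 1024).
#' @return an object of class `report_layout`.
#' @export
report_layout <- function(slices, grid_window = NULL, overlay = NULL,
                          overlay_range = NULL, show_selection = TRUE,
                          show_sat_bands = TRUE, size = 1024L) {
  structure(list(slices = as.integer(slices), grid_window = grid_window,
                 overlay = overlay, overlay_range = overlay_range,
                 show_selection = show_selection,
                 show_sat_bands = show_sat_bands, size = as.integer(size)),
            class = "report_layout")
}

# Patient-coordinate extent (corner-to-corner) of an axis-aligned geometry.
grid_extent <- function(g) {
  lo <- g$origin - g$spacing / 2
  hi <- g$origin + g$spacing * (g$dims - 0.5)
  rbind(lo, hi)
}

#' Render one report panel
#'
#' Draws, bottom to top: the anatomical slice nearest the requested
#' spectroscopic slice as a grayscale underlay; the optional metabolite-map
#' heat overlay (semi-transparent, only in unmasked voxels); the voxel grid;
#' one spectrum polyline (real part) per voxel of the grid window; the
#' selection box outline in pure yellow; sat bands as purple shading.
#' Rendering is pure integer arithmetic: identical inputs give byte-identical
#' rasters.
#'
#' @param ds a reconstructed frequency-domain single-channel [mrs_dataset()].
#' @param anatomical list with `values` (3-D array) and `geometry`, e.g. from
#'   [read_dicom_mri_series()], or `NULL` for a black background.
#' @param layout a [report_layout()].
#' @param slice 1-based spectroscopic slice index.
#' @return integer RGB raster `(size, size, 3)`, values 0..255.
#' @export
render_slice_panel <- function(ds, anatomical, layout, slice) {
  d <- dim(ds$data)
  if (slice < 1L || slice > d[3])
    stop("slice ", slice, " outside volume (1..", d[3], ")")
  size <- layout$size
  img <- raster_new(size)
  g <- ds$geometry
  ext <- grid_extent(g)
  px_x <- function(x) (x - ext[1, 1]) / (ext[2, 1] - ext[1, 1]) * size
  px_y <- function(y) (y - ext[1, 2]) / (ext[2, 2] - ext[1, 2]) * size
  z_slice <- voxel_center(g, 0L, 0L, slice - 1L)[3]

  # anatomical underlay (nearest-neighbour resample)
  if (!is.null(anatomical)) {
    ag <- anatomical$geometry
    az <- round((z_slice - ag$origin[3]) / ag$spacing[3]) + 1L
    az <- min(max(az, 1L), ag$dims[3])
    sl <- anatomical$values[, , az]
    vmax <- max(sl); if (vmax <= 0) vmax <- 1
    rows <- seq_len(size); cols <- seq_len(size)
    pys <- ext[1, 2] + (rows - 0.5) / size * (ext[2, 2] - ext[1, 2])
    pxs <- ext[1, 1] + (cols - 0.5) / size * (ext[2, 1] - ext[1, 1])
    ai <- pmin(pmax(round((pxs - ag$origin[1]) / ag$spacing[1]) + 1L, 1L),
               ag$dims[1])
    aj <- pmin(pmax(round((pys - ag$origin[2]) / ag$spacing[2]) + 1L, 1L),
               ag$dims[2])
    # raster rows follow patient y, columns patient x
    under <- array(as.integer(round(pmin(outer(aj, ai, function(j, i)
      sl[cbind(i, j)]) / vmax, 1) * 255)), dim = c(size, size))
    for (ch in 1:3) img[, , ch] <- under
  }

  # metabolite-map heat overlay, semi-transparent inside unmasked voxels
  if (!is.null(layout$overlay)) {
    ov <- layout$overlay
    rng <- layout$overlay_range
    if (is.null(rng)) {
      fin <- ov$values[ov$mask & is.finite(ov$values)]
      rng <- if (length(fin)) range(fin) else c(0, 1)
    }
    span <- if (rng[2] > rng[1]) rng[2] - rng[1] else 1
    for (j in seq_len(g$dims[2])) for (i in seq_len(g$dims[1])) {
      if (!ov$mask[i, j, slice] || !is.finite(ov$values[i, j, slice])) next
      col <- heat_color((ov$values[i, j, slice] - rng[1]) / span)[1, ]
      r0 <- as.integer(floor(px_y((ext[1, 2] + (j - 1) * g$spacing[2])))) + 1L
      r1 <- as.integer(ceiling(px_y(ext[1, 2] + j * g$spacing[2])))
      c0 <- as.integer(floor(px_x(ext[1, 1] + (i - 1) * g$spacing[1]))) + 1L
      c1 <- as.integer(ceiling(px_x(ext[1, 1] + i * g$spacing[1])))
      img <- raster_blend_rect(img, r0, r1, c0, c1, col, alpha = 0.45)
    }
  }

  # voxel grid lines
  grid_col <- c(90L, 90L, 90L)
  for (i in 0:g$dims[1]) {
    c_ <- min(max(as.integer(round(px_x(ext[1, 1] + i * g$spacing[1]))), 1L), size)
    img <- raster_line(img, 1L, c_, size, c_, grid_col)
  }
  for (j in 0:g$dims[2]) {
    r_ <- min(max(as.integer(round(px_y(ext[1, 2] + j * g$spacing[2]))), 1L), size)
    img <- raster_line(img, r_, 1L, r_, size, grid_col)
  }

  # per-voxel spectra (real part), white polylines. For speed, each
  # polyline is rasterized column-by-column (two samples per pixel column,
  # vertical span filled), and all voxels are written in one assignment.
  gw <- layout$grid_window
  if (is.null(gw)) gw <- c(1L, g$dims[1], 1L, g$dims[2])
  sub <- Re(ds$data[gw[1]:gw[2], gw[3]:gw[4], slice, , 1, drop = FALSE])
  smax <- max(abs(sub)); if (smax == 0) smax <- 1
  n <- d[4]
  rows_acc <- vector("list", (gw[2] - gw[1] + 1L) * (gw[4] - gw[3] + 1L))
  cols_acc <- rows_acc
  cell <- 0L
  for (j in gw[3]:gw[4]) for (i in gw[1]:gw[2]) {
    cell <- cell + 1L
    spec <- Re(ds$data[i, j, slice, , 1])
    c0 <- px_x(ext[1, 1] + (i - 1) * g$spacing[1])
    c1 <- px_x(ext[1, 1] + i * g$spacing[1])
    r0 <- px_y(ext[1, 2] + (j - 1) * g$spacing[2])
    r1 <- px_y(ext[1, 2] + j * g$spacing[2])
    cell_h <- r1 - r0
    ncol_px <- max(2L, as.integer(floor(c1)) - as.integer(ceiling(c0)))
    at <- seq(0.5 / ncol_px, 1 - 0.5 / ncol_px, length.out = ncol_px)
    sp <- stats::approx(seq(0, 1, length.out = n), spec, xout = at)$y
    ys <- r1 - (sp / smax * 0.45 + 0.5) * cell_h
    ys <- as.integer(round(pmin(pmax(ys, r0 + 1), r1)))
    xs <- as.integer(round(c0 + at * (c1 - c0)))
    y_from <- pmin(ys[-length(ys)], ys[-1])
    y_to <- pmax(ys[-length(ys)], ys[-1])
    lens <- y_to - y_from + 1L
    rows_acc[[cell]] <- sequence(lens, from = y_from)
    cols_acc[[cell]] <- rep(xs[-1], lens)
  }
  rr <- unlist(rows_acc); cc <- unlist(cols_acc)
  ok <- rr >= 1L & rr <= size & cc >= 1L & cc <= size
  for (ch in 1:3) img[cbind(rr[ok], cc[ok], ch)] <- 255L

  # selection box outline (pure yellow)
  if (isTRUE(layout$show_selection) && !is.null(ds$selection)) {
    sel <- ds$selection
    if (abs(z_slice - sel$center[3]) <= sel$size[3] / 2) {
      c0 <- as.integer(round(px_x(sel$center[1] - sel$size[1] / 2)))
      c1 <- as.integer(round(px_x(sel$center[1] + sel$size[1] / 2)))
      r0 <- as.integer(round(px_y(sel$center[2] - sel$size[2] / 2)))
      r1 <- as.integer(round(px_y(sel$center[2] + sel$size[2] / 2)))
      yellow <- c(255L, 255L, 0L)
      img <- raster_line(img, r0, c0, r0, c1, yellow)
      img <- raster_line(img, r1, c0, r1, c1, yellow)
      img <- raster_line(img, r0, c0, r1, c0, yellow)
      img <- raster_line(img, r0, c1, r1, c1, yellow)
    }
  }

  # sat bands: purple shading where the pixel lies inside the slab
  if (isTRUE(layout$show_sat_bands) && length(ds$sat_bands)) {
    rows <- seq_len(size); cols <- seq_len(size)
    pys <- ext[1, 2] + (rows - 0.5) / size * (ext[2, 2] - ext[1, 2])
    pxs <- ext[1, 1] + (cols - 0.5) / size * (ext[2, 1] - ext[1, 1])
    for (sb in ds$sat_bands) {
      dist <- outer(pys * sb$normal[2], pxs * sb$normal[1], `+`) +
        z_slice * sb$normal[3]
      inside <- abs(dist - sb$distance) <= sb$thickness / 2
      if (!any(inside)) next
      for (ch in 1:3) {
        purple <- c(160L, 60L, 200L)[ch]
        plane <- img[, , ch]
        plane[inside] <- as.integer(round(0.5 * plane[inside] + 0.5 * purple))
        img[, , ch] <- plane
      }
    }
  }
  img
}

#' Build a secondary-capture report series
#'
#' Renders one panel per requested slice plus two summary panels (the
#' acquisition grid and selection referenced to anatomy, and the overlay map
#' alone), then encodes them as a DICOM Secondary Capture series via
#' [write_secondary_capture()]. PNG copies are written alongside.
#'
#' @param ds a reconstructed frequency-domain single-channel [mrs_dataset()].
#' @param anatomical anatomical volume list (`values`, `geometry`) or `NULL`.
#' @param layout a [report_layout()] with a non-empty `slices`.
#' @param path output DICOM path stem.
#' @param png_dir optional directory for PNG copies (default: none).
#' @return character vector of DICOM file paths (`length(slices) + 2`).
#' @export
build_report <- function(ds, anatomical, layout, path, png_dir = NULL) {
  if (length(layout$slices) == 0L) stop("empty slice list")
  panels <- lapply(layout$slices, function(s)
    render_slice_panel(ds, anatomical, layout, s))
  # summary 1: grid + annotations, no spectra window content (tiny window)
  sum_layout <- layout
  sum_layout$grid_window <- c(1L, 1L, 1L, 1L)
  mid <- layout$slices[(length(layout$slices) + 1L) %/% 2L]
  panels <- c(panels, list(render_slice_panel(ds, anatomical, sum_layout, mid)))
  # summary 2: overlay-only view (or plain anatomy when no overlay)
  ov_layout <- sum_layout
  ov_layout$show_selection <- FALSE
  panels <- c(panels, list(render_slice_panel(ds, anatomical, ov_layout, mid)))
  if (!is.null(png_dir)) {
    if (!dir.exists(png_dir)) dir.create(png_dir, recursive = TRUE)
    for (i in seq_along(panels))
      png::writePNG(panels[[i]] / 255, file.path(png_dir,
                                                 sprintf("panel_%02d.png", i)))
  }
  write_secondary_capture(panels, path)
}
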