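#' Spectral axis of an MRSI acquisition
#'
#' Bundles the sampling parameters of the spectral dimension and owns all
#' frequency/ppm/index arithmetic. The dwell time and sweep width are
#' redundant (`sweep_width == 1/dwell`) and are checked against each other.
#'
#' Index convention: spectral indices are 0-based. In the frequency domain the
#' carrier (0 Hz offset) sits at index `floor(n_points/2)` (the centred
#' position after an fftshift), and chemical shift in ppm decreases as the
#' index increases, the usual NMR display convention:
#' \deqn{ppm(i) = ppm_{ref} + (\lfloor N/2 \rfloor - i) \cdot SW / (N f_0)}
#'
#' @param n_points number of spectral samples (>= 1).
#' @param dwell dwell time in seconds per sample.
#' @param f0 transmitter frequency in MHz.
#' @param ppm_ref chemical shift in ppm assigned to the carrier frequency.
#'   Defaults to 4.7, water at body temperature, the standard in vivo 1H
#'   reference.
#' @param sweep_width spectral width in Hz; defaults to `1/dwell`.
#' @param domain `"time"` or `"frequency"`.
#' @return an object of class `spectral_axis`.
#' @export
spectral_axis <- function(n_points, dwell, f0, ppm_ref = 4.7,
                          sweep_width = 1 / dwell, domain = "time") {
  n_points <- as.integer(n_points)
  stopifnot(length(n_points) == 1L, n_points >= 1L,
            length(dwell) == 1L, dwell > 0,
            length(f0) == 1L, f0 > 0)
  domain <- match.arg(domain, c("time", "frequency"))
  if (abs(sweep_width * dwell - 1) > 1e-9) {
    stop("sweep_width must equal 1/dwell (relative tolerance 1e-9); got SW*dwell = ",
         format(sweep_width * dwell, digits = 15))
  }
  structure(
    list(n_points = n_points, dwell = dwell, sweep_width = sweep_width,
         f0 = f0, ppm_ref = ppm_ref, domain = domain),
    class = "spectral_axis"
  )
}

#' @export
print.spectral_axis <- function(x, ...) {
  cat(sprintf("<spectral_axis> %d pts, SW %.6g Hz, f0 %.6g MHz, ref %.3g ppm, %s domain\n",
              x$n_points, x$sweep_width, x$f0, x$ppm_ref, x$domain))
  invisible(x)
}

#' Hz per spectral bin
#' @param axis a [spectral_axis()].
#' @return frequency increment of one spectral bin, in Hz.
#' @export
hz_per_bin <- function(axis) axis$sweep_width / axis$n_points

#' Offset frequency (Hz from the carrier) of each spectral bin
#'
#' Bin `i` (0-based, frequency domain, carrier centred at `floor(N/2)`) has
#' offset frequency `(i - floor(N/2)) * SW / N`.
#'
#' @param axis a [spectral_axis()].
#' @return numeric vector of length `n_points`, Hz.
#' @export
bin_offset_hz <- function(axis) {
  n <- axis$n_points
  (seq_len(n) - 1L - n %/% 2L) * axis$sweep_width / n
}

#' Convert a chemical shift to a (fractional) spectral index
#'
#' @param axis a frequency-domain [spectral_axis()].
#' @param ppm chemical shift(s) in ppm.
#' @return fractional 0-based spectral index (index increases as ppm
#'   decreases).
#' @export
ppm_to_index <- function(axis, ppm) {
  if (axis$domain != "frequency")
    stop("ppm_to_index requires a frequency-domain axis")
  n <- axis$n_points
  idx <- n %/% 2L - (ppm - axis$ppm_ref) * n * axis$f0 / axis$sweep_width
  span <- ppm_range(axis)
  bad <- ppm < span[1] | ppm > span[2]
  if (any(bad)) {
    stop(sprintf("ppm value %.6g outside axis range [%.6g, %.6g] ppm",
                 ppm[which(bad)[1]], span[1], span[2]))
  }
  idx
}

#' Convert an integer spectral index to its chemical shift
#'
#' @param axis a frequency-domain [spectral_axis()].
#' @param index 0-based integer spectral index in `[0, n_points)`.
#' @return chemical shift in ppm.
#' @export
index_to_ppm <- function(axis, index) {
  if (axis$domain != "frequency")
    stop("index_to_ppm requires a frequency-domain axis")
  n <- axis$n_points
  if (any(index < 0 | index >= n))
    stop("spectral index out of bounds [0, ", n - 1L, "]")
  axis$ppm_ref + (n %/% 2L - index) * axis$sweep_width / (n * axis$f0)
}

#' ppm span covered by the axis
#' @param axis a [spectral_axis()].
#' @return `c(lo, hi)`: ppm of the last and first bin (lo < hi).
#' @export
ppm_range <- function(axis) {
  n <- axis$n_points
  p0 <- axis$ppm_ref + (n %/% 2L) * axis$sweep_width / (n * axis$f0)
  p1 <- axis$ppm_ref + (n %/% 2L - (n - 1L)) * axis$sweep_width / (n * axis$f0)
  c(p1, p0)
}

axis_as_domain <- function(axis, domain) {
  axis$domain <- domain
  axis
}
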