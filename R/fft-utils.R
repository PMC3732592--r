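# Array FFT helpers shared by the phantom generator and the recon chain.
# Conventions (fixed package-wide so the phantom forward model round-trips
# exactly): forward transforms are unscaled sums, inverse transforms carry
# the full 1/N; the centred (zero-frequency-at-floor(N/2)) layout is obtained
# with fftshift after a forward transform and undone with ifftshift before an
# inverse transform.

fft_axis <- function(arr, axis, inverse = FALSE, scale = FALSE) {
  d <- dim(arr)
  perm <- c(axis, setdiff(seq_along(d), axis))
  a <- aperm(arr, perm)
  m <- matrix(a, nrow = d[axis])
  m <- stats::mvfft(m, inverse = inverse)
  if (scale) m <- m / d[axis]
  a <- array(m, dim = d[perm])
  aperm(a, order(perm))
}

shift_index <- function(n, inverse = FALSE) {
  h <- if (inverse) ceiling(n / 2) else floor(n / 2)
  if (h == 0L || h == n) return(seq_len(n))
  c(seq.int(h + 1L, n), seq_len(h))
}

fftshift_axis <- function(arr, axis, inverse = FALSE) {
  d <- dim(arr)
  idx <- rep(list(quote(expr = )), length(d))
  idx[[axis]] <- shift_index(d[axis], inverse)
  do.call(`[`, c(list(arr), idx, list(drop = FALSE)))
}

# Apply a function along the spectral axis (4) of the 5-D data array.
map_spectral <- function(data, fun) {
  d <- dim(data)
  m <- matrix(aperm(data, c(4, 1, 2, 3, 5)), nrow = d[4])
  m <- fun(m)
  aperm(array(m, dim = d[c(4, 1, 2, 3, 5)]), order(c(4L, 1L, 2L, 3L, 5L)))
}
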