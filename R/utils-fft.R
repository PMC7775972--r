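# FFT utilities shared by the simulator, alignment, background removal and
# dipole inversion. R's fft() transforms over all array dimensions; the
# normalized inverse and axis-restricted variants live here so every module
# uses one convention.

fft_nd <- function(x) stats::fft(x)

ifft_nd <- function(x) stats::fft(x, inverse = TRUE) / length(x)

# Signed DFT index (0, 1, ..., -2, -1), matching the standard fftfreq layout.
fft_index <- function(n) {
  i <- 0:(n - 1)
  i[i >= ceiling(n / 2)] <- i[i >= ceiling(n / 2)] - n
  i
}

# Spatial frequencies in cycles per unit length for sample spacing d.
fft_freq <- function(n, d = 1) fft_index(n) / (n * d)

# 3D arrays of k-coordinates (cycles/mm) for a grid with the given voxel size.
k_grid <- function(shape, voxel_size_mm = c(1, 1, 1)) {
  fx <- fft_freq(shape[1], voxel_size_mm[1])
  fy <- fft_freq(shape[2], voxel_size_mm[2])
  fz <- fft_freq(shape[3], voxel_size_mm[3])
  list(
    kx = array(fx, dim = shape),
    ky = aperm(array(fy, dim = shape[c(2, 1, 3)]), c(2, 1, 3)),
    kz = aperm(array(fz, dim = shape[c(3, 1, 2)]), c(2, 3, 1))
  )
}

# FFT along a single axis of a 3D (or 4D) array, via mvfft on a reshaped copy.
fft_axis <- function(x, axis, inverse = FALSE) {
  d <- dim(x)
  perm <- c(axis, setdiff(seq_along(d), axis))
  xp <- aperm(x, perm)
  dp <- dim(xp)
  m <- matrix(xp, nrow = dp[1])
  m <- stats::mvfft(m, inverse = inverse)
  xp <- array(m, dim = dp)
  aperm(xp, order(perm))
}

#' Translate a volume by a (possibly subvoxel) shift using Fourier phase ramps
#'
#' Shifting by `shift` voxels moves image content in the positive axis
#' direction: `out(x) = in(x - shift)` with periodic boundaries.
#'
#' @param vol 3D numeric or complex array.
#' @param shift numeric length-3 shift in voxels (can be fractional).
#' @return array of the same type and dimensions.
#' @keywords internal
fourier_shift <- function(vol, shift) {
  if (all(shift == 0)) return(vol)
  kk <- k_grid(dim(vol), c(1, 1, 1))
  ramp <- exp(-2i * pi * (kk$kx * shift[1] + kk$ky * shift[2] + kk$kz * shift[3]))
  out <- ifft_nd(fft_nd(vol) * ramp)
  if (is.complex(vol)) out else Re(out)
}

# Wrap phase into (-pi, pi].
wrap_phase <- function(x) atan2(sin(x), cos(x))

# Frequency shift (Hz) produced by 1 ppm of field change at this field
# strength: gamma/2pi [MHz/T] * B0 [T].
hz_per_ppm <- function(params) params$gamma_MHz_per_T * params$field_strength_T

# Voxel-center coordinates (mm) relative to the grid center, per axis,
# expanded to full 3D arrays.
coord_grid <- function(shape, voxel_size_mm) {
  cx <- (seq_len(shape[1]) - (shape[1] + 1) / 2) * voxel_size_mm[1]
  cy <- (seq_len(shape[2]) - (shape[2] + 1) / 2) * voxel_size_mm[2]
  cz <- (seq_len(shape[3]) - (shape[3] + 1) / 2) * voxel_size_mm[3]
  list(
    x = array(cx, dim = shape),
    y = aperm(array(cy, dim = shape[c(2, 1, 3)]), c(2, 1, 3)),
    z = aperm(array(cz, dim = shape[c(3, 1, 2)]), c(2, 3, 1))
  )
}
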