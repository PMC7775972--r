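#' Fourier-domain unit dipole kernel
#'
#' `D(k) = 1/3 - (k . b)^2 / |k|^2` on the discrete FFT grid, with
#' `D(0) = 0`: the spatial mean of the susceptibility distribution is
#' unobservable, which is also why maps are referenced to the whole-brain
#' mean downstream. Values lie in `[-2/3, 1/3]`, reaching -2/3 along the
#' field direction, 1/3 perpendicular to it, and 0 on the magic-angle cone.
#'
#' @param shape grid dimensions.
#' @param voxel_size_mm voxel size (mm).
#' @param b0_direction unit vector of the main field.
#' @return object of class `dipole_kernel` with elements `D`, `shape`,
#'   `voxel_size_mm`, `b0_direction`.
#' @export
make_dipole_kernel <- function(shape, voxel_size_mm, b0_direction) {
  stopifnot(all(voxel_size_mm > 0), length(shape) == 3)
  b <- b0_direction / sqrt(sum(b0_direction^2))
  kk <- k_grid(shape, voxel_size_mm)
  k2 <- kk$kx^2 + kk$ky^2 + kk$kz^2
  kb <- kk$kx * b[1] + kk$ky * b[2] + kk$kz * b[3]
  D <- array(0, dim = shape)
  nz <- k2 > 0
  D[nz] <- 1 / 3 - (kb[nz]^2) / k2[nz]
  structure(list(D = D, shape = shape, voxel_size_mm = voxel_size_mm,
                 b0_direction = b), class = "dipole_kernel")
}

# Normalized spherical kernel of the given radius, centered at the FFT
# origin (wrap-around layout), returned as its Fourier transform. The sphere
# boundary is anti-aliased with a one-voxel partial-volume ramp: a hard
# rasterized sphere violates the mean-value property at the 1e-1 level,
# which the deconvolution step would amplify by up to 1/reg_param.
smv_kernel_fft <- function(shape, voxel_size_mm, radius_mm) {
  ix <- fft_index(shape[1]) * voxel_size_mm[1]
  iy <- fft_index(shape[2]) * voxel_size_mm[2]
  iz <- fft_index(shape[3]) * voxel_size_mm[3]
  X <- array(ix, dim = shape)
  Y <- aperm(array(iy, dim = shape[c(2, 1, 3)]), c(2, 1, 3))
  Z <- aperm(array(iz, dim = shape[c(3, 1, 2)]), c(2, 3, 1))
  r <- sqrt(X^2 + Y^2 + Z^2)
  w <- min(voxel_size_mm)
  k <- pmin(pmax((radius_mm - r) / w + 0.5, 0), 1)
  k <- k / sum(k)
  fft_nd(k)
}

#' Variable-kernel spherical-mean-value background field removal (v-SHARP)
#'
#' Removes the harmonic background field generated by sources outside the
#' mask. Spherical-mean-value filters with radii descending from
#' `max_kernel_mm` to one voxel are applied; each voxel uses the largest
#' sphere that fits entirely inside the mask, so the usable region erodes
#' only by the smallest radius at the boundary. The filtered field is then
#' deconvolved by the largest kernel's `(1 - SMV)` response, truncating
#' Fourier components whose response magnitude falls below `reg_param`.
#'
#' @param field a `field_map_result` or a frequency-offset volume (Hz).
#' @param mask logical volume or `brain_mask` (the phi0-refined mask).
#' @param max_kernel_mm largest sphere radius (default 12 mm).
#' @param reg_param truncation threshold on the `(1 - SMV)` Fourier response
#'   (default 0.02).
#' @param voxel_size_mm voxel size; taken from `params` if supplied.
#' @param params optional [acquisition_params()].
#' @return list with `local_field_hz` (zero outside the eroded mask) and
#'   `eroded_mask` (a `brain_mask`, provenance `"vsharp-eroded"`).
#' @export
vsharp_background_removal <- function(field, mask, max_kernel_mm = 12,
                                      reg_param = 0.02,
                                      voxel_size_mm = NULL, params = NULL) {
  if (inherits(field, "field_map_result")) field_v <- field$delta_f_hz
  else field_v <- field
  maskv <- as_mask(mask)
  if (is.null(voxel_size_mm))
    voxel_size_mm <- if (!is.null(params)) params$voxel_size_mm else c(1, 1, 1)
  shape <- dim(field_v)
  step <- min(voxel_size_mm)
  radii <- rev(seq(step, max_kernel_mm, by = step))
  if (length(radii) == 0) radii <- step

  fmask <- array(as.numeric(maskv), dim = shape)
  fv <- field_v
  fv[!maskv] <- 0
  Ffield <- fft_nd(fv)
  Fmask <- fft_nd(fmask)

  filtered <- array(0, dim = shape)
  covered <- array(FALSE, dim = shape)
  eroded_largest <- NULL
  S_largest <- NULL
  for (rad in radii) {
    S <- smv_kernel_fft(shape, voxel_size_mm, rad)
    inside <- Re(ifft_nd(S * Fmask)) > 1 - 1e-6
    if (is.null(eroded_largest)) {
      eroded_largest <- inside
      S_largest <- S
    }
    smv_field <- Re(ifft_nd(S * Ffield))
    new_vox <- inside & !covered
    filtered[new_vox] <- fv[new_vox] - smv_field[new_vox]
    covered <- covered | inside
  }
  if (!any(covered))
    stop("mask is thinner than the smallest SMV kernel everywhere")
  final_mask <- covered

  C <- 1 - S_largest
  inv <- fft_nd(filtered) / C
  inv[Mod(C) < reg_param] <- 0
  local <- Re(ifft_nd(inv))
  local[!final_mask] <- 0
  list(local_field_hz = local,
       eroded_mask = structure(list(mask = final_mask,
                                    provenance = "vsharp-eroded"),
                               class = "brain_mask"))
}

# Sign with sign(0) := +1, the convention used when thresholding the dipole
# kernel's zero cone.
sign_pos <- function(x) ifelse(x >= 0, 1, -1)

#' Thresholded k-space division (TKD) dipole inversion
#'
#' Direct inversion of the dipole convolution: the field (converted to ppm)
#' is divided by the dipole kernel in k-space, replacing near-zero kernel
#' values by `threshold * sign(D)` (with `sign(0) = +1`) to stabilize the
#' magic-angle cone.
#'
#' @param local_field_hz background-free frequency-offset volume (Hz).
#' @param kernel a [make_dipole_kernel()] on the same grid.
#' @param params [acquisition_params()] (field strength, gyromagnetic ratio).
#' @param threshold kernel magnitude threshold in (0, 2/3] (default 0.2).
#' @param mask optional mask stored with the result.
#' @param correct_underestimation rescale by the central value of the
#'   inversion's point-spread function, `mean(D/D_thresholded)`, the
#'   standard amplitude correction for TKD's systematic underestimation
#'   (default TRUE).
#' @return object of class `susceptibility_map` (unreferenced), chi in ppb.
#' @export
tkd_inversion <- function(local_field_hz, kernel, params = acquisition_params(),
                          threshold = 0.2, mask = NULL,
                          correct_underestimation = TRUE) {
  if (threshold <= 0 || threshold > 2 / 3)
    stop("threshold must lie in (0, 2/3]")
  D <- kernel$D
  Dt <- ifelse(abs(D) >= threshold, D, threshold * sign_pos(D))
  f_ppm <- local_field_hz / hz_per_ppm(params)
  chi_ppm <- Re(ifft_nd(fft_nd(f_ppm) / Dt))
  psi <- if (correct_underestimation) mean(D / Dt) else 1
  susceptibility_map(chi_ppm * 1000 / psi, mask = mask, method = "tkd",
                     reference = "unreferenced",
                     inversion_params = list(threshold = threshold,
                                             psf_correction = psi))
}

#' Streak-reduced two-pass dipole inversion
#'
#' A two-level inversion in the spirit of streak-artifact-reducing QSM:
#' strong sources (air bubbles, vessels) dominate the streaking that direct
#' inversion spreads along the magic-angle cone, so they are estimated and
#' removed first. (1) A first-pass TKD detects strong sources by
#' thresholding |chi| at a high percentile; (2) the strong-source component
#' is re-estimated with weak regularization, its forward field computed and
#' subtracted from the input; (3) the residual (weak-source) field is
#' inverted with stronger regularization; (4) the two components are summed.
#'
#' @param local_field_hz background-free frequency-offset volume (Hz).
#' @param kernel a [make_dipole_kernel()] on the same grid.
#' @param params [acquisition_params()].
#' @param threshold first-pass TKD threshold (default 0.2).
#' @param strong_percentile percentile of |chi| defining strong sources
#'   (default 99.5).
#' @param strong_pass_threshold weakly regularized threshold used to
#'   re-estimate the strong sources (default 0.05).
#' @param residual_threshold more strongly regularized threshold for the
#'   residual field (default 0.25).
#' @param mask optional mask stored with the result (also restricts the
#'   percentile computation).
#' @return object of class `susceptibility_map` (unreferenced), chi in ppb.
#' @export
streak_reduced_inversion <- function(local_field_hz, kernel,
                                     params = acquisition_params(),
                                     threshold = 0.2,
                                     strong_percentile = 99.5,
                                     strong_pass_threshold = 0.05,
                                     residual_threshold = 0.25,
                                     mask = NULL) {
  first <- tkd_inversion(local_field_hz, kernel, params, threshold, mask)
  maskv <- if (is.null(mask)) NULL else as_mask(mask)
  absv <- if (is.null(maskv)) abs(first$chi_ppb) else abs(first$chi_ppb[maskv])
  cut <- as.numeric(quantile(absv, strong_percentile / 100))
  strong <- abs(first$chi_ppb) > cut
  if (!is.null(maskv)) strong <- strong & maskv

  weakreg <- tkd_inversion(local_field_hz, kernel, params,
                           strong_pass_threshold, mask)
  chi_strong <- array(0, dim = dim(first$chi_ppb))
  chi_strong[strong] <- weakreg$chi_ppb[strong]

  f_strong <- Re(ifft_nd(kernel$D * fft_nd(chi_strong / 1000))) *
    hz_per_ppm(params)
  resid_field <- local_field_hz - f_strong
  chi_resid <- tkd_inversion(resid_field, kernel, params,
                             residual_threshold, mask)
  susceptibility_map(chi_strong + chi_resid$chi_ppb, mask = mask,
                     method = "star", reference = "unreferenced",
                     inversion_params = list(
                       threshold = threshold,
                       strong_percentile = strong_percentile,
                       strong_pass_threshold = strong_pass_threshold,
                       residual_threshold = residual_threshold))
}

#' Susceptibility map container
#'
#' @param chi_ppb susceptibility volume in ppb.
#' @param mask optional logical volume or `brain_mask`.
#' @param method inversion method tag.
#' @param reference referencing tag.
#' @param inversion_params named list of the inversion parameters used.
#' @return object of class `susceptibility_map`.
#' @export
susceptibility_map <- function(chi_ppb, mask = NULL, method = "tkd",
                               reference = "unreferenced",
                               inversion_params = list()) {
  structure(list(chi_ppb = chi_ppb, mask = mask, method = method,
                 reference = reference, inversion_params = inversion_params),
            class = "susceptibility_map")
}

#' Reference a susceptibility map to the whole-brain mean
#'
#' The k-space center of the inverted susceptibility is undefined, so maps
#' are relative; lacking a pathology-free internal reference region, the
#' whole-brain mean is set to zero. Idempotent and invariant to constant
#' shifts of the input.
#'
#' @param chi a `susceptibility_map` (or chi volume in ppb).
#' @param mask logical volume or `brain_mask`.
#' @return a `susceptibility_map` with reference `"whole-brain-mean-zero"`.
#' @export
reference_susceptibility <- function(chi, mask) {
  maskv <- as_mask(mask)
  if (!any(maskv)) stop("empty mask")
  if (inherits(chi, "susceptibility_map")) {
    v <- chi$chi_ppb
    if (!all(is.finite(v[maskv]))) stop("non-finite chi inside mask")
    chi$chi_ppb <- v - mean(v[maskv])
    chi$reference <- "whole-brain-mean-zero"
    chi$mask <- maskv
    chi
  } else {
    if (!all(is.finite(chi[maskv]))) stop("non-finite chi inside mask")
    susceptibility_map(chi - mean(chi[maskv]), mask = maskv,
                       reference = "whole-brain-mean-zero")
  }
}
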