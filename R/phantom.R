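#' Specification of a synthetic whole-brain susceptibility phantom
#'
#' Defines the geometry, tissue properties and acquisition artefacts of a
#' ground-truth phantom: a brain-shaped ellipsoid (white-matter core, grey
#' matter shell and a cortical-ribbon patch emulating a focal M1
#' hyperintensity) immersed in a susceptibility-matched surround inside a
#' spherical container, with optional air bubbles. Artefact knobs cover
#' per-coil phase offsets, complex noise, per-repeat frequency drift, and
#' phase-encode translations of echoes and repeats.
#'
#' Tissue susceptibilities are in ppb relative to the surround, R2* in 1/s,
#' M0 in arbitrary units. Defaults are plausible for fixed post-mortem tissue
#' at 7 T and are deliberately configuration-exposed rather than canonical.
#' Default drift per repeat is {0, 5, 8, 9} Hz: decreasing increments
#' {5, 3, 1} Hz, emulating a scanner whose passive-shim temperature settles
#' over the course of the repeats. The default inter-repeat and per-echo
#' translations along the phase-encode axis shrink/grow accordingly.
#'
#' @param grid_shape 3 positive integers.
#' @param container_radius_mm radius of the fluid-filled spherical container.
#' @param brain_semiaxes_mm semi-axes (mm) of the brain ellipsoid.
#' @param white_fraction scale of the inner (white matter) ellipsoid relative
#'   to the brain ellipsoid.
#' @param tissue_chi_ppb,tissue_r2s_per_s,tissue_m0 named lists with entries
#'   `surround`, `white`, `grey`, `ribbon`.
#' @param ribbon_center_mm,ribbon_radius_mm sphere (mm, grid-centered
#'   coordinates) whose intersection with grey matter defines the ribbon
#'   patch; `NULL` centers it on the top pole of the brain ellipsoid.
#' @param bubbles list of `list(center_mm=, radius_mm=, chi_ppm=)` air
#'   bubbles; must lie inside the container.
#' @param n_coils number of receive coils (>= 1).
#' @param coil_phase_offsets_rad per-coil constant phase offsets; `NULL`
#'   spreads them evenly over (-pi, pi].
#' @param noise_sigma std of the additive complex Gaussian noise per channel
#'   (same units as M0).
#' @param repeat_drift_Hz per-repeat global frequency offset (Hz).
#' @param repeat_pe_shift_voxels per-repeat translation along the
#'   phase-encode axis (voxels), the image-domain footprint of the drift.
#' @param echo_pe_shift_voxels per-echo translation along the phase-encode
#'   axis (voxels), growing with echo time under drift.
#' @param seed RNG seed used by [simulate_acquisition()].
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(48, 48, 48),
                         container_radius_mm = 44,
                         brain_semiaxes_mm = c(38, 30, 28),
                         white_fraction = 0.6,
                         tissue_chi_ppb = list(surround = 0, white = -30,
                                               grey = 20, ribbon = 50),
                         tissue_r2s_per_s = list(surround = 0, white = 50,
                                                 grey = 40, ribbon = 50),
                         tissue_m0 = list(surround = 0, white = 1000,
                                          grey = 800, ribbon = 800),
                         ribbon_center_mm = NULL,
                         ribbon_radius_mm = 8,
                         bubbles = list(list(center_mm = c(0, 32, 0),
                                             radius_mm = 3, chi_ppm = 9.4)),
                         n_coils = 4L,
                         coil_phase_offsets_rad = NULL,
                         noise_sigma = 16,
                         repeat_drift_Hz = c(0, 5, 8, 9),
                         repeat_pe_shift_voxels = c(0, 1.0, 0.6, 0.2),
                         echo_pe_shift_voxels = c(0, 0.3, 0.6, 0.9, 1.2, 1.5),
                         seed = 1L) {
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 4),
            container_radius_mm > 0, length(brain_semiaxes_mm) == 3,
            white_fraction > 0, white_fraction < 1, ribbon_radius_mm > 0)
  if (any(brain_semiaxes_mm <= 0))
    stop("degenerate geometry: brain ellipsoid semi-axes must be positive")
  labs <- c("surround", "white", "grey", "ribbon")
  for (l in list(tissue_chi_ppb, tissue_r2s_per_s, tissue_m0))
    if (!all(labs %in% names(l)))
      stop("tissue property lists need entries: ", paste(labs, collapse = ", "))
  if (n_coils < 1) stop("n_coils must be >= 1")
  if (is.null(coil_phase_offsets_rad))
    coil_phase_offsets_rad <- wrap_phase(2 * pi * (seq_len(n_coils) - 1) / n_coils)
  if (length(coil_phase_offsets_rad) != n_coils)
    stop("coil_phase_offsets_rad must have one entry per coil")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  for (b in bubbles) {
    stopifnot(length(b$center_mm) == 3, b$radius_mm > 0)
    if (sqrt(sum(b$center_mm^2)) + b$radius_mm > container_radius_mm)
      stop("bubble extends outside the container")
  }
  if (is.null(ribbon_center_mm))
    ribbon_center_mm <- c(0, 0, brain_semiaxes_mm[3] * (1 + white_fraction) / 2)
  structure(list(
    grid_shape = as.integer(grid_shape),
    container_radius_mm = container_radius_mm,
    brain_semiaxes_mm = as.numeric(brain_semiaxes_mm),
    white_fraction = white_fraction,
    tissue_chi_ppb = tissue_chi_ppb,
    tissue_r2s_per_s = tissue_r2s_per_s,
    tissue_m0 = tissue_m0,
    ribbon_center_mm = as.numeric(ribbon_center_mm),
    ribbon_radius_mm = ribbon_radius_mm,
    bubbles = bubbles,
    n_coils = as.integer(n_coils),
    coil_phase_offsets_rad = as.numeric(coil_phase_offsets_rad),
    noise_sigma = noise_sigma,
    repeat_drift_Hz = as.numeric(repeat_drift_Hz),
    repeat_pe_shift_voxels = as.numeric(repeat_pe_shift_voxels),
    echo_pe_shift_voxels = as.numeric(echo_pe_shift_voxels),
    seed = as.integer(seed)
  ), class = "phantom_spec")
}

# Integer label codes used in the ground-truth label volume.
PHANTOM_LABELS <- c(surround = 0L, white = 1L, grey = 2L, ribbon = 3L,
                    bubble = 4L)

#' Build the ground-truth phantom volumes
#'
#' Rasterizes the phantom geometry into piecewise-constant susceptibility,
#' R2* and M0 maps plus a tissue label volume and brain mask. Bubbles
#' overwrite susceptibility with their ppm value (converted to ppb) and are
#' signal voids (M0 = 0). Fully deterministic.
#'
#' @param spec a [phantom_spec()].
#' @param params an [acquisition_params()] supplying the voxel size.
#' @return an object of class `ground_truth` with elements `chi_ppb`,
#'   `r2s_per_s`, `m0`, `labels`, `brain_mask`, `voxel_size_mm`.
#' @export
build_phantom <- function(spec, params = acquisition_params()) {
  shape <- spec$grid_shape
  vox <- params$voxel_size_mm
  co <- coord_grid(shape, vox)

  labels <- array(PHANTOM_LABELS[["surround"]], dim = shape)
  brain <- (co$x / spec$brain_semiaxes_mm[1])^2 +
           (co$y / spec$brain_semiaxes_mm[2])^2 +
           (co$z / spec$brain_semiaxes_mm[3])^2 <= 1
  wa <- spec$brain_semiaxes_mm * spec$white_fraction
  white <- (co$x / wa[1])^2 + (co$y / wa[2])^2 + (co$z / wa[3])^2 <= 1
  labels[brain] <- PHANTOM_LABELS[["grey"]]
  labels[white] <- PHANTOM_LABELS[["white"]]

  rib_sphere <- (co$x - spec$ribbon_center_mm[1])^2 +
                (co$y - spec$ribbon_center_mm[2])^2 +
                (co$z - spec$ribbon_center_mm[3])^2 <= spec$ribbon_radius_mm^2
  rib <- rib_sphere & labels == PHANTOM_LABELS[["grey"]]
  if (!any(rib))
    stop("ribbon region does not overlap grey matter")
  labels[rib] <- PHANTOM_LABELS[["ribbon"]]

  chi <- array(0, dim = shape)
  r2s <- array(0, dim = shape)
  m0 <- array(0, dim = shape)
  for (lab in names(PHANTOM_LABELS)[1:4]) {
    sel <- labels == PHANTOM_LABELS[[lab]]
    chi[sel] <- spec$tissue_chi_ppb[[lab]]
    r2s[sel] <- spec$tissue_r2s_per_s[[lab]]
    m0[sel] <- spec$tissue_m0[[lab]]
  }

  for (b in spec$bubbles) {
    inb <- (co$x - b$center_mm[1])^2 + (co$y - b$center_mm[2])^2 +
           (co$z - b$center_mm[3])^2 <= b$radius_mm^2
    chi[inb] <- b$chi_ppm * 1000
    r2s[inb] <- 0
    m0[inb] <- 0
    labels[inb] <- PHANTOM_LABELS[["bubble"]]
  }

  brain_mask <- labels %in% PHANTOM_LABELS[c("white", "grey", "ribbon")]
  dim(brain_mask) <- shape
  structure(list(chi_ppb = chi, r2s_per_s = r2s, m0 = m0, labels = labels,
                 brain_mask = brain_mask, voxel_size_mm = vox),
            class = "ground_truth")
}

#' Forward dipole field of a susceptibility distribution
#'
#' Computes the frequency-offset map induced by a susceptibility volume via
#' k-space convolution with the unit dipole kernel
#' `D(k) = 1/3 - (k.b)^2/|k|^2`, `D(0) = 0` (the spatial mean of chi is
#' unobservable, matching the whole-brain referencing convention of the
#' inversion stage). The convolution is periodic; by default the grid is
#' zero-padded by a factor of 2 per axis to suppress wrap-around.
#'
#' @param chi_ppb susceptibility volume in ppb.
#' @param params an [acquisition_params()] (voxel size, B0 direction and
#'   strength, gyromagnetic ratio).
#' @param pad_factor integer zero-padding factor (1 disables padding).
#' @return frequency-offset volume in Hz.
#' @export
forward_dipole_field <- function(chi_ppb, params = acquisition_params(),
                                 pad_factor = 2) {
  if (!all(is.finite(chi_ppb))) stop("chi volume contains non-finite values")
  shape <- dim(chi_ppb)
  stopifnot(length(shape) == 3, pad_factor >= 1)
  pshape <- shape * as.integer(pad_factor)
  chip <- array(0, dim = pshape)
  chip[seq_len(shape[1]), seq_len(shape[2]), seq_len(shape[3])] <- chi_ppb / 1000
  D <- make_dipole_kernel(pshape, params$voxel_size_mm, params$b0_direction)
  f <- Re(ifft_nd(D$D * fft_nd(chip))) * hz_per_ppm(params)
  f[seq_len(shape[1]), seq_len(shape[2]), seq_len(shape[3])]
}

# Smooth complex coil sensitivity profiles: Gaussian magnitude lobes centered
# on a ring around the volume, a weak linear phase, and the configured
# constant per-coil offset. Deterministic in the coil index.
make_coil_sensitivities <- function(shape, voxel_size_mm, n_coils,
                                    phase_offsets_rad) {
  co <- coord_grid(shape, voxel_size_mm)
  fov <- shape * voxel_size_mm
  sens <- vector("list", n_coils)
  for (c_i in seq_len(n_coils)) {
    if (n_coils == 1) {
      mag <- array(1, dim = shape)
      gvec <- c(0, 0, 0)
    } else {
      ang <- 2 * pi * (c_i - 1) / n_coils
      ctr <- c(cos(ang), sin(ang), 0) * fov[1:3] / 3
      sigma <- max(fov) * 0.6
      mag <- 0.15 + exp(-((co$x - ctr[1])^2 + (co$y - ctr[2])^2 +
                          (co$z - ctr[3])^2) / (2 * sigma^2))
      gvec <- 0.02 * c(cos(ang + 1), sin(ang + 1), cos(2 * ang)) / max(voxel_size_mm)
    }
    ph <- phase_offsets_rad[c_i] +
      gvec[1] * co$x + gvec[2] * co$y + gvec[3] * co$z
    sens[[c_i]] <- mag * exp(1i * ph)
  }
  sens
}

#' Simulate the multi-coil, multi-echo, multi-repeat GRE acquisition
#'
#' Forward-simulates the complex GRE signal of a ground-truth phantom:
#' `S = C_c(r) * M0 * exp(-TE*R2*) * exp(i(phi0_c + 2*pi*(df(r)+drift_r)*TE))`
#' plus additive complex Gaussian noise per channel. Each echo is translated
#' along the phase-encode axis by the configured per-echo shift, and each
#' repeat by its per-repeat shift, via Fourier phase ramps (subvoxel capable).
#' Per-coil constant phase offsets are folded into the smooth sensitivities.
#'
#' @param truth a [build_phantom()] result.
#' @param spec the [phantom_spec()] used to build it.
#' @param params an [acquisition_params()].
#' @param seed RNG seed; defaults to `spec$seed`.
#' @return a [multi_coil_echo_data()] object.
#' @export
simulate_acquisition <- function(truth, spec, params = acquisition_params(),
                                 seed = spec$seed) {
  shape <- dim(truth$chi_ppb)
  stopifnot(identical(dim(truth$m0), shape), identical(dim(truth$r2s_per_s), shape))
  te_s <- params$echo_times_ms / 1000
  if (length(te_s) == 0) stop("echo time list is empty")
  if (spec$noise_sigma < 0) stop("noise_sigma must be >= 0")
  n_rep <- params$n_repeats
  if (length(spec$repeat_drift_Hz) != n_rep)
    stop("repeat_drift_Hz must have one entry per repeat")
  rep_shift <- spec$repeat_pe_shift_voxels
  if (length(rep_shift) < n_rep) rep_shift <- rep_len(rep_shift, n_rep)
  echo_shift <- spec$echo_pe_shift_voxels
  if (length(echo_shift) < length(te_s)) echo_shift <- rep_len(echo_shift, length(te_s))

  df <- forward_dipole_field(truth$chi_ppb, params)
  sens <- make_coil_sensitivities(shape, params$voxel_size_mm, spec$n_coils,
                                  spec$coil_phase_offsets_rad)
  set.seed(seed)
  data <- array(0i, dim = c(shape, length(te_s), spec$n_coils, n_rep))
  nvox <- prod(shape)
  for (r in seq_len(n_rep)) {
    for (n in seq_along(te_s)) {
      decay <- truth$m0 * exp(-te_s[n] * truth$r2s_per_s)
      phase_evo <- exp(2i * pi * (df + spec$repeat_drift_Hz[r]) * te_s[n])
      base <- decay * phase_evo
      shift <- numeric(3)
      shift[params$phase_encode_axis] <- echo_shift[n] + rep_shift[r]
      if (any(shift != 0)) base <- fourier_shift(base, shift)
      for (c_i in seq_len(spec$n_coils)) {
        vol <- sens[[c_i]] * base
        if (spec$noise_sigma > 0)
          vol <- vol + spec$noise_sigma *
            (rnorm(nvox) + 1i * rnorm(nvox))
        data[, , , n, c_i, r] <- vol
      }
    }
  }
  multi_coil_echo_data(data, params)
}

#' Container for raw per-coil complex echo data
#'
#' @param data complex array with dimensions (x, y, z, echo, coil, repeat).
#' @param params an [acquisition_params()]; the echo dimension must match
#'   `echo_times_ms`.
#' @return object of class `multi_coil_echo_data`.
#' @export
multi_coil_echo_data <- function(data, params) {
  d <- dim(data)
  stopifnot(length(d) == 6, is.complex(data))
  if (d[4] != length(params$echo_times_ms))
    stop("echo dimension does not match params$echo_times_ms")
  structure(list(data = data, params = params,
                 grid_shape = d[1:3], n_echoes = d[4],
                 n_coils = d[5], n_repeats = d[6]),
            class = "multi_coil_echo_data")
}

#' @export
print.multi_coil_echo_data <- function(x, ...) {
  cat("Multi-coil GRE echo data: grid", paste(x$grid_shape, collapse = "x"),
      "|", x$n_echoes, "echoes |", x$n_coils, "coils |",
      x$n_repeats, "repeats\n")
  invisible(x)
}
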