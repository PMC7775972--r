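# Shared fixture builders. Everything is generated in code; no data files.

# Acquisition with the standard 6-echo protocol on an isotropic grid.
mini_params <- function(voxel = 2, n_repeats = 1) {
  acquisition_params(voxel_size_mm = rep(voxel, 3), n_repeats = n_repeats)
}

# A small artefact-free phantom spec (single coil, no noise/drift/shifts).
clean_spec <- function(grid_n = 32, n_coils = 1, n_repeats = 1, ...) {
  args <- list(
    grid_shape = rep(grid_n, 3), container_radius_mm = 28,
    brain_semiaxes_mm = c(24, 20, 18),
    ribbon_center_mm = c(0, 0, 15), ribbon_radius_mm = 6,
    bubbles = list(), n_coils = n_coils,
    coil_phase_offsets_rad = rep(0, n_coils), noise_sigma = 0,
    repeat_drift_Hz = rep(0, n_repeats),
    repeat_pe_shift_voxels = rep(0, n_repeats),
    echo_pe_shift_voxels = rep(0, 6))
  over <- list(...)
  args[names(over)] <- over   # plain replacement (modifyList drops unnamed
                              # nested lists such as `bubbles`)
  do.call(phantom_spec, args)
}

# Build a single-coil combined-like acquisition directly from a prescribed
# frequency-offset field (Hz), offset field (rad) and M0/R2* maps via the
# signal equation. Returns a multi_coil_echo_data with one coil, one repeat.
synth_echoes <- function(df_hz, params = mini_params(),
                         m0 = NULL, r2s = NULL, phi0 = NULL,
                         noise_sd = 0, seed = 1) {
  shape <- dim(df_hz)
  if (is.null(m0)) m0 <- array(1000, dim = shape)
  if (is.null(r2s)) r2s <- array(40, dim = shape)
  if (is.null(phi0)) phi0 <- array(0, dim = shape)
  te <- params$echo_times_ms / 1000
  data <- array(0i, dim = c(shape, length(te), 1, 1))
  if (noise_sd > 0) set.seed(seed)
  for (e in seq_along(te)) {
    vol <- m0 * exp(-te[e] * r2s) * exp(1i * (phi0 + 2 * pi * df_hz * te[e]))
    if (noise_sd > 0)
      vol <- vol + noise_sd * (rnorm(length(vol)) + 1i * rnorm(length(vol)))
    data[, , , e, 1, 1] <- vol
  }
  multi_coil_echo_data(data, params)
}

# Ellipsoid mask on a coordinate grid.
ellipsoid_mask <- function(shape, voxel, semiaxes, center = c(0, 0, 0)) {
  co <- pmqsm:::coord_grid(shape, rep(voxel, 3))
  ((co$x - center[1]) / semiaxes[1])^2 +
    ((co$y - center[2]) / semiaxes[2])^2 +
    ((co$z - center[3]) / semiaxes[3])^2 <= 1
}

# Analytic field of a uniformly magnetized sphere (chi in ppm), in Hz;
# zero inside the sphere (this kernel convention), dipolar outside.
analytic_sphere_field <- function(shape, voxel, center_mm, radius_mm,
                                  chi_ppm, params = mini_params(voxel)) {
  co <- pmqsm:::coord_grid(shape, rep(voxel, 3))
  rx <- co$x - center_mm[1]
  ry <- co$y - center_mm[2]
  rz <- co$z - center_mm[3]
  r <- sqrt(rx^2 + ry^2 + rz^2)
  f0 <- pmqsm:::hz_per_ppm(params)
  out <- f0 * chi_ppm / 3 * (radius_mm / pmax(r, 1e-9))^3 *
    (3 * (rz / pmax(r, 1e-9))^2 - 1)
  out[r <= radius_mm] <- 0
  out
}

rmse <- function(x, y) sqrt(mean((x - y)^2))
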