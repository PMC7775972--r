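test_that("k-space slice truncation halves slices and doubles voxel size", {
  p <- acquisition_params(voxel_size_mm = c(0.5, 0.5, 0.55))
  set.seed(4)
  data <- array(complex(real = rnorm(6 * 6 * 208 * 6),
                        imaginary = rnorm(6 * 6 * 208 * 6)),
                dim = c(6, 6, 208, 6, 1, 1))
  mc <- multi_coil_echo_data(data, p)
  out <- truncate_kspace_slice(mc, 2)
  expect_equal(out$grid_shape[3], 104)
  expect_equal(out$params$voxel_size_mm[3], 1.1)
  expect_error(truncate_kspace_slice(mc, 0), ">= 1")
  expect_error(truncate_kspace_slice(mc, 300), "smaller")
})

test_that("slice truncation is the identity for factor 1 and for band-limited input", {
  p <- acquisition_params(voxel_size_mm = c(1, 1, 1))
  n <- 32
  # band-limited along the slice axis: only |k| < n/4 populated
  z <- seq_len(n)
  vol <- array(0i, c(4, 4, n, 6, 1, 1))
  for (e in 1:6) for (i in 1:4) for (j in 1:4) {
    vol[i, j, , e, 1, 1] <- 2 + cos(2 * pi * 3 * z / n + i) +
      1i * sin(2 * pi * 5 * z / n + j + e)
  }
  mc <- multi_coil_echo_data(vol, p)
  id <- truncate_kspace_slice(mc, 1)
  expect_lt(max(Mod(id$data - mc$data)), 1e-10 * max(Mod(mc$data)))
  tr <- truncate_kspace_slice(mc, 2)
  # the retained coarse samples sit at the odd original positions
  expect_lt(max(Mod(tr$data[, , , , , , drop = FALSE] -
                    mc$data[, , seq(1, n, by = 2), , , , drop = FALSE])), 1e-8)
})

test_that("coil phase offsets cancel exactly in the combined phase", {
  p <- mini_params()
  shape <- c(8, 8, 8)
  df <- array(17, shape)     # 17 Hz everywhere
  te <- p$echo_times_ms / 1000
  offs <- c(0.5, -1.2)
  data <- array(0i, c(shape, 6, 2, 1))
  for (c_i in 1:2) for (e in 1:6) {
    data[, , , e, c_i, 1] <- (2 + c_i) *
      exp(1i * (offs[c_i] + 2 * pi * df * te[e]))
  }
  mc <- multi_coil_echo_data(data, p)
  for (w in c("weighted", "unweighted")) {
    cs <- combine_coils(mc, 1, weighting = w)
    for (e in 1:5) {
      expected <- pmqsm:::wrap_phase(2 * pi * 17 * cs$effective_te_ms[e] / 1000)
      expect_lt(max(abs(cs$phase[, , , e] - expected)), 1e-10)
    }
    # sum-of-squares magnitude: coils 3 and 4 -> 5
    expect_equal(as.numeric(cs$magnitude[1, 1, 1, 1]), 5, tolerance = 1e-12)
  }
})

test_that("single coil with zero offset reduces to the wrapped phase difference", {
  p <- mini_params()
  set.seed(9)
  df <- array(rnorm(8^3, sd = 30), c(8, 8, 8))
  mc <- synth_echoes(df, p)
  cs <- combine_coils(mc, 1)
  te <- p$echo_times_ms / 1000
  for (e in 1:5) {
    raw_n <- Arg(mc$data[, , , e + 1, 1, 1])
    raw_1 <- Arg(mc$data[, , , 1, 1, 1])
    expect_lt(max(abs(cs$phase[, , , e] -
                      pmqsm:::wrap_phase(raw_n - raw_1))), 1e-12)
  }
})

test_that("combined magnitude is invariant to per-coil phase offsets", {
  p <- mini_params()
  shape <- c(6, 6, 6)
  set.seed(2)
  base <- array(complex(real = rnorm(prod(shape) * 6),
                        imaginary = rnorm(prod(shape) * 6)),
                dim = c(shape, 6))
  mk <- function(offs) {
    d <- array(0i, c(shape, 6, 2, 1))
    for (c_i in 1:2) for (e in 1:6)
      d[, , , e, c_i, 1] <- base[, , , e] * exp(1i * offs[c_i]) * c_i
    multi_coil_echo_data(d, p)
  }
  a <- combine_coils(mk(c(0, 0)), 1)
  b <- combine_coils(mk(c(1.1, -2.3)), 1)
  expect_lt(max(abs(a$magnitude - b$magnitude)), 1e-10)
})

test_that("per-echo phase-encode shifts are recovered to subvoxel precision", {
  p <- mini_params()
  spec <- clean_spec(grid_n = 24, echo_pe_shift_voxels = c(0, 0, 0, 0, 0, 2))
  truth <- build_phantom(spec, p)
  sim <- simulate_acquisition(truth, spec, p)
  al <- align_echoes_first_to_rest(sim, 1)
  expect_equal(al$shifts_voxels[6], 2, tolerance = 0.1 / 2)
  expect_lt(max(abs(al$shifts_voxels[2:5])), 0.05)
})

test_that("the echo alignment honors the phase-encode constraint", {
  p <- mini_params()
  spec <- clean_spec(grid_n = 24)
  truth <- build_phantom(spec, p)
  sim <- simulate_acquisition(truth, spec, p)
  # shift echo 6 along the READOUT axis only
  sh <- numeric(3); sh[p$readout_axis] <- 1.5
  sim$data[, , , 6, 1, 1] <- pmqsm:::fourier_shift(sim$data[, , , 6, 1, 1], sh)
  al <- align_echoes_first_to_rest(sim, 1)
  expect_lt(abs(al$shifts_voxels[6]), 0.05)
})

test_that("translation estimation is antisymmetric", {
  p <- mini_params()
  spec <- clean_spec(grid_n = 24)
  truth <- build_phantom(spec, p)
  a <- truth$m0
  b <- pmqsm:::fourier_shift(a, c(0.7, -0.4, 0.2))
  ab <- pmqsm:::estimate_translation(a, b)
  ba <- pmqsm:::estimate_translation(b, a)
  expect_equal(ab, -ba, tolerance = 1e-2)
  expect_equal(ab, c(0.7, -0.4, 0.2), tolerance = 0.05)
})

test_that("repeat alignment recovers injected 3D translations", {
  p <- mini_params(n_repeats = 3)
  spec <- clean_spec(grid_n = 24, n_repeats = 3)
  truth <- build_phantom(spec, p)
  sim <- simulate_acquisition(truth, spec, p)
  series <- lapply(1:3, combine_coils, data = sim)
  shift2 <- c(0.5, -1.0, 0.25)
  shift3 <- c(0.25, -0.5, 0.1)   # smaller than repeat 2: settling drift
  shift_series <- function(s, t) {
    for (e in 1:6) s$magnitude[, , , e] <- pmax(
      pmqsm:::fourier_shift(s$magnitude[, , , e], t), 0)
    for (e in 1:5) s$phase[, , , e] <- Arg(
      pmqsm:::fourier_shift(exp(1i * s$phase[, , , e]), t))
    s
  }
  series[[2]] <- shift_series(series[[2]], shift2)
  series[[3]] <- shift_series(series[[3]], shift3)
  ar <- align_repeats(series)
  expect_equal(ar$shifts[1, ], c(0, 0, 0))
  expect_equal(ar$shifts[2, ], shift2, tolerance = 0.1)
  expect_equal(ar$shifts[3, ], shift3, tolerance = 0.1)
  # monotonically decreasing injected shifts come out decreasing
  expect_true(all(abs(ar$shifts[3, ]) <= abs(ar$shifts[2, ]) + 0.02))
  # identical repeats give zero shifts
  ar0 <- align_repeats(lapply(1:2, function(i) series[[1]]))
  expect_lt(max(abs(ar0$shifts)), 1e-6)
})
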