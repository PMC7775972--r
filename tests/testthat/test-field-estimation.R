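test_that("magnitude-threshold mask recovers a two-intensity phantom exactly", {
  shape <- c(20, 20, 20)
  brain <- ellipsoid_mask(shape, 1, c(7, 6, 5))
  mag <- array(1, shape)
  mag[brain] <- 100
  m <- generate_mask(mag, 0.1)
  expect_identical(m$mask, brain)
  expect_identical(m$provenance, "initial")
  # threshold 0 keeps all nonzero voxels (here: everything, one component)
  mag0 <- array(0, shape)
  mag0[brain] <- 5
  m0 <- generate_mask(mag0, 0)
  expect_identical(m0$mask, brain)
  expect_error(generate_mask(mag, 1.1), "empty mask")
})

test_that("mask generation keeps the largest component and fills holes", {
  shape <- c(24, 24, 24)
  brain <- ellipsoid_mask(shape, 1, c(8, 7, 6))
  blob <- ellipsoid_mask(shape, 1, c(1.4, 1.4, 1.4), center = c(10, 10, 10))
  hole <- ellipsoid_mask(shape, 1, c(1.8, 1.8, 1.8))
  mag <- array(0.1, shape)
  mag[brain | blob] <- 100
  mag[hole] <- 0.1    # interior cavity (air bubble): should be filled
  m <- generate_mask(mag, 0.1)
  expect_identical(m$mask, brain)   # blob dropped, hole filled
})

test_that("unwrapping restores a smooth ramp modulo a global 2*pi multiple", {
  shape <- c(32, 8, 8)
  x <- array(seq(0, 6 * pi, length.out = 32), dim = shape)
  wrapped <- pmqsm:::wrap_phase(x)
  mask <- array(TRUE, shape)
  u <- unwrap_phase_3d(wrapped, mask)
  # voxel-wise multiple of 2*pi from the wrapped input
  expect_lt(max(abs(pmqsm:::wrap_phase(u - wrapped))), 1e-10)
  # equals the ramp up to one global 2*pi*k
  off <- u - x
  expect_lt(diff(range(off)), 1e-10)
  expect_equal(off[1] / (2 * pi), round(off[1] / (2 * pi)), tolerance = 1e-10)
})

test_that("phase already free of wraps is returned unchanged", {
  set.seed(5)
  shape <- c(10, 10, 10)
  sm <- array(cumsum(rnorm(prod(shape), sd = 1e-3)), shape) # tiny smooth
  ph <- pmqsm:::wrap_phase(sm + 0.3)
  u <- unwrap_phase_3d(ph, array(TRUE, shape))
  expect_lt(max(abs(u - ph)), 1e-12)
})

test_that("disconnected regions unwrap independently and consistently", {
  shape <- c(40, 10, 10)
  mask <- array(FALSE, shape)
  mask[2:15, 2:9, 2:9] <- TRUE
  mask[25:39, 2:9, 2:9] <- TRUE
  x <- array(seq(0, 8 * pi, length.out = 40), dim = shape)
  u <- unwrap_phase_3d(pmqsm:::wrap_phase(x), mask)
  for (rng in list(2:15, 25:39)) {
    off <- (u - x)[rng, 2:9, 2:9]
    expect_lt(diff(range(off)), 1e-9)  # internally consistent
  }
})

test_that("two-echo initialization matches the analytic values", {
  p <- mini_params()
  shape <- c(8, 8, 8)
  mask <- array(TRUE, shape)
  # noiseless uniform 20 Hz: exact frequency, zero offset
  cs <- combine_coils(synth_echoes(array(20, shape), p), 1)
  init <- initialize_field_fit(cs, mask)
  expect_equal(max(abs(init$delta_f_hz - 20)), 0, tolerance = 1e-9)
  expect_lt(max(abs(init$phi0_rad)), 1e-9)
  # a 0.3 rad residual offset on all combined echoes lands in phi0
  cs$phase <- pmqsm:::wrap_phase(cs$phase + 0.3)
  init2 <- initialize_field_fit(cs, mask)
  expect_equal(max(abs(init2$delta_f_hz - 20)), 0, tolerance = 1e-9)
  expect_equal(mean(init2$phi0_rad), 0.3, tolerance = 1e-9)
})

test_that("initialization survives aliasing on a smooth 100 Hz blob", {
  p <- mini_params(voxel = 2)
  shape <- c(24, 24, 24)
  co <- pmqsm:::coord_grid(shape, rep(2, 3))
  blob <- 100 * exp(-(co$x^2 + co$y^2 + co$z^2) / (2 * 12^2))
  mask <- array(TRUE, shape)
  mc <- synth_echoes(blob, p)
  init <- initialize_field_fit(combine_coils(mc, 1), mask)
  # 100 Hz accrues 4.15 rad > pi per effective spacing: wrapped per-voxel,
  # but spatial unwrapping on the smooth blob recovers it
  expect_gt(max(blob), aliasing_threshold_hz())
  expect_lt(max(abs(init$delta_f_hz - blob)), 1e-6)
})

test_that("the vectorized field fit agrees with an independent LM oracle", {
  p <- mini_params()
  te <- effective_echo_times(p) / 1000
  set.seed(8)
  shape <- c(10, 1, 1)
  df <- array(runif(10, -60, 60), shape)
  phi0 <- array(runif(10, -1, 1), shape)
  mc <- synth_echoes(df, p, phi0 = phi0, noise_sd = 10, seed = 21)
  cs <- combine_coils(mc, 1)
  mask <- array(TRUE, shape)
  fit <- fit_field_nonlinear(cs, mask, list(delta_f_hz = df, phi0_rad = phi0))
  for (i in 1:10) {
    m <- cs$magnitude[i, 1, 1, 2:6]
    ph <- cs$phase[i, 1, 1, ]
    z <- complex(modulus = m, argument = ph)
    oracle <- minpack.lm::nls.lm(
      par = c(phi0[i], 2 * pi * df[i]),
      fn = function(q) {
        r <- z - m * exp(1i * (q[1] + q[2] * te))
        c(Re(r), Im(r))
      },
      control = minpack.lm::nls.lm.control(ftol = 1e-15, ptol = 1e-15))
    expect_equal(fit$delta_f_hz[i, 1, 1], oracle$par[2] / (2 * pi),
                 tolerance = 1e-6)
  }
})

test_that("noiseless multi-echo fit is exact, including beyond the aliasing limit", {
  p <- mini_params()
  shape <- c(12, 12, 12)
  df <- array(100, shape)   # beyond the 75.76 Hz per-spacing limit
  mc <- synth_echoes(df, p)
  cs <- combine_coils(mc, 1)
  mask <- array(TRUE, shape)
  fit <- fit_field_nonlinear(cs, mask,
                             list(delta_f_hz = df, phi0_rad = array(0, shape)))
  expect_lt(max(abs(fit$delta_f_hz - 100)), 1e-9)
  # a 10 Hz voxel from a zero init is also exact (inside the main basin;
  # the multi-echo cost has sidelobes ~1/TE'_max ~ 30 Hz apart, which is
  # exactly why the two-echo initialization exists)
  mc2 <- synth_echoes(array(10, shape), p)
  fit2 <- fit_field_nonlinear(combine_coils(mc2, 1), mask, init = NULL)
  expect_lt(max(abs(fit2$delta_f_hz - 10)), 1e-9)
})

test_that("field fit is unbiased at SNR 50 across 1000 voxels", {
  p <- mini_params()
  shape <- c(1000, 1, 1)
  df <- array(30, shape)
  mc <- synth_echoes(df, p, m0 = array(1000, shape),
                     r2s = array(0, shape), noise_sd = 20, seed = 77)
  cs <- combine_coils(mc, 1)
  mask <- array(TRUE, shape)
  fit <- fit_field_nonlinear(cs, mask, initialize_field_fit(cs, mask))
  expect_equal(mean(fit$delta_f_hz), 30, tolerance = 0.5 / 30)
})

test_that("two noiseless echoes reproduce the closed-form estimate exactly", {
  p <- acquisition_params(echo_times_ms = c(2, 8.6, 15.2))  # 2 effective
  shape <- c(6, 6, 6)
  set.seed(10)
  df <- array(runif(prod(shape), -40, 40), shape)
  mc <- synth_echoes(df, p)
  cs <- combine_coils(mc, 1)
  mask <- array(TRUE, shape)
  init <- initialize_field_fit(cs, mask)
  fit <- fit_field_nonlinear(cs, mask, init)
  expect_lt(max(abs(fit$delta_f_hz - init$delta_f_hz)), 1e-9)
})

test_that("a constant phase added to all echoes is absorbed into phi0", {
  p <- mini_params()
  shape <- c(8, 8, 8)
  df <- array(25, shape)
  mask <- array(TRUE, shape)
  f1 <- fit_field_nonlinear(combine_coils(synth_echoes(df, p), 1), mask, NULL)
  cs2 <- combine_coils(synth_echoes(df, p), 1)
  cs2$phase <- pmqsm:::wrap_phase(cs2$phase + 0.8)
  f2 <- fit_field_nonlinear(cs2, mask, NULL)
  expect_lt(max(abs(f1$delta_f_hz - f2$delta_f_hz)), 1e-8)
  expect_equal(max(abs(f2$phi0_rad - 0.8)), 0, tolerance = 1e-7)
})

test_that("phi0 mask refinement removes exactly the flagged voxels", {
  shape <- c(10, 10, 10)
  mask <- array(TRUE, shape)
  phi0 <- array(0, shape)
  bad <- sample(prod(shape), 5)
  phi0[bad] <- 2
  res <- structure(list(delta_f_hz = array(0, shape), phi0_rad = phi0,
                        rms_residual = array(0, shape), mask = mask,
                        converged = array(TRUE, shape), repeat_index = 1L),
                   class = "field_map_result")
  ref <- refine_mask_phi0(res, 1)
  expect_equal(attr(ref, "n_removed"), 5)
  expect_identical(which(!ref$mask), sort(bad))
  expect_identical(ref$provenance, "phi0-refined")
  # all-zero phi0: unchanged; threshold pi removes nothing (domain bound)
  res$phi0_rad <- array(0, shape)
  expect_equal(attr(refine_mask_phi0(res, 1), "n_removed"), 0)
  res$phi0_rad <- phi0
  expect_equal(attr(refine_mask_phi0(res, pi), "n_removed"), 0)
  expect_error(refine_mask_phi0(res, 0), "positive")
})

test_that("readout phase gradients are estimated and removed per echo", {
  p <- mini_params()
  shape <- c(32, 16, 16)
  mask <- array(TRUE, shape)
  df <- array(10, shape)
  mc <- synth_echoes(df, p)
  cs0 <- combine_coils(mc, 1)
  ro <- slice.index(array(0, shape), p$readout_axis)
  slope_of <- function(series, e) {
    d <- Arg(exp(1i * (series$phase[, , , e] -
                       (series$effective_te_ms[e] / series$effective_te_ms[1]) *
                       series$phase[, , , 1])))
    coef(lm(as.numeric(d) ~ as.numeric(ro)))[2]
  }
  # no injected gradient: series unchanged
  cs_id <- remove_readout_phase_gradient(cs0, mask, p)
  expect_lt(max(abs(cs_id$phase - cs0$phase)), 1e-9)
  # inject slope 0.01 rad/voxel on effective echoes 2..5, plus an
  # echo-index-proportional component (accumulating mistiming)
  cs1 <- cs0
  for (e in 2:5) {
    inj <- (0.01 + 0.002 * e) * (ro - mean(ro))
    cs1$phase[, , , e] <- pmqsm:::wrap_phase(cs1$phase[, , , e] + inj)
    expect_gt(abs(slope_of(cs1, e)), 0.009)
  }
  cs2 <- remove_readout_phase_gradient(cs1, mask, p)
  for (e in 2:5) expect_lt(abs(slope_of(cs2, e)), 1e-6)
})

test_that("repeat-field averaging reports the drift diagnostic", {
  shape <- c(8, 8, 8)
  set.seed(12)
  base <- array(rnorm(prod(shape), sd = 5), shape)
  mask <- array(TRUE, shape)
  mk <- function(off, extra = 0) {
    structure(list(delta_f_hz = base + off + extra,
                   phi0_rad = array(0, shape),
                   rms_residual = array(0, shape), mask = mask,
                   converged = array(TRUE, shape), repeat_index = 1L),
              class = "field_map_result")
  }
  res <- average_repeat_fields(lapply(c(0, 5, 8, 9), mk))
  expect_equal(res$delta_f_hz, base + 5.5, tolerance = 1e-12)
  expect_equal(res$drift$mean_delta_f_hz - mean(base), c(0, 5, 8, 9),
               tolerance = 1e-9)
  expect_equal(res$drift$increment_hz[-1], c(5, 3, 1), tolerance = 1e-9)
  expect_true(all(diff(res$drift$increment_hz[-1]) < 0))
  # single repeat: identity
  one <- average_repeat_fields(list(mk(0)))
  expect_equal(one$delta_f_hz, base, tolerance = 1e-12)
  # local corruption in one of four repeats is attenuated by 1/4
  corrupt <- array(0, shape); corrupt[3, 3, 3] <- 40
  res2 <- average_repeat_fields(list(mk(0), mk(0), mk(0), mk(0, corrupt)))
  expect_equal(res2$delta_f_hz[3, 3, 3] - base[3, 3, 3], 10, tolerance = 1e-9)
  expect_error(average_repeat_fields(list()), "empty")
})
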