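#' Truncate k-space along the slice axis to match resolutions
#'
#' Center-crops the raw k-space of every coil/echo/repeat volume along the
#' slice axis, keeping the central `ceiling(n/factor)` samples. This is the
#' standard trick for downsampling thin-slice acquisitions to the slice
#' thickness of the rest of a cohort (e.g. 208 slices at 0.55 mm -> 104 at
#' 1.1 mm with factor 2). Voxel size along the slice axis is multiplied by
#' the factor; energy outside the kept band is discarded. Values of
#' band-limited inputs are preserved.
#'
#' @param data a [multi_coil_echo_data()].
#' @param factor positive integer truncation factor (< slice count).
#' @return a [multi_coil_echo_data()] on the truncated grid.
#' @export
truncate_kspace_slice <- function(data, factor) {
  stopifnot(inherits(data, "multi_coil_echo_data"))
  factor <- as.integer(factor)
  ax <- data$params$slice_axis
  n <- data$grid_shape[ax]
  if (factor < 1) stop("factor must be >= 1")
  if (factor >= n) stop("factor must be smaller than the slice count")
  m <- as.integer(ceiling(n / factor))

  # Keep the m signed frequencies closest to DC; index them straight off the
  # unshifted spectrum so no fftshift bookkeeping is needed.
  ks_new <- fft_index(m)
  orig_pos <- (ks_new %% n) + 1L

  new_shape <- data$grid_shape
  new_shape[ax] <- m
  out <- array(0i, dim = c(new_shape, data$n_echoes, data$n_coils,
                           data$n_repeats))
  for (r in seq_len(data$n_repeats)) {
    for (c_i in seq_len(data$n_coils)) {
      for (e in seq_len(data$n_echoes)) {
        vol <- data$data[, , , e, c_i, r]
        spec <- fft_axis(vol, ax)
        idx <- list(seq_len(dim(spec)[1]), seq_len(dim(spec)[2]),
                    seq_len(dim(spec)[3]))
        idx[[ax]] <- orig_pos
        crop <- spec[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
        # A band-limited signal resampled onto the coarser grid satisfies
        # G_k = (m/n) F_k; mvfft's unnormalized inverse then needs 1/m,
        # so overall divide by n.
        out[, , , e, c_i, r] <- fft_axis(crop, ax, inverse = TRUE) / n
      }
    }
  }
  params <- data$params
  params$voxel_size_mm[ax] <- params$voxel_size_mm[ax] * factor
  multi_coil_echo_data(out, params)
}

#' Coil-combined magnitude and offset-free phase series
#'
#' Combines one repeat of multi-coil echo data into (i) sum-of-squares
#' magnitude images for all echoes and (ii) coil-combined phase images at the
#' effective echo times `TE_n - TE_1`. Per coil, the complex signal of the
#' first (short-TE) echo is conjugate-multiplied into every later echo, which
#' cancels the coil-specific, time-independent phase offset exactly; the
#' offset-corrected signals are then complex-summed over coils.
#'
#' When `echo_shifts` (from [align_echoes_first_to_rest()]) are supplied, the
#' first echo is resampled into each later echo's frame before subtraction,
#' so the later echoes - which feed all downstream stages - are never
#' interpolated.
#'
#' @param data a [multi_coil_echo_data()].
#' @param repeat_index which repeat to combine.
#' @param echo_shifts optional numeric vector (one per echo, first entry 0)
#'   of phase-encode-axis displacements of each echo relative to the first.
#' @param weighting `"weighted"` keeps the natural first-echo magnitude
#'   weights of the conjugate product (SNR-optimal complex sum);
#'   `"unweighted"` divides them out.
#' @return an object of class `combined_echo_series` with elements
#'   `magnitude` (x,y,z,echo), `phase` (x,y,z,effective echo, in (-pi, pi]),
#'   `effective_te_ms`, `flags` (voxels with zero first-echo signal in any
#'   coil), `repeat_index`, `params`.
#' @export
combine_coils <- function(data, repeat_index = 1L, echo_shifts = NULL,
                          weighting = c("weighted", "unweighted")) {
  stopifnot(inherits(data, "multi_coil_echo_data"))
  weighting <- match.arg(weighting)
  ne <- data$n_echoes
  if (ne < 2) stop("need at least two echoes for offset removal")
  shape <- data$grid_shape
  pe <- data$params$phase_encode_axis
  if (is.null(echo_shifts)) echo_shifts <- numeric(ne)

  magnitude <- array(0, dim = c(shape, ne))
  for (e in seq_len(ne)) {
    sos <- array(0, dim = shape)
    for (c_i in seq_len(data$n_coils))
      sos <- sos + Mod(data$data[, , , e, c_i, repeat_index])^2
    magnitude[, , , e] <- sqrt(sos)
  }

  flags <- array(FALSE, dim = shape)
  phase <- array(0, dim = c(shape, ne - 1))
  for (e in 2:ne) {
    comb <- array(0i, dim = shape)
    for (c_i in seq_len(data$n_coils)) {
      s1 <- data$data[, , , 1, c_i, repeat_index]
      if (echo_shifts[e] != 0) {
        sh <- numeric(3)
        sh[pe] <- echo_shifts[e]
        s1 <- fourier_shift(s1, sh)
      }
      sn <- data$data[, , , e, c_i, repeat_index]
      prod_ <- sn * Conj(s1)
      if (weighting == "unweighted") {
        a1 <- Mod(s1)
        zero <- a1 == 0
        flags <- flags | (zero & Mod(sn) > 0)
        a1[zero] <- 1
        prod_ <- prod_ / a1
      } else {
        flags <- flags | (Mod(s1) == 0 & Mod(sn) > 0)
      }
      comb <- comb + prod_
    }
    phase[, , , e - 1] <- Arg(comb)
  }

  structure(list(
    magnitude = magnitude,
    phase = phase,
    effective_te_ms = effective_echo_times(data$params),
    echo_times_ms = data$params$echo_times_ms,
    flags = flags,
    repeat_index = as.integer(repeat_index),
    params = data$params
  ), class = "combined_echo_series")
}

# Cross-correlation translation estimate between two real volumes.
# Returns the displacement t of `mov` relative to `ref`, i.e. the shift to
# apply to `ref` (via fourier_shift) to land in `mov`'s frame; equivalently
# mov(x) ~ ref(x - t). `axis` restricts the search to lags along one axis.
# Subvoxel precision: the integer correlation peak is refined by maximizing
# the continuous cross-correlation (evaluated at arbitrary lags through the
# Fourier shift theorem) with coordinate-wise golden-section search.
estimate_translation <- function(ref, mov, axis = NULL) {
  a <- mov - mean(mov)
  b <- ref - mean(ref)
  if (sqrt(mean(a^2)) < 1e-12 * max(1, mean(Mod(mov))) ||
      sqrt(mean(b^2)) < 1e-12 * max(1, mean(Mod(ref)))) {
    warning("featureless image(s): translation set to 0")
    return(if (is.null(axis)) c(0, 0, 0) else 0)
  }
  Cs <- fft_nd(a) * Conj(fft_nd(b))
  cc <- Re(ifft_nd(Cs))
  d <- dim(cc)
  kk <- k_grid(d, c(1, 1, 1))
  # continuous cross-correlation at an arbitrary (fractional) lag
  cc_at <- function(t) {
    Re(sum(Cs * exp(2i * pi * (kk$kx * t[1] + kk$ky * t[2] + kk$kz * t[3])))) /
      length(Cs)
  }
  refine_axis <- function(t0, ax) {
    f <- function(s) {
      t <- t0
      t[ax] <- s
      cc_at(t)
    }
    opt <- stats::optimize(f, lower = t0[ax] - 1, upper = t0[ax] + 1,
                           maximum = TRUE, tol = 1e-4)
    opt$maximum
  }
  if (!is.null(axis)) {
    idx <- list(1L, 1L, 1L)
    idx[[axis]] <- seq_len(d[axis])
    prof <- as.numeric(cc[idx[[1]], idx[[2]], idx[[3]]])
    p <- which.max(prof)
    t0 <- numeric(3)
    t0[axis] <- fft_index(d[axis])[p]
    return(refine_axis(t0, axis))
  }
  p <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  t0 <- vapply(1:3, function(ax) fft_index(d[ax])[p[ax]], 0)
  for (sweep in 1:2)
    for (ax in 1:3) t0[ax] <- refine_axis(t0, ax)
  t0
}

#' Estimate per-echo phase-encode translations of the first echo
#'
#' B0 drift during a repeat translates later echoes along the phase-encode
#' axis. The shift of each later echo relative to the first is estimated by
#' cross-correlation of sum-of-squares magnitudes (subvoxel via parabolic
#' peak interpolation), constrained to the phase-encode axis. The returned
#' shifts are what [combine_coils()] uses to resample the *first* echo into
#' each later echo's frame; later echoes are never interpolated.
#'
#' @param data a [multi_coil_echo_data()].
#' @param repeat_index which repeat to analyse.
#' @return list with `shifts_voxels` (one per echo; first entry 0) and
#'   `axis` (the phase-encode axis index).
#' @export
align_echoes_first_to_rest <- function(data, repeat_index = 1L) {
  stopifnot(inherits(data, "multi_coil_echo_data"))
  pe <- data$params$phase_encode_axis
  shape <- data$grid_shape
  sos <- function(e) {
    acc <- array(0, dim = shape)
    for (c_i in seq_len(data$n_coils))
      acc <- acc + Mod(data$data[, , , e, c_i, repeat_index])^2
    sqrt(acc)
  }
  m1 <- sos(1)
  shifts <- numeric(data$n_echoes)
  for (e in 2:data$n_echoes)
    shifts[e] <- estimate_translation(m1, sos(e), axis = pe)
  list(shifts_voxels = shifts, axis = pe)
}

#' Align combined repeats by translation to a common reference
#'
#' Registers every repeat's combined series to the second echo of repeat 1
#' by a rigid translation (all three axes), estimated by cross-correlation
#' of magnitudes with parabolic subvoxel refinement and applied by Fourier
#' phase ramps. Phase volumes are shifted through their complex exponential
#' to avoid wrap artefacts.
#'
#' @param series_list list of [combine_coils()] results, one per repeat.
#' @return list with `shifts` (n_repeats x 3 matrix, voxels) and `aligned`
#'   (list of aligned `combined_echo_series`).
#' @export
align_repeats <- function(series_list) {
  stopifnot(length(series_list) >= 1)
  ref <- series_list[[1]]$magnitude[, , , 2]
  n_rep <- length(series_list)
  shifts <- matrix(0, nrow = n_rep, ncol = 3)
  aligned <- series_list
  if (n_rep == 1) return(list(shifts = shifts, aligned = aligned))
  for (r in 2:n_rep) {
    mov <- series_list[[r]]$magnitude[, , , 2]
    t_r <- estimate_translation(ref, mov, axis = NULL)
    shifts[r, ] <- t_r
    s <- series_list[[r]]
    for (e in seq_len(dim(s$magnitude)[4]))
      s$magnitude[, , , e] <- pmax(fourier_shift(s$magnitude[, , , e], -t_r), 0)
    for (e in seq_len(dim(s$phase)[4]))
      s$phase[, , , e] <- Arg(fourier_shift(exp(1i * s$phase[, , , e]), -t_r))
    aligned[[r]] <- s
  }
  list(shifts = shifts, aligned = aligned)
}
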