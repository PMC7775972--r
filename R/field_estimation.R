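#' Generate a brain mask from the first-echo magnitude
#'
#' Thresholds the magnitude at `threshold_frac` of its robust maximum (the
#' 99th percentile), keeps the largest 6-connected component, and fills
#' interior holes.
#'
#' @param first_echo_magnitude non-negative magnitude volume.
#' @param threshold_frac fraction of the robust maximum (default 0.1).
#' @return an object of class `brain_mask`: list with logical `mask` and
#'   `provenance = "initial"`.
#' @export
generate_mask <- function(first_echo_magnitude, threshold_frac = 0.1) {
  stopifnot(all(first_echo_magnitude >= 0))
  robust_max <- as.numeric(quantile(first_echo_magnitude, 0.99))
  thr <- threshold_frac * robust_max
  mask <- first_echo_magnitude > thr
  if (!any(mask))
    stop(sprintf("empty mask: threshold %.4g (frac %.3g of robust max %.4g)",
                 thr, threshold_frac, robust_max))
  lab <- .cc_label_3d(mask, dim(mask))
  counts <- tabulate(lab)
  keep <- which.max(counts)
  mask <- lab == keep
  mask <- fill_holes_3d(mask)
  structure(list(mask = mask, provenance = "initial"), class = "brain_mask")
}

# Fill interior background cavities: any background component that does not
# touch the array boundary is enclosed by the mask.
fill_holes_3d <- function(mask) {
  d <- dim(mask)
  lab <- .cc_label_3d(!mask, d)
  nl <- max(lab)
  if (nl == 0) return(mask)
  touches <- logical(nl)
  border <- unique(c(
    lab[c(1, d[1]), , ], lab[, c(1, d[2]), ], lab[, , c(1, d[3])]
  ))
  touches[border[border > 0]] <- TRUE
  fill <- lab > 0 & !touches[pmax(lab, 1)]
  out <- mask | fill
  dim(out) <- d
  out
}

as_mask <- function(m) {
  if (inherits(m, "brain_mask")) m$mask else m
}

#' Spatial 3D phase unwrapping by quality-guided region growing
#'
#' Unwraps a wrapped phase volume within a mask. Each connected mask region
#' grows from its highest-quality voxel (quality = negative local wrapped
#' phase-gradient energy), unwrapping each admitted voxel against its
#' already-unwrapped neighbour. The contract is the modulo-2*pi property:
#' within each region, output - input is a voxel-wise integer multiple of
#' 2*pi, and the output is smooth where the underlying phase is smooth. The
#' 2*pi*k offset between disconnected regions is unconstrained.
#'
#' @param wrapped phase volume in (-pi, pi].
#' @param mask logical volume or `brain_mask`.
#' @return unwrapped phase volume (unchanged outside the mask).
#' @export
unwrap_phase_3d <- function(wrapped, mask) {
  mask <- as_mask(mask)
  if (!any(mask)) stop("empty mask")
  q <- -phase_gradient_energy(wrapped)
  .unwrap_rg(wrapped, mask, q, dim(wrapped))
}

# Sum of squared wrapped central phase differences along the three axes;
# large values mark noisy or discontinuous phase.
phase_gradient_energy <- function(ph) {
  d <- dim(ph)
  acc <- array(0, dim = d)
  for (ax in 1:3) {
    if (d[ax] < 2) next
    ip <- iq <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
    ip[[ax]] <- c(2:d[ax], d[ax])      # forward neighbour (clamped)
    iq[[ax]] <- c(1, 1:(d[ax] - 1))    # backward neighbour (clamped)
    fwd <- wrap_phase(ph[ip[[1]], ip[[2]], ip[[3]]] - ph)
    bwd <- wrap_phase(ph - ph[iq[[1]], iq[[2]], iq[[3]]])
    acc <- acc + fwd^2 + bwd^2
  }
  acc
}

#' Initialize the field fit from the first two effective echoes
#'
#' Builds starting values for the nonlinear field fit: the wrapped phase
#' difference between the first two effective echoes is spatially unwrapped
#' and scaled to a frequency estimate, and the (unwrapped) first effective
#' echo supplies the residual offset. Because the early-echo phase contains
#' few wraps, this initialization keeps the subsequent fit on the correct
#' branch even where the per-spacing aliasing limit is exceeded.
#'
#' @param series a [combine_coils()] result.
#' @param mask logical volume or `brain_mask`.
#' @return list with `delta_f_hz` and `phi0_rad` volumes.
#' @export
initialize_field_fit <- function(series, mask) {
  mask <- as_mask(mask)
  te <- series$effective_te_ms / 1000
  if (length(te) < 2) stop("need at least two effective echoes")
  shape <- dim(series$phase)[1:3]
  ph1 <- array(series$phase[, , , 1], dim = shape)
  ph2 <- array(series$phase[, , , 2], dim = shape)
  dphi <- Arg(exp(1i * ph2) / exp(1i * ph1))
  dphi_u <- unwrap_phase_3d(dphi, mask)
  delta_f <- dphi_u / (2 * pi * (te[2] - te[1]))
  ph1_u <- unwrap_phase_3d(ph1, mask)
  phi0 <- ph1_u - 2 * pi * delta_f * te[1]
  delta_f[!mask] <- 0
  phi0[!mask] <- 0
  list(delta_f_hz = delta_f, phi0_rad = phi0)
}

#' Voxel-wise nonlinear complex field fit
#'
#' Estimates the frequency offset and residual phase offset per voxel by
#' minimizing the squared complex residual
#' `|| S(TE') - |S(TE')| * exp(i(phi0 + 2*pi*df*TE')) ||^2`
#' over the effective echoes, with the magnitude taken from the data. The
#' solver is a Levenberg-Marquardt iteration vectorized across voxels (the
#' 2x2 normal equations are solved for all masked voxels simultaneously).
#' Voxels that do not converge are retained with their initialization values
#' and flagged; large residual phase offsets are the natural goodness-of-fit
#' diagnostic and feed [refine_mask_phi0()].
#'
#' @param series a [combine_coils()] result.
#' @param mask logical volume or `brain_mask`.
#' @param init list with `delta_f_hz`, `phi0_rad` (see
#'   [initialize_field_fit()]); `NULL` starts from zero.
#' @param max_iter maximum iterations (default 50).
#' @param tol convergence tolerance on the parameters (default 1e-10).
#' @return object of class `field_map_result`: `delta_f_hz`, `phi0_rad`
#'   (wrapped), `rms_residual`, `mask`, `converged`, `repeat_index`.
#' @export
fit_field_nonlinear <- function(series, mask, init = NULL, max_iter = 50,
                                tol = 1e-10) {
  maskv <- as_mask(mask)
  idx <- which(maskv)
  te <- series$effective_te_ms / 1000
  ne <- length(te)
  nv <- length(idx)
  M <- matrix(0, nv, ne)
  PH <- matrix(0, nv, ne)
  for (e in seq_len(ne)) {
    M[, e] <- series$magnitude[, , , e + 1][idx]
    PH[, e] <- series$phase[, , , e][idx]
  }
  Z <- M * exp(1i * PH)
  if (is.null(init)) {
    p1 <- numeric(nv)
    p2 <- numeric(nv)
  } else {
    p1 <- init$phi0_rad[idx]
    p2 <- 2 * pi * init$delta_f_hz[idx]
  }
  p1_init <- p1
  p2_init <- p2

  M2 <- M * M
  A11 <- rowSums(M2)
  A12 <- as.numeric(M2 %*% te)
  A22 <- as.numeric(M2 %*% te^2)
  ok <- A11 > 0  # voxels with any signal
  cost_of <- function(q1, q2) {
    TH <- outer(q2, te) + q1
    rowSums(Mod(Z - M * exp(1i * TH))^2)
  }
  cost <- cost_of(p1, p2)
  lambda <- rep(1e-3, nv)
  active <- ok
  for (it in seq_len(max_iter)) {
    if (!any(active)) break
    TH <- outer(p2, te) + p1
    E <- exp(1i * TH)
    W <- Im(Conj(E) * (Z - M * E)) * M
    g1 <- rowSums(W)
    g2 <- as.numeric(W %*% te)
    a <- A11 * (1 + lambda)
    dd <- A22 * (1 + lambda)
    det <- a * dd - A12^2
    det[det == 0] <- .Machine$double.eps
    d1 <- (dd * g1 - A12 * g2) / det
    d2 <- (a * g2 - A12 * g1) / det
    t1 <- p1 + ifelse(active, d1, 0)
    t2 <- p2 + ifelse(active, d2, 0)
    new_cost <- cost_of(t1, t2)
    accept <- active & (new_cost <= cost)
    p1[accept] <- t1[accept]
    p2[accept] <- t2[accept]
    cost[accept] <- new_cost[accept]
    lambda[accept] <- pmax(lambda[accept] / 3, 1e-12)
    rej <- active & !accept
    lambda[rej] <- pmin(lambda[rej] * 4, 1e10)
    done <- accept & abs(d1) < tol * (1 + abs(p1)) &
      abs(d2) < tol * (1 + abs(p2))
    active <- active & !done
  }
  converged_v <- ok & !active
  # non-convergent voxels keep their initialization
  p1[!converged_v] <- p1_init[!converged_v]
  p2[!converged_v] <- p2_init[!converged_v]
  cost[!converged_v] <- cost_of(p1, p2)[!converged_v]

  shape <- dim(series$magnitude)[1:3]
  delta_f <- array(0, dim = shape)
  phi0 <- array(0, dim = shape)
  rmsres <- array(0, dim = shape)
  convmap <- array(TRUE, dim = shape)
  delta_f[idx] <- p2 / (2 * pi)
  phi0[idx] <- wrap_phase(p1)
  rmsres[idx] <- sqrt(cost / ne)
  convmap[idx] <- converged_v
  structure(list(delta_f_hz = delta_f, phi0_rad = phi0,
                 rms_residual = rmsres, mask = maskv,
                 converged = convmap,
                 repeat_index = series$repeat_index),
            class = "field_map_result")
}

#' Refine the brain mask using the fitted residual phase offset
#'
#' Large focal residual offsets mark voxels with unreliable phase (vessels,
#' air bubbles, non-convergent fits); they are removed from the mask before
#' background field removal.
#'
#' @param result a [fit_field_nonlinear()] result.
#' @param phi0_abs_threshold_rad removal threshold (default 1.0 rad).
#' @return a `brain_mask` with provenance `"phi0-refined"` and attribute
#'   `n_removed`.
#' @export
refine_mask_phi0 <- function(result, phi0_abs_threshold_rad = 1.0) {
  if (phi0_abs_threshold_rad <= 0) stop("threshold must be positive")
  old <- result$mask
  keep <- old & abs(result$phi0_rad) <= phi0_abs_threshold_rad
  out <- structure(list(mask = keep, provenance = "phi0-refined"),
                   class = "brain_mask")
  attr(out, "n_removed") <- sum(old) - sum(keep)
  out
}

#' Remove the linear readout-direction phase gradient
#'
#' Echo-dependent phase gradients along the readout axis (eddy currents or
#' accumulating readout mistiming) masquerade as field gradients. For each
#' later effective echo, the increment of its phase over the linear
#' prediction from the first effective echo is reduced to per-readout-slab
#' circular means within the mask, a straight line is fitted along the
#' readout coordinate, and the fitted *slope* is subtracted from that echo's
#' phase (the intercept is left untouched so the global frequency content is
#' preserved).
#'
#' @param series a [combine_coils()] result.
#' @param mask logical volume or `brain_mask`.
#' @param params acquisition parameters (readout axis); defaults to the
#'   series' own.
#' @return the corrected `combined_echo_series`, with the fitted slopes
#'   (rad/voxel, one per effective echo) in attribute `slopes`.
#' @export
remove_readout_phase_gradient <- function(series, mask, params = series$params) {
  maskv <- as_mask(mask)
  ro <- params$readout_axis
  te <- series$effective_te_ms
  ne <- length(te)
  ratios <- te / te[1]
  int_ratios <- round(ratios)
  if (max(abs(ratios - int_ratios)) > 1e-6) {
    warning("effective echo times are not integer multiples of the first; ",
            "using per-echo TE' ratios for the linear prediction")
  }
  d <- dim(series$magnitude)[1:3]
  nro <- d[ro]
  xcoord_1d <- seq_len(nro)
  # per-slab index along the readout axis for every voxel
  slab <- slice.index(array(0, dim = d), ro)
  ph1 <- array(series$phase[, , , 1], dim = d)
  slopes <- numeric(ne)
  f_slab <- factor(slab[maskv], levels = seq_len(nro))
  w_all <- as.numeric(table(f_slab))
  for (e in 2:ne) {
    diffmap <- Arg(exp(1i * (series$phase[, , , e] - ratios[e] * ph1)))
    dv <- diffmap[maskv]
    zr <- tapply(cos(dv), f_slab, sum)
    zi <- tapply(sin(dv), f_slab, sum)
    keep <- w_all > 0
    xs <- which(keep)
    w <- w_all[keep]
    m <- atan2(zi[keep], zr[keep])
    # unwrap the 1D slab profile before the linear fit
    for (j in seq_along(m)[-1])
      m[j] <- m[j - 1] + wrap_phase(m[j] - m[j - 1])
    wbar <- sum(w * xs) / sum(w)
    b <- sum(w * (xs - wbar) * (m - sum(w * m) / sum(w))) /
      sum(w * (xs - wbar)^2)
    slopes[e] <- b
    ramp_1d <- b * (xcoord_1d - wbar)
    ramp <- array(ramp_1d[slab], dim = d)
    series$phase[, , , e] <- wrap_phase(series$phase[, , , e] - ramp)
  }
  attr(series, "slopes") <- slopes
  series
}

#' Average per-repeat field maps and report the drift diagnostic
#'
#' Voxel-wise mean of the per-repeat frequency-offset maps over the
#' intersection of the repeat masks. Estimating the field per repeat and
#' averaging the maps (rather than averaging phase data) is robust to B0
#' drift between repeats and to localized field changes in single repeats:
#' a corruption confined to one of R repeats is attenuated by 1/R. The
#' per-repeat whole-brain mean frequency offsets and their increments are
#' returned as the drift diagnostic.
#'
#' @param results list of [fit_field_nonlinear()] results on a common grid.
#' @return a `field_map_result` with `repeat_index = "averaged"` and a
#'   `drift` element: data frame with columns `repeat_index`,
#'   `mean_delta_f_hz`, `increment_hz`.
#' @export
average_repeat_fields <- function(results) {
  if (length(results) == 0) stop("empty list of field maps")
  masks <- lapply(results, function(r) as_mask(r$mask))
  common <- Reduce(`&`, masks)
  acc <- array(0, dim = dim(results[[1]]$delta_f_hz))
  accphi <- array(0i, dim = dim(acc))
  accres <- array(0, dim = dim(acc))
  means <- numeric(length(results))
  for (i in seq_along(results)) {
    acc <- acc + results[[i]]$delta_f_hz
    accphi <- accphi + exp(1i * results[[i]]$phi0_rad)
    accres <- accres + results[[i]]$rms_residual
    means[i] <- mean(results[[i]]$delta_f_hz[common])
  }
  n <- length(results)
  drift <- data.frame(repeat_index = seq_len(n),
                      mean_delta_f_hz = means,
                      increment_hz = c(NA, diff(means)))
  out <- structure(list(delta_f_hz = acc / n,
                        phi0_rad = Arg(accphi),
                        rms_residual = accres / n,
                        mask = common,
                        converged = Reduce(`&`, lapply(results, `[[`, "converged")),
                        repeat_index = "averaged",
                        drift = drift),
                   class = "field_map_result")
  out$delta_f_hz[!common] <- 0
  out
}
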