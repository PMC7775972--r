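#' Scaled-MAD outlier filter
#'
#' Outliers are values more than `k` scaled median absolute deviations from
#' the median, with scaled MAD = 1.4826 * median(|x - median(x)|) (the
#' normal-consistency convention). When the scaled MAD is zero (all values
#' equal), nothing is excluded.
#'
#' @param values numeric vector.
#' @param k threshold in scaled-MAD units (default 3).
#' @return list with `kept` (values retained) and `outlier_idx` (indices of
#'   excluded values).
#' @export
#' @examples
#' mad_outlier_filter(c(1, 2, 3, 100))$kept  # 1 2 3
mad_outlier_filter <- function(values, k = 3) {
  if (length(values) == 0) stop("empty input")
  med <- median(values)
  smad <- 1.4826 * median(abs(values - med))
  if (smad == 0) return(list(kept = values, outlier_idx = integer(0)))
  out <- which(abs(values - med) > k * smad)
  list(kept = if (length(out)) values[-out] else values, outlier_idx = out)
}

#' ROI mean after robust outlier rejection
#'
#' Applies [mad_outlier_filter()] to the map values inside the ROI (dropping
#' e.g. residual air-bubble voxels) and returns the mean of the surviving
#' voxels with bookkeeping counts. More than half the ROI being rejected is
#' flagged with a warning (a sign that the ROI placement or the map is
#' suspect).
#'
#' @param map volume (e.g. chi in ppb or R2* in 1/s).
#' @param roi logical volume, `brain_mask`, or [roi_definition()].
#' @param k scaled-MAD threshold (default 3).
#' @return list with `mean`, `n_voxels`, `n_outliers`.
#' @export
roi_summary <- function(map, roi, k = 3) {
  roiv <- if (inherits(roi, "roi_definition")) roi$mask else as_mask(roi)
  vals <- map[roiv]
  if (length(vals) == 0) stop("empty ROI")
  flt <- mad_outlier_filter(vals, k)
  if (length(flt$kept) == 0)
    stop("ROI rejected entirely by the outlier filter (n = ", length(vals), ")")
  if (length(flt$outlier_idx) > length(vals) / 2)
    warning("outlier filter removed more than half of the ROI (",
            length(flt$outlier_idx), "/", length(vals), ")")
  list(mean = mean(flt$kept), n_voxels = length(vals),
       n_outliers = length(flt$outlier_idx))
}

#' ROI definition
#'
#' @param label region label (e.g. "M1-hand", "ACC", "V2").
#' @param mask logical volume.
#' @param hemisphere "L", "R" or "both".
#' @return object of class `roi_definition`.
#' @export
roi_definition <- function(label, mask, hemisphere = "both") {
  if (!any(mask)) stop("empty ROI mask")
  structure(list(label = label, mask = mask, hemisphere = hemisphere),
            class = "roi_definition")
}

#' Standardize stained-area fractions within staining batches
#'
#' Immunohistochemistry batches differ systematically in staining intensity;
#' stained-area fractions (SAF) are therefore standardized within each batch
#' (demean, then divide by the standard deviation) before batches are
#' combined. Standardized SAFs have zero mean per batch and may be negative.
#'
#' @param records data frame with at least columns `saf` and the batch
#'   column.
#' @param by name of the batch column (default "batch").
#' @param sd_type `"sample"` (n-1 denominator, default) or `"population"`.
#' @return the data frame with an added `saf_std` column.
#' @export
standardize_saf <- function(records, by = "batch",
                            sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  stopifnot(is.data.frame(records), "saf" %in% names(records),
            by %in% names(records))
  if (any(records$saf < 0 | records$saf > 1))
    stop("raw SAF values must lie in [0, 1]")
  records$saf_std <- NA_real_
  for (b in unique(records[[by]])) {
    sel <- records[[by]] == b
    x <- records$saf[sel]
    if (length(x) < 2) stop("batch '", b, "' has fewer than 2 records")
    s <- sd(x)
    if (sd_type == "population") s <- s * sqrt((length(x) - 1) / length(x))
    if (s == 0) stop("batch '", b, "' has zero within-batch variance")
    records$saf_std[sel] <- (x - mean(x)) / s
  }
  records
}

#' Pearson and first-order partial correlation
#'
#' Pearson correlation with a two-tailed p-value; when a covariate is given,
#' additionally the partial correlation computed by regressing the covariate
#' out of both variables (ordinary least squares) and correlating the
#' residuals, with the p-value on n - 3 degrees of freedom. The double
#' residualization equals the closed-form first-order partial-correlation
#' formula.
#'
#' @param x,y numeric vectors (n >= 3).
#' @param covariate optional numeric vector (n >= 4 required).
#' @return list with `r`, `p`, `n`, and, when a covariate is supplied,
#'   `partial_r`, `partial_p`.
#' @export
correlation_suite <- function(x, y, covariate = NULL) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 3)
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance in x or y")
  ct <- stats::cor.test(x, y)
  out <- list(r = unname(ct$estimate), p = ct$p.value, n = n)
  if (!is.null(covariate)) {
    stopifnot(length(covariate) == n, n >= 4)
    if (sd(covariate) == 0) stop("zero variance in covariate")
    rx <- resid(lm(x ~ covariate))
    ry <- resid(lm(y ~ covariate))
    pr <- cor(rx, ry)
    tstat <- pr * sqrt((n - 3) / (1 - pr^2))
    out$partial_r <- pr
    out$partial_p <- 2 * pt(-abs(tstat), df = n - 3)
  }
  out
}

#' Welch's t-test with Hedges's g effect size
#'
#' Two-sample comparison with unequal variances (Satterthwaite degrees of
#' freedom) plus the small-sample-corrected standardized mean difference:
#' Hedges's g = Cohen's d (pooled-SD) * J, with J = 1 - 3/(4*nu - 1) and
#' nu = n_a + n_b - 2. Positive g means group A exceeds group B.
#'
#' @param group_a,group_b numeric vectors (n >= 2 each).
#' @return list with `t`, `df`, `p`, `cohen_d`, `hedges_g`.
#' @export
group_comparison <- function(group_a, group_b) {
  na <- length(group_a)
  nb <- length(group_b)
  stopifnot(na >= 2, nb >= 2)
  va <- var(group_a)
  vb <- var(group_b)
  if (va == 0 && vb == 0 && mean(group_a) == mean(group_b)) {
    return(list(t = NA_real_, df = NA_real_, p = NA_real_,
                cohen_d = 0, hedges_g = 0,
                note = "t undefined: zero variance in both groups"))
  }
  tt <- t.test(group_a, group_b, var.equal = FALSE)
  nu <- na + nb - 2
  sp <- sqrt(((na - 1) * va + (nb - 1) * vb) / nu)
  d <- (mean(group_a) - mean(group_b)) / sp
  j <- 1 - 3 / (4 * nu - 1)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       cohen_d = d, hedges_g = j * d)
}

#' Regress a covariate out of a measurement, preserving units
#'
#' Removes the ordinary-least-squares contribution of a covariate (e.g. the
#' fixative type as an indicator variable) and restores the grand mean, so
#' the residualized values stay on the original scale.
#'
#' @param values numeric vector.
#' @param covariate numeric, factor or logical covariate (must vary).
#' @return residualized values + grand mean.
#' @export
regress_out_covariate <- function(values, covariate) {
  if (length(unique(covariate)) < 2) stop("covariate is constant")
  fit <- lm(values ~ covariate)
  resid(fit) + mean(values)
}
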