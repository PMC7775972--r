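test_that("scaled-MAD filter matches the hand computation", {
  # [1,2,3,100]: median 2.5, MAD 1.0, scaled 1.4826, threshold 4.4478
  out <- mad_outlier_filter(c(1, 2, 3, 100), k = 3)
  expect_equal(out$kept, c(1, 2, 3))
  expect_equal(out$outlier_idx, 4L)
  # all equal: degenerate MAD excludes nothing
  eq <- mad_outlier_filter(rep(7, 10))
  expect_equal(length(eq$outlier_idx), 0)
  expect_error(mad_outlier_filter(numeric(0)), "empty")
})

test_that("the outlier filter is affine invariant", {
  set.seed(16)
  for (i in 1:5) {
    x <- c(rnorm(30), rnorm(3, mean = 15))
    a <- runif(1, 0.5, 4)
    b <- runif(1, -10, 10)
    expect_identical(mad_outlier_filter(x)$outlier_idx,
                     mad_outlier_filter(a * x + b)$outlier_idx)
  }
})

test_that("ROI summaries reject bubble voxels before averaging", {
  shape <- c(12, 12, 1)
  set.seed(30)
  map <- array(rnorm(prod(shape), mean = 20, sd = 0.5), shape)
  roi <- array(FALSE, shape)
  roi[1:103] <- TRUE
  map[101:103] <- 9400       # residual air-bubble values inside the ROI
  s <- roi_summary(map, roi)
  expect_equal(s$mean, 20, tolerance = 0.02)
  expect_equal(s$n_outliers, 3)
  expect_equal(s$n_voxels, 103)
  # homogeneous ROI
  h <- roi_summary(array(5, shape), roi)
  expect_equal(h$mean, 5)
  expect_equal(h$n_outliers, 0)
})

test_that("SAF standardization is per batch with the sample-SD convention", {
  rec <- data.frame(subject = 1:6, region = "M1", stain = "ferritin",
                    batch = rep(c("A", "B"), each = 3),
                    saf = c(0.1, 0.2, 0.3, 0.02, 0.04, 0.09))
  out <- standardize_saf(rec)
  expect_equal(out$saf_std[1:3], c(-1, 0, 1), tolerance = 1e-12)
  for (b in c("A", "B")) {
    expect_equal(mean(out$saf_std[out$batch == b]), 0, tolerance = 1e-12)
    expect_equal(sd(out$saf_std[out$batch == b]), 1, tolerance = 1e-12)
  }
  pop <- standardize_saf(rec, sd_type = "population")
  expect_equal(pop$saf_std[1:3], c(-1.2247, 0, 1.2247), tolerance = 1e-4)
  expect_error(standardize_saf(data.frame(batch = "A", saf = 0.1)), "fewer")
  expect_error(
    standardize_saf(data.frame(batch = c("A", "A"), saf = c(0.1, 0.1))),
    "variance")
})

test_that("partial correlation equals the first-order closed form", {
  x <- c(1, 2, 3, 4)
  y <- c(2, 1, 4, 3)
  z <- c(1, 1, 2, 2)
  out <- correlation_suite(x, y, covariate = z)
  expect_equal(out$r, 0.6, tolerance = 1e-12)
  # closed form: (r_xy - r_xz r_yz)/sqrt((1-r_xz^2)(1-r_yz^2)) = -1
  r_xy <- cor(x, y); r_xz <- cor(x, z); r_yz <- cor(y, z)
  closed <- (r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) * (1 - r_yz^2))
  expect_equal(out$partial_r, closed, tolerance = 1e-12)
  expect_equal(out$partial_r, -1, tolerance = 1e-12)
})

test_that("partial correlation reduces to plain r for orthogonal covariates", {
  set.seed(17)
  for (i in 1:5) {
    n <- 40
    z <- rnorm(n)
    x <- rnorm(n); x <- resid(lm(x ~ z))      # orthogonal to z
    y <- 0.5 * x + rnorm(n, sd = 0.3); y <- resid(lm(y ~ z))
    out <- correlation_suite(x, y, covariate = z)
    expect_equal(out$partial_r, out$r, tolerance = 1e-10)
  }
  expect_equal(correlation_suite(1:5, 2 * (1:5) + 1)$r, 1, tolerance = 1e-12)
  expect_error(correlation_suite(1:5, rep(1, 5)), "variance")
})

test_that("Welch t and Hedges's g match the textbook formulas", {
  a <- c(1, 2, 3, 4)
  b <- c(3, 4, 5, 6)
  out <- group_comparison(a, b)
  # independent formula computation
  se <- sqrt(var(a) / 4 + var(b) / 4)
  t_ref <- (mean(a) - mean(b)) / se
  df_ref <- (var(a) / 4 + var(b) / 4)^2 /
    ((var(a) / 4)^2 / 3 + (var(b) / 4)^2 / 3)
  p_ref <- 2 * pt(-abs(t_ref), df_ref)
  sp <- sqrt(((4 - 1) * var(a) + (4 - 1) * var(b)) / 6)
  g_ref <- (1 - 3 / (4 * 6 - 1)) * (mean(a) - mean(b)) / sp
  expect_equal(out$t, t_ref, tolerance = 1e-12)
  expect_equal(out$df, df_ref, tolerance = 1e-12)
  expect_equal(out$p, p_ref, tolerance = 1e-12)
  expect_equal(out$hedges_g, g_ref, tolerance = 1e-12)
  expect_lt(out$hedges_g, 0)   # group A below group B
  # identical groups: g = 0, p = 1
  eqg <- group_comparison(c(1, 2, 3), c(1, 2, 3))
  expect_equal(eqg$hedges_g, 0)
  expect_equal(eqg$p, 1)
  # degenerate zero-variance case reported as undefined
  und <- group_comparison(c(2, 2), c(2, 2))
  expect_true(is.na(und$t))
})

test_that("Welch t equals Student's t for equal n and equal variances", {
  set.seed(18)
  a <- rnorm(10)
  b <- rnorm(10)
  b <- (b - mean(b)) / sd(b) * sd(a) + mean(b)   # force equal variance
  w <- group_comparison(a, b)
  s <- t.test(a, b, var.equal = TRUE)
  expect_equal(w$t, unname(s$statistic), tolerance = 1e-10)
  expect_equal(w$df, unname(s$parameter), tolerance = 1e-10)
})

test_that("Hedges's g shrinks toward zero relative to Cohen's d", {
  set.seed(19)
  for (i in 1:10) {
    na <- sample(2:6, 1); nb <- sample(2:6, 1)
    a <- rnorm(na); b <- rnorm(nb, mean = 1)
    out <- group_comparison(a, b)
    expect_lte(abs(out$hedges_g), abs(out$cohen_d))
  }
})

test_that("covariate regression preserves units and removes group offsets", {
  set.seed(20)
  base <- rnorm(12, mean = 30, sd = 2)
  fix <- rep(c(0, 1), each = 6)
  vals <- base + 10 * fix
  res <- regress_out_covariate(vals, factor(fix))
  expect_equal(mean(res[fix == 0]), mean(res[fix == 1]), tolerance = 1e-10)
  expect_equal(mean(res), mean(vals), tolerance = 1e-12)
  # orthogonal covariate: values unchanged up to the mean
  zc <- rnorm(12); zc <- resid(lm(zc ~ vals))
  res2 <- regress_out_covariate(vals, zc)
  expect_equal(unname(res2 - mean(res2)), vals - mean(vals), tolerance = 1e-8)
  # collinear covariate: residuals collapse to the grand mean
  res3 <- regress_out_covariate(vals, 2 * vals + 3)
  expect_equal(unname(res3), rep(mean(vals), 12), tolerance = 1e-10)
  expect_error(regress_out_covariate(vals, rep(1, 12)), "constant")
})
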