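test_that("Shannon index matches closed forms and the brute-force oracle", {
  expect_equal(shannon(rep(1, 4)), log(4), tolerance = 1e-12)
  expect_equal(shannon(c(0, 5, 0)), 0)
  expect_equal(shannon(c(0.5, 0.25, 0.25)),
               -(0.5 * log(0.5) + 0.5 * log(0.25)), tolerance = 1e-12)
  expect_equal(round(shannon(c(0.5, 0.25, 0.25)), 4), 1.0397)
  expect_error(shannon(c(0, 0)), "all-zero")
  set.seed(101)
  for (i in 1:200) {
    x <- rpois(sample(2:12, 1), 5) + ifelse(runif(1) < 0.5, 0, 1)
    if (sum(x) == 0) x[1] <- 1
    expect_equal(shannon(x), shannon_brute(x), tolerance = 1e-12)
  }
})

test_that("Bray-Curtis matches hand arithmetic and the brute-force oracle", {
  expect_equal(bray_curtis(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(bray_curtis(c(1, 0, 2), c(0, 3, 0)), 1)
  expect_equal(bray_curtis(c(6, 2, 0), c(2, 2, 4)), 0.5)
  expect_error(bray_curtis(c(0, 0), c(0, 0)), "undefined")
  expect_error(bray_curtis(c(1, 2), c(1, 2, 3)), "registry")
  set.seed(102)
  for (i in 1:200) {
    n <- sample(2:10, 1)
    x <- runif(n, 0, 5); y <- runif(n, 0, 5)
    expect_equal(bray_curtis(x, y), bc_brute(x, y), tolerance = 1e-12)
    expect_equal(bray_curtis(x, y), bray_curtis(y, x))  # symmetry
    expect_true(bray_curtis(x, y) >= 0 && bray_curtis(x, y) <= 1)
  }
})

test_that("layer dissimilarity series handles identity, disjointness, gaps", {
  meta <- make_meta(t_surface = c(10, 20, 25), t_deep = c(9, 9, 9))
  v <- matrix(0, 2, 6, dimnames = list(
    c("a", "b"), meta$sample_id[order(meta$month_index, meta$layer)]))
  # month 0: identical layers; month 1: disjoint; month 2: deep missing
  v[, "m00_surface"] <- c(3, 1); v[, "m00_deep"] <- c(3, 1)
  v[, "m01_surface"] <- c(5, 0); v[, "m01_deep"] <- c(0, 2)
  v[, "m02_surface"] <- c(1, 1)
  ft <- feature_table(v[, colnames(v) != "m02_deep"], "counts")
  meta2 <- meta[meta$sample_id %in% colnames(ft$values), ]
  expect_warning(out <- layer_dissimilarity_series(ft, meta), "month_index 2")
  expect_equal(out$bc, c(0, 1))
  expect_error(layer_dissimilarity_series(
    feature_table(v[, c(1, 2), drop = FALSE], "counts"),
    meta[meta$month_index == 2, ]), "no month")
})

test_that("layer dissimilarity is lowest in the mixed window on lake data", {
  pl <- cached_pipeline(1)
  bc <- pl$layer_bc$asv
  expect_equal(nrow(bc), 16L)
  expect_true(bc$calendar_month[which.min(bc$bc)] %in% c(2, 3))
  expect_true(all(bc$bc >= 0 & bc$bc <= 1))
})

test_that("time-lag curve counts pairs correctly and flags degenerate sds", {
  meta <- make_meta(t_surface = c(10, 20), t_deep = c(9, 9))
  v <- matrix(c(3, 1, 5, 2), 2, 2,
              dimnames = list(c("a", "b"), c("m00_surface", "m01_surface")))
  lc <- timelag_curve(feature_table(v, "counts"), meta, "surface")
  expect_equal(nrow(lc), 1L)
  expect_equal(lc$lag_months, 1)
  expect_equal(lc$sd_bc, 0)
  expect_false(lc$sd_defined)
  expect_equal(lc$n_pairs, 1L)

  # constant community: all lags at zero dissimilarity
  n <- 6
  meta <- make_meta(t_surface = rep(15, n), t_deep = rep(9, n))
  vc <- matrix(rep(c(4, 1), n), 2, n,
               dimnames = list(c("a", "b"), sprintf("m%02d_surface", 0:(n - 1))))
  lc <- timelag_curve(feature_table(vc, "counts"), meta, "surface")
  expect_equal(lc$lag_months, 1:(n - 1))
  expect_equal(sum(lc$n_pairs), n * (n - 1) / 2)
  expect_equal(lc$mean_bc, rep(0, n - 1))
})

test_that("seasonal forcing brings month-12 pairs closer than month-6 pairs", {
  pl <- cached_pipeline(1)
  lag <- pl$lag$asv_surface
  expect_lt(lag$mean_bc[lag$lag_months == 12], lag$mean_bc[lag$lag_months == 6])
  expect_equal(sum(lag$n_pairs), 16 * 15 / 2)
})

test_that("lag-group comparison dispatches to a sensible test", {
  x <- c(0.2, 0.21, 0.22, 0.2, 0.21)
  expect_gt(compare_lag_groups(x, x + 1e-4)$p_value, 0.2)
  set.seed(6)
  a <- rnorm(30); b <- rnorm(30, mean = 3)
  expect_lt(compare_lag_groups(a, b)$p_value, 0.01)
  skewed_a <- exp(rnorm(40, 0, 2)); skewed_b <- exp(rnorm(40, 1, 2))
  expect_equal(compare_lag_groups(skewed_a, skewed_b)$test, "mann_whitney")
  expect_error(compare_lag_groups(1, c(1, 2)), "at least two")
})
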