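cfg <- chamber_preset("huvec")

make_curve <- function(x, y) {
  structure(tibble::tibble(bin_center = x, mean = y,
                           sem = 0, n = 10),
            kind = "orientation_deg",
            class = c("response_curve", "tbl_df", "tbl", "data.frame"))
}

test_that("binning a constant response gives flat means with zero SEM", {
  m <- tibble::tibble(shear_dyn_cm2 = rep(seq(3, 59, length.out = 8),
                                          each = 20),
                      orientation_deg = 27.5,
                      image = rep(1:8, each = 20))
  curve <- suppressMessages(bin_by_shear(m, config = cfg, n_bins = 8))
  expect_true(all(curve$mean == 27.5))
  expect_true(all(curve$sem == 0))
})

test_that("uniformly oriented populations bin to 45 degrees everywhere", {
  model <- response_model(angle_concentration = 0)
  set.seed(77)
  # ground-truth angles at 16 positions, 625 cells each (n = 10^4)
  positions <- seq(0, 7, length.out = 16)
  m <- dplyr::bind_rows(lapply(seq_along(positions), function(i) {
    tibble::tibble(
      x_cm = positions[i], image = i,
      orientation_deg = fold_angle(stats::runif(625, -90, 90)))
  }))
  curve <- suppressMessages(
    bin_by_shear(m, config = cfg, n_bins = 8, per_image = FALSE))
  expect_true(all(abs(curve$mean - 45) < 2))
})

test_that("a single occupied bin yields a curve of length one", {
  m <- tibble::tibble(shear_dyn_cm2 = rep(10, 5),
                      orientation_deg = c(30, 40, 50, 20, 35), image = 1)
  curve <- suppressMessages(bin_by_shear(m, config = cfg, n_bins = 15,
                                         per_image = FALSE))
  expect_identical(nrow(curve), 1L)
  expect_gt(curve$sem, 0)
  expect_error(bin_by_shear(m[0, ], config = cfg), "no finite")
})

test_that("LOWESS reproduces a line and resists an outlier", {
  x <- seq(2, 60, length.out = 12)
  lin <- make_curve(x, 3 + 0.5 * x)
  sm <- smooth_lowess(lin, frac = 0.5)
  expect_equal(sm$smoothed, lin$mean, tolerance = 1e-6)
  # one gross outlier over a jittered flat level: robustness iterations keep
  # the smooth at the flat level (at a half-span window the fit at the
  # outlier's own abscissa is degenerate and excluded from the check)
  set.seed(8)
  level <- 20 + rnorm(12, 0, 0.3)
  flat <- make_curve(x, replace(level, 6, 80))
  smf <- smooth_lowess(flat, frac = 0.5, iter = 3)
  expect_true(all(abs(smf$smoothed[-6] - 20) < 2))
  smw <- smooth_lowess(flat, frac = 0.8, iter = 3)
  expect_true(all(abs(smw$smoothed - 20) < 2))
  # without robustness the outlier drags the local fits far off the level
  sm0 <- smooth_lowess(flat, frac = 0.5, iter = 0)
  expect_gt(max(abs(sm0$smoothed - 20)), 5)
  expect_error(smooth_lowess(make_curve(x[1:3], x[1:3])), ">= 4 bins")
  expect_error(smooth_lowess(lin, frac = 0), "frac")
})

test_that("LOWESS at frac = 1 matches a brute-force tri-cube weighted fit", {
  x <- seq(1, 15, 1)
  set.seed(5)
  y <- 10 + 0.8 * x + rnorm(15, 0, 0.5)
  sm <- smooth_lowess(make_curve(x, y), frac = 1, iter = 0)
  oracle <- vapply(x, function(x0) tricube_fit_at(x, y, x0, frac = 1),
                   numeric(1))
  expect_equal(sm$smoothed, oracle, tolerance = 1e-6)
})

test_that("set-point estimation finds the optimum and criterion range", {
  x <- seq(2, 60, length.out = 15)
  # V-shaped orientation response with minimum at 15
  y <- 20 + 25 * pmin(1, abs(x - 15) / 20)
  sp <- estimate_set_point(smooth_lowess(make_curve(x, y), frac = 0.3))
  expect_lt(abs(sp$optimum_shear - 15), 4.2)  # one bin width
  expect_false(sp$at_boundary)
  expect_lte(sp$range_lo, sp$optimum_shear)
  expect_gte(sp$range_hi, sp$optimum_shear)
})

test_that("set-point estimate is invariant to affine response rescaling", {
  x <- seq(2, 60, length.out = 15)
  y <- 20 + 25 * pmin(1, abs(x - 18) / 15)
  a <- estimate_set_point(smooth_lowess(make_curve(x, y)))
  b <- estimate_set_point(smooth_lowess(make_curve(x, 3.2 * y + 11)))
  expect_identical(a$optimum_shear, b$optimum_shear)
  expect_identical(a$range_lo, b$range_lo)
  expect_identical(a$range_hi, b$range_hi)
})

test_that("monotone curves flag the optimum as a boundary", {
  x <- seq(2, 60, length.out = 10)
  sp <- estimate_set_point(smooth_lowess(make_curve(x, 10 + x)))
  expect_true(sp$at_boundary)
  expect_identical(sp$optimum_shear, x[1])
  # max-direction readout (Smad1-like)
  spx <- estimate_set_point(smooth_lowess(make_curve(x, 10 + x)),
                            direction = "max")
  expect_identical(spx$optimum_shear, x[10])
})

test_that("one-way ANOVA matches the hand-computed F statistic", {
  values <- c(1, 2, 3, 2, 3, 4, 3, 4, 5)
  groups <- rep(c("a", "b", "c"), each = 3)
  res <- anova_shear_effect(values, groups)
  expect_equal(res$F, 3, tolerance = 1e-12)
  expect_identical(res$df1, 2L)
  expect_identical(res$df2, 6L)
  expect_equal(res$p, stats::pf(3, 2, 6, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("ANOVA degenerate and monotone-shift behaviour", {
  # identical group means with residual variance: F ~ 0
  res <- anova_shear_effect(c(1, 3, 1, 3, 1, 3), rep(c("a", "b", "c"), 2))
  expect_lt(res$F, 1e-10)
  # growing separation monotonically grows F
  base <- c(1, 2, 3, 1, 2, 3)
  fs <- vapply(c(0.5, 1, 2, 4, 8), function(s) {
    anova_shear_effect(c(base[1:3], base[4:6] + s),
                       rep(c("a", "b"), each = 3))$F
  }, numeric(1))
  expect_true(all(diff(fs) > 0))
  # zero within-group variance: equal means -> undefined, unequal -> Inf
  res0 <- anova_shear_effect(c(3, 3, 3, 3), c("a", "a", "b", "b"))
  expect_true(res0$undefined)
  res_inf <- anova_shear_effect(c(1, 1, 2, 2), c("a", "a", "b", "b"))
  expect_false(res_inf$undefined)
  expect_identical(res_inf$F, Inf)
  expect_error(anova_shear_effect(1:5, rep("a", 5)), "groups")
})

test_that("no shear effect is declared under the uniform null at ~5%", {
  set.seed(2024)
  rejections <- 0L
  for (i in 1:200) {
    v <- fold_angle(runif(8 * 25, -90, 90))
    g <- rep(1:8, each = 25)
    if (anova_shear_effect(v, g)$p < 0.05) rejections <- rejections + 1L
  }
  expect_lte(rejections, 20L)  # <= 10% of 200 null simulations
})
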