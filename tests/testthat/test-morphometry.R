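test_that("moment orientation recovers the drawn ellipse angle", {
  # 8 x 5 um ellipse at 0.65 um/px: semi-axes 12.3 x 7.7 px
  for (case in list(c(0, 0.5), c(90, 0.5), c(30, 1), c(60, 1))) {
    mask <- ellipse_mask(128, 128, 64, 64, 12.3, 7.7, case[1])
    expect_lt(abs(orientation(mask) - case[1]), case[2],
              label = sprintf("orientation error at %g deg", case[1]))
  }
})

test_that("orientation tolerates translation and axial symmetry", {
  a <- orientation(ellipse_mask(128, 128, 40, 40, 12.3, 7.7, 30))
  b <- orientation(ellipse_mask(128, 128, 80, 70, 12.3, 7.7, 30))
  expect_equal(a, b, tolerance = 0.5 / 90)
  # a 180-degree rotation of the region leaves the axis unchanged
  d <- orientation(ellipse_mask(128, 128, 64, 64, 12.3, 7.7, 30 + 180))
  expect_equal(a, d, tolerance = 0.5 / 90)
  # negative angles fold onto the acute range
  e <- orientation(ellipse_mask(128, 128, 64, 64, 12.3, 7.7, -30))
  expect_equal(e, a, tolerance = 0.5 / 90)
})

test_that("degenerate regions yield a flagged orientation", {
  circle <- ellipse_mask(64, 64, 32, 32, 10, 10, 0)
  expect_true(is.na(orientation(circle)))
  tiny <- matrix(FALSE, 16, 16); tiny[8, 8:10] <- TRUE
  expect_true(is.na(orientation(tiny)))  # < 5 pixels
  # label-matrix interface
  lab <- matrix(0L, 64, 64); lab[ellipse_mask(64, 64, 32, 32, 14, 7, 0)] <- 3L
  expect_equal(orientation(lab, label = 3L), 0, tolerance = 0.5)
})

test_that("translocation factor hits its limits and midpoint exactly", {
  # entire signal in the nucleus -> TF = 1
  all_nuc <- make_cell_image(nuclear_signal = 5000, cyto_signal = 0)
  expect_identical(
    translocation_factor(all_nuc$nucleus, all_nuc$cell, all_nuc$ch2), 1)
  # entire signal in the cytoplasm -> TF = 0
  all_cyt <- make_cell_image(nuclear_signal = 0, cyto_signal = 5000)
  expect_identical(
    translocation_factor(all_cyt$nucleus, all_cyt$cell, all_cyt$ch2), 0)
  # split evenly -> TF = 0.5
  half <- make_cell_image(nuclear_signal = 2500, cyto_signal = 2500)
  expect_equal(translocation_factor(half$nucleus, half$cell, half$ch2), 0.5,
               tolerance = 0.01)
})

test_that("translocation factor handles background and degeneracy", {
  im <- make_cell_image(nuclear_signal = 3000, cyto_signal = 1000,
                        background = 50)
  tf_raw <- translocation_factor(im$nucleus, im$cell, im$ch2)
  tf_bg <- translocation_factor(im$nucleus, im$cell, im$ch2, background = 50)
  expect_equal(tf_bg, 0.75, tolerance = 1e-10)
  # a uniform offset dilutes the nuclear share (nucleus < half the cell area)
  expect_lt(tf_raw, tf_bg)
  # scale invariance with exactly scaled background
  tf_scaled <- translocation_factor(im$nucleus, im$cell, im$ch2 * 3,
                                    background = 150)
  expect_equal(tf_scaled, tf_bg, tolerance = 1e-12)
  # whole-cell sum <= 0 after subtraction -> undefined
  flat <- make_cell_image(nuclear_signal = 0, cyto_signal = 0,
                          background = 10)
  expect_true(is.na(
    translocation_factor(flat$nucleus, flat$cell, flat$ch2,
                         background = 10)))
  expect_error(translocation_factor(im$cell, im$nucleus, im$ch2),
               "contained")
})

test_that("measured TF increases monotonically with the generator fraction", {
  cfg <- chamber_preset("huvec")
  model <- response_model()
  fractions <- seq(0.05, 0.95, length.out = 10)
  measured <- vapply(seq_along(fractions), function(i) {
    sc <- sample_scene(cfg, model, 2, 12, seed = 100,
                       width_px = 256, height_px = 256)
    sc$cells$tf_true <- fractions[i]
    img <- render_scene(sc, seed = 200)
    masks <- derive_cell_regions(segment_nuclei(img))
    mean(measure_cells(masks, img)$tf, na.rm = TRUE)
  }, numeric(1))
  expect_equal(cor(fractions, measured, method = "spearman"), 1,
               tolerance = 1e-8)
})

test_that("background estimation finds the extracellular mode", {
  cells <- matrix(0L, 64, 64); cells[20:40, 20:40] <- 1L
  ch2 <- matrix(150, 64, 64); ch2[cells == 1L] <- 900
  ch2[1, 1:10] <- 152  # minor contamination
  expect_identical(estimate_background(ch2, cells), 150)
})

test_that("profile AUC matches hand and closed-form integrals", {
  # all-zero profile
  expect_identical(profile_auc(0:10, rep(0, 11))$auc, 0)
  # rectangular pulse of height H over width W, sampled on its edges
  d <- c(0, 2, 2.0001, 5, 5.0001, 8)
  y <- c(0, 0, 7, 7, 0, 0)
  expect_equal(profile_auc(d, y)$auc, 7 * 3, tolerance = 1e-3)
  # Gaussian pulse: integral A * sigma * sqrt(2*pi)
  x <- seq(-25, 25, by = 0.01)
  g <- 40 * exp(-x^2 / (2 * 5^2))
  res <- profile_auc(x, g)
  expect_equal(res$auc, 40 * 5 * sqrt(2 * pi), tolerance = 1e-3)
  expect_equal(res$auc_per_um, res$auc / 50, tolerance = 1e-12)
  # additivity over concatenation at a shared endpoint
  left <- profile_auc(x[x <= 0], g[x <= 0])$auc
  right <- profile_auc(x[x >= 0], g[x >= 0])$auc
  expect_equal(left + right, res$auc, tolerance = 1e-12)
  expect_error(profile_auc(c(0, 2, 1), c(1, 1, 1)), "increasing")
  expect_error(profile_auc(1, 1), "samples")
})

test_that("background subtraction clips negative intensities at zero", {
  res <- profile_auc(c(0, 1, 2), c(5, 1, 5), background = 3)
  # clipped trapezoid: y = (2, 0, 2)
  expect_equal(res$auc, 2, tolerance = 1e-12)
})

test_that("line profiles read from two-column CSV", {
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(distance_um = c(0, 1, 2), intensity = c(1, 2, 3)),
            path, row.names = FALSE)
  lp <- read_line_profile(path)
  expect_named(lp, c("distance_um", "intensity"))
  expect_identical(nrow(lp), 3L)
})
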