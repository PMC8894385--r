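test_that("segmentation finds every planted interior cell", {
  set.seed(101)
  shapes <- vsmcscreen:::sample_shapes(10, 10, phenotype_params())
  pos <- vsmcscreen:::place_cells(shapes$semi_major, 800)
  specs <- cbind(pos, shapes, body_intensity = 0.8, nucleus_scale = 0.45)
  well <- render_well(specs, image_size = 800, seed = 101)
  mask <- segment_cells(well$image)
  expect_equal(max(mask), 20L)
  expect_true(all(sort(unique(mask[mask > 0])) == 1:20))
})

test_that("a noise-only image yields zero labels with a warning", {
  set.seed(7)
  blank <- array(pmax(stats::rnorm(2 * 200^2, 0, 0.02), 0),
                 dim = c(200, 200, 2))
  expect_warning(mask <- segment_cells(blank))
  expect_equal(max(mask), 0L)
})

test_that("touching cells with distinct nuclei are split into two labels", {
  n <- 220
  nuc <- body <- matrix(0, n, n)
  # two ellipses whose bodies touch at x ~ 110
  body <- vsmcscreen:::draw_ellipse(body, 80, 110, 32, 22, 0, 0.8)
  body <- vsmcscreen:::draw_ellipse(body, 141, 110, 32, 22, 0, 0.8)
  nuc <- vsmcscreen:::draw_ellipse(nuc, 80, 110, 12, 9, 0, 1)
  nuc <- vsmcscreen:::draw_ellipse(nuc, 141, 110, 12, 9, 0, 1)
  img <- array(c(nuc, body), dim = c(n, n, 2))
  mask <- segment_cells(img)
  expect_equal(max(mask), 2L)
  # the split lies near the planted ridge between the two nuclei
  rec <- measure_shape(mask)
  expect_equal(nrow(rec), 2L)
  expect_lt(max(abs(rec$area - sum(body > 0) / 2)) / (sum(body > 0) / 2), 0.1)
})

test_that("channel mismatch is rejected", {
  expect_error(segment_cells(list(matrix(0, 10, 10), matrix(0, 12, 12))),
               "shapes differ")
  expect_error(segment_cells(array(0, dim = c(10, 10, 3))), "two-channel")
})

test_that("morphometrics recover circles, ellipses and the rectangle formula", {
  circ <- measure_shape(ellipse_mask(30, 30))
  expect_gte(circ$elongation_e, 1)
  expect_lte(circ$elongation_e, 1.05)
  expect_gte(circ$csi, 0.95)
  expect_lte(circ$csi, 1)

  ell <- measure_shape(ellipse_mask(25, 5))
  expect_lt(abs(ell$elongation_e - 5) / 5, 0.05)

  # CSI closed form with the perimeter fixed at 100 for a 40 x 10 rectangle
  expect_equal(shape_index(40 * 10, 100), 4 * pi * 400 / 100^2)
})

test_that("elongation is invariant to rotation and translation", {
  base <- render_one_and_measure(48, 8, 0)$elongation_e
  for (case in list(c(0.7, 0, 0), c(1.9, 0, 0), c(0.7, 0.3, -0.4),
                    c(pi / 2, 0, 0))) {
    e <- render_one_and_measure(48, 8, case[1], off_x = case[2],
                                off_y = case[3])$elongation_e
    expect_lt(abs(e / base - 1), 0.02)
  }
})

test_that("degenerate one-pixel-wide objects are flagged, not dropped", {
  m <- matrix(0L, 30, 30)
  m[5:25, 10] <- 1L
  rec <- measure_shape(m)
  expect_equal(nrow(rec), 1L)
  expect_true(rec$degenerate)
  expect_warning(out <- classify_phenotype(rec))
  expect_equal(as.character(out$phenotype), "unclassified")
})

test_that("phenotype classes follow the published thresholds", {
  rec <- data.frame(
    elongation_e = c(3.5, 1.5, 2.0, 4.0, 3.0, 2.0, 2.0, 1.0),
    csi = c(0.30, 0.80, 0.50, 0.80, 0.30, 0.40, 0.60, 0.95))
  out <- classify_phenotype(rec)
  expect_equal(as.character(out$phenotype),
               c("contractile",   # E > 3, CSI < 0.4
                 "synthetic",     # 1 < E < 3, CSI > 0.6
                 "undecided",     # 0.4 < CSI < 0.6
                 "unclassified",  # conflicting: high E with high CSI
                 "unclassified",  # E exactly 3: strict inequality
                 "unclassified",  # CSI exactly 0.4
                 "unclassified",  # CSI exactly 0.6
                 "unclassified")) # E exactly 1
})

test_that("classification partitions all records exactly once", {
  set.seed(21)
  rec <- data.frame(elongation_e = stats::runif(500, 1, 8),
                    csi = stats::runif(500, 0.01, 1))
  out <- classify_phenotype(rec)
  expect_false(anyNA(out$phenotype))
  expect_equal(sum(table(out$phenotype)), 500L)
})

test_that("generator truth labels are recovered at the default thresholds", {
  des <- plate_design("m", 0.5, n_cells = 400)
  truth <- plate_truth(generate_plate(des, seed = 31))
  out <- classify_phenotype(truth_records(truth))
  agree <- mean(as.character(out$phenotype) == truth$phenotype_true)
  expect_gte(agree, 0.95)
})

test_that("threshold configuration rejects overlapping intervals", {
  expect_error(class_thresholds(csi_contractile_max = 0.7), "non-overlapping")
  expect_error(class_thresholds(csi_undecided = c(0.6, 0.4)),
               "non-overlapping")
})
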