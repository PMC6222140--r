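cal <- probe_calibration()

test_that("background subtraction honours the reference and clamps at zero", {
  truth <- matrix(c(0, 5, 10, 20), 2, 2)
  ref <- matrix(c(3, 3, 3, 3), 2, 2)
  expect_equal(subtract_background(truth + ref, ref), truth)
  expect_equal(subtract_background(truth, matrix(0, 2, 2)), truth)
  over <- matrix(100, 2, 2)
  expect_true(all(subtract_background(truth, over) == 0))
  expect_error(subtract_background(truth, matrix(0, 3, 3)), "shape")
})

test_that("scalar background subtraction removes a flat pedestal", {
  img <- matrix(50, 40, 40)
  img[15:25, 15:25] <- 500
  corr <- subtract_background(img)
  expect_equal(median(corr[img == 50]), 0)
  expect_equal(max(corr), 450)
})

test_that("well-separated bright cells segment one-to-one against truth", {
  g <- generate_field(scene_spec(n_cells = 10, field_shape = c(256, 256),
                                 crowding_px = 45, oxidized_fraction = 0.9,
                                 expression_sdlog = 0.1, speckle_shape = 8),
                      cal, noise_spec(seed = 31))
  lab <- segment_intensity(subtract_background(g$field$channels$ex405))
  expect_length(map_labels(lab), 10)
  m <- match_to_ground_truth(lab, g$truth$cell_labels, iou_threshold = 0.4)
  expect_equal(m$n_matched, 10L)
})

test_that("crowded fields under-segment on intensity alone", {
  g <- generate_field(scene_spec(n_cells = 25, field_shape = c(192, 192),
                                 crowding_px = 14, oxidized_fraction = 0.9),
                      cal, noise_spec(seed = 8))
  lab <- segment_intensity(subtract_background(g$field$channels$ex405))
  expect_lt(length(map_labels(lab)), 25)
})

test_that("blank images yield empty label maps, not errors", {
  z <- matrix(0, 64, 64)
  expect_length(map_labels(segment_intensity(z)), 0)
  expect_length(map_labels(segment_nuclei(z)), 0)
})

test_that("Otsu segmentation is invariant to a positive gain", {
  g <- generate_field(scene_spec(n_cells = 8, field_shape = c(160, 160),
                                 crowding_px = 30), cal, noise_spec(seed = 12))
  img <- subtract_background(g$field$channels$nuclear)
  a <- segment_nuclei(img)
  b <- segment_nuclei(img * 7.3)
  expect_identical(matrix(as.integer(a), 160, 160),
                   matrix(as.integer(b), 160, 160))
})

test_that("disjoint nuclei are segmented exactly and split when touching", {
  g <- generate_field(scene_spec(n_cells = 10, field_shape = c(256, 256),
                                 crowding_px = 40), cal, noise_spec(seed = 4))
  nuc <- segment_nuclei(subtract_background(g$field$channels$nuclear))
  expect_length(map_labels(nuc), 10)
  m <- match_to_ground_truth(nuc, g$truth$nucleus_labels, iou_threshold = 0.4)
  expect_equal(m$n_matched, 10L)

  # two overlapping discs with centers two radii apart split into 2
  img <- matrix(0, 64, 64)
  for (c0 in list(c(32, 26), c(32, 38))) {
    d2 <- outer((1:64 - c0[1])^2, (1:64 - c0[2])^2, "+")
    img[d2 <= 36] <- 600
  }
  lab <- segment_nuclei(img, segmentation_params(min_object_area_px = 20))
  expect_length(map_labels(lab), 2)
})

test_that("ring construction matches the disc geometry exactly", {
  n <- 41
  d <- sqrt(outer((1:n - 21)^2, (1:n - 21)^2, "+"))
  nuc <- matrix(0L, n, n); nuc[d <= 5] <- 1L
  ring <- ring_rois(label_map(nuc, "nucleus"),
                    segmentation_params(ring_dilation_width_px = 3))
  expect_identical(matrix(as.integer(ring), n, n) == 1L, d > 5 & d <= 8)
})

test_that("width-zero rings are empty with a warning", {
  nuc <- matrix(0L, 20, 20); nuc[8:12, 8:12] <- 1L
  expect_warning(
    ring <- ring_rois(label_map(nuc, "nucleus"),
                      segmentation_params(ring_dilation_width_px = 0)),
    "empty")
  expect_length(map_labels(ring), 0)
})

test_that("distant nuclei give disjoint rings with preserved labels", {
  nuc <- matrix(0L, 60, 60)
  d1 <- outer((1:60 - 15)^2, (1:60 - 15)^2, "+")
  d2 <- outer((1:60 - 15)^2, (1:60 - 45)^2, "+")
  nuc[d1 <= 25] <- 1L; nuc[d2 <= 25] <- 2L
  ring <- ring_rois(label_map(nuc, "nucleus"),
                    segmentation_params(ring_dilation_width_px = 3))
  oracle <- oracle_rings(nuc, 3)
  expect_identical(matrix(as.integer(ring), 60, 60), oracle)
  expect_identical(map_labels(ring), 1:2)
})

test_that("rings equal the brute-force Euclidean oracle on random fixtures", {
  for (s in 1:8) {
    nuc <- random_nucleus_map(c(28, 30), n_blobs = 3, seed = s)
    for (cfg in list(c(w = 3, e = 0), c(w = 4, e = 1))) {
      ring <- ring_rois(label_map(nuc, "nucleus"),
                        segmentation_params(ring_dilation_width_px = cfg["w"],
                                            nucleus_erosion_px = cfg["e"]))
      expect_identical(matrix(as.integer(ring), 28, 30),
                       oracle_rings(nuc, cfg["w"], cfg["e"]),
                       label = sprintf("seed %d w %d e %d", s, cfg["w"], cfg["e"]))
    }
  }
})

test_that("every ring pixel's nearest nucleus is its own label", {
  g <- generate_field(scene_spec(n_cells = 12, field_shape = c(160, 160),
                                 crowding_px = 16), cal, noise_spec(seed = 6))
  nuc <- g$truth$nucleus_labels
  ring <- ring_rois(nuc, segmentation_params(ring_dilation_width_px = 5))
  expect_true(all((as.integer(ring) > 0) + (as.integer(nuc) > 0) <= 1))
  rm <- matrix(as.integer(ring), 160, 160)
  px <- which(rm > 0, arr.ind = TRUE)
  pick <- px[seq(1, nrow(px), length.out = 50), , drop = FALSE]
  nm <- matrix(as.integer(nuc), 160, 160)
  for (r in seq_len(nrow(pick))) {
    i <- pick[r, 1]; j <- pick[r, 2]
    cand <- which(nm > 0, arr.ind = TRUE)
    d2 <- (cand[, 1] - i)^2 + (cand[, 2] - j)^2
    best <- nm[cand[which.min(d2), , drop = FALSE]]
    expect_equal(rm[i, j], best)
  }
})

test_that("ground-truth matching follows the IoU contract", {
  a <- label_map(matrix(c(rep(0L, 10), rep(1L, 6), rep(0L, 4),
                          rep(2L, 5), rep(0L, 75)), 10, 10), "cell")
  expect_equal(match_to_ground_truth(a, a)$f1, 1)
  empty <- label_map(matrix(0L, 10, 10), "cell")
  expect_equal(match_to_ground_truth(empty, a)$recall, 0)
  expect_equal(match_to_ground_truth(empty, empty)$precision, 1)

  # one merged prediction over two truth objects at IoU 0.4 each
  truth <- matrix(0L, 20, 20)
  truth[3:10, 3:7] <- 1L   # 40 px
  truth[3:10, 12:16] <- 2L # 40 px
  pred <- matrix(0L, 20, 20)
  pred[3:10, 3:16] <- 1L   # 112 px; IoU with each = 40 / 112
  res <- match_to_ground_truth(label_map(pred, "cell"),
                               label_map(truth, "cell"), iou_threshold = 0.5)
  expect_equal(res$n_matched, 0L)
  expect_equal(res$recall, 0)
})
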