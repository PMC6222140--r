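cal <- probe_calibration()

test_that("ratio images follow the gain-invariant masked contract", {
  a <- matrix(2, 8, 8); b <- matrix(4, 8, 8)
  r <- ratio_image(a, b, intensity_floor = 1)
  expect_true(all(r == 0.5))
  expect_identical(ratio_image(a * 3, b * 3, intensity_floor = 1), r)
  b2 <- b; b2[5, 5] <- 0.2
  r2 <- ratio_image(a, b2, intensity_floor = 1)
  expect_true(is.na(r2[5, 5]))
  expect_false(any(is.infinite(r2), na.rm = TRUE))
  expect_error(ratio_image(a, matrix(1, 4, 4)), "shape")
})

test_that("single-pixel and uniform ROIs measure exactly", {
  ch <- list(ex405 = matrix(1:16 * 1.0, 4, 4), ex488 = matrix(8, 4, 4),
             nuclear = matrix(2, 4, 4), tmrm = matrix(3, 4, 4))
  f <- field_image(ch, well_id = "W1")
  rois <- matrix(0L, 4, 4); rois[2, 3] <- 1L
  rec <- measure_rois(label_map(rois, "cell"), f,
                      ratio_image(ch$ex405, ch$ex488, 1))
  expect_equal(rec$area_px, 1L)
  expect_equal(rec$mean_405, ch$ex405[2, 3])
  expect_equal(rec$ratio, ch$ex405[2, 3] / 8)

  rois2 <- matrix(1L, 4, 4)
  rec2 <- measure_rois(label_map(rois2, "cell"), f)
  expect_equal(rec2$granularity, 0) # uniform ex488 has zero CV
})

test_that("per-cell ratios are invariant to a common channel gain", {
  g <- generate_field(scene_spec(n_cells = 6, field_shape = c(128, 128),
                                 crowding_px = 30), cal, noise_spec(seed = 13))
  ch <- lapply(g$field$channels, subtract_background)
  f1 <- g$field; f1$channels <- ch
  f2 <- g$field
  f2$channels <- ch; f2$channels$ex405 <- ch$ex405 * 2.5
  f2$channels$ex488 <- ch$ex488 * 2.5
  rings <- ring_rois(g$truth$nucleus_labels)
  r1 <- measure_rois(rings, f1, ratio_image(ch$ex405, ch$ex488, 9))
  r2 <- measure_rois(rings, f2, ratio_image(ch$ex405 * 2.5, ch$ex488 * 2.5,
                                            9 * 2.5))
  expect_equal(r1$ratio, r2$ratio, tolerance = 1e-12)
})

test_that("measured ring ratios recover the generator truth", {
  g <- generate_field(scene_spec(n_cells = 20, field_shape = c(256, 256),
                                 crowding_px = 28,
                                 oxidized_fraction = function(n)
                                   runif(n, 0.05, 0.95)),
                      cal, noise_spec(seed = 17))
  ch <- lapply(g$field$channels, subtract_background)
  f <- g$field; f$channels <- ch
  rings <- ring_rois(g$truth$nucleus_labels)
  rec <- measure_rois(rings, f, ratio_image(ch$ex405, ch$ex488, 9))
  rel_err <- abs(rec$ratio - g$truth$true_ratio[rec$cell_label]) /
    g$truth$true_ratio[rec$cell_label]
  expect_lt(median(rel_err), 0.05)
})

test_that("well summaries aggregate ratios and the high-ratio gate", {
  layout <- data.frame(well_id = c("B01", "C01"),
                       role = c("negative_control", "treatment"))
  rec <- data.frame(well_id = "B01", ratio = c(0.4, 0.5, 0.6),
                    mean_tmrm = c(1, 2, 3))
  ws <- well_summary(rec, layout, high_ratio_gate = 1)
  b <- ws[ws$well_id == "B01", ]
  expect_equal(b$ratio_mean, 0.5)
  expect_equal(b$ratio_sd, 0.1)
  expect_equal(b$fraction_high_ratio, 0) # all cells below the gate
  expect_equal(ws[ws$well_id == "C01", "n_cells"], 0)
  expect_true(is.na(ws[ws$well_id == "C01", "ratio_mean"]))
  # default gate: control mean + 3 sd
  ws2 <- well_summary(rec, layout)
  expect_equal(attr(ws2, "high_ratio_gate"), 0.5 + 3 * 0.1)
})

test_that("fraction_high_ratio tracks the simulated oxidized fraction", {
  layout <- demo_layout(1, 1)
  fracs <- c(0.2, 0.5, 0.8)
  got <- vapply(seq_along(fracs), function(i) {
    p <- fracs[i]
    sc <- scene_spec(n_cells = 40, field_shape = c(256, 256), crowding_px = 28,
                     oxidized_fraction = function(n)
                       ifelse(runif(n) < p, 0.9, cal$f_baseline))
    g <- generate_field(sc, cal, noise_spec(seed = 40 + i))
    ch <- lapply(g$field$channels, subtract_background)
    f <- g$field; f$channels <- ch; f$well_id <- "C01"
    rec <- measure_rois(ring_rois(g$truth$nucleus_labels), f,
                        ratio_image(ch$ex405, ch$ex488, 9))
    rec$well_id <- "C01"
    ws <- well_summary(rec, layout, high_ratio_gate = 1.0)
    ws$fraction_high_ratio[ws$well_id == "C01"]
  }, numeric(1))
  expect_true(all(diff(got) > 0))
  expect_equal(got[2], 0.5, tolerance = 0.25)
})

test_that("correlation follows the Pearson contract", {
  x <- 1:10
  expect_equal(correlate(x, -2 * x + 1), -1)
  set.seed(1); z <- rnorm(20)
  expect_equal(correlate(z, z), 1)
  expect_error(correlate(rep(1, 5), 1:5), "zero variance")
  expect_error(correlate(1:3, 1:4), "lengths differ")
  expect_error(correlate(c(1, 2), c(3, 4)), "at least 3")
})

test_that("dying cells show negative TMRM-vs-ratio correlation", {
  # snapshot of an asynchronous dying population: cells at different stages
  k <- kinetic_params()
  stage <- round(seq(5, 55, length.out = 60))
  ratio <- vapply(stage, function(t)
    simulate_redox_trajectory(k, 60, seed = t)$ratio[t], numeric(1))
  tmrm <- vapply(stage, function(t)
    simulate_redox_trajectory(k, 60, seed = 100 + t)$tmrm[t], numeric(1))
  expect_lt(correlate(tmrm, ratio), 0)
})
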