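cal <- probe_calibration()

test_that("field generation is a pure function of spec and seed", {
  sc <- scene_spec(n_cells = 8, field_shape = c(128, 128), crowding_px = 30)
  a <- generate_field(sc, cal, noise_spec(seed = 11))
  b <- generate_field(sc, cal, noise_spec(seed = 11))
  expect_identical(a$field$channels, b$field$channels)
  expect_identical(a$truth$true_oxidized_fraction, b$truth$true_oxidized_fraction)
  expect_identical(matrix(as.integer(a$truth$cell_labels), 128, 128),
                   matrix(as.integer(b$truth$cell_labels), 128, 128))
  c <- generate_field(sc, cal, noise_spec(seed = 12))
  expect_false(identical(a$field$channels$ex405, c$field$channels$ex405))
})

test_that("ground truth has exactly the requested cells with matching label sets", {
  g <- generate_field(scene_spec(n_cells = 10, field_shape = c(256, 256),
                                 crowding_px = 40), cal, noise_spec(seed = 2))
  expect_identical(map_labels(g$truth$nucleus_labels), 1:10)
  expect_identical(map_labels(g$truth$cell_labels), 1:10)
  # conservation: per-label pixel counts sum to the nonzero pixel count
  for (m in list(g$truth$nucleus_labels, g$truth$cell_labels)) {
    v <- as.integer(m)
    expect_identical(sum(tabulate(v[v > 0])), sum(v > 0))
  }
})

test_that("flat-field photon noise is Poisson (variance ~ mean)", {
  g <- generate_field(scene_spec(n_cells = 0, field_shape = c(128, 128),
                                 background_level = 200),
                      cal, noise_spec(read_noise_sd = 0, seed = 5))
  px <- as.numeric(g$field$channels$ex405)
  expect_gte(length(px), 1e4)
  expect_equal(var(px) / mean(px), 1, tolerance = 0.1)
})

test_that("noise-free renders are monotone in the oxidized fraction", {
  sc_lo <- scene_spec(n_cells = 6, field_shape = c(160, 160), crowding_px = 40,
                      oxidized_fraction = 0.2)
  sc_hi <- sc_lo; sc_hi$oxidized_fraction <- 0.7
  lo <- generate_field(sc_lo, cal, noise_spec(seed = 9), noiseless = TRUE)
  hi <- generate_field(sc_hi, cal, noise_spec(seed = 9), noiseless = TRUE)
  # identical geometry, so per-cell means are directly comparable
  expect_identical(matrix(as.integer(lo$truth$cell_labels), 160, 160),
                   matrix(as.integer(hi$truth$cell_labels), 160, 160))
  labs <- as.integer(lo$truth$cell_labels)
  for (k in 1:6) {
    sel <- labs == k
    expect_gte(mean(hi$field$channels$ex405[sel]), mean(lo$field$channels$ex405[sel]))
    expect_lte(mean(hi$field$channels$ex488[sel]), mean(lo$field$channels$ex488[sel]))
  }
})

test_that("impossible placement fails naming the constraint", {
  expect_error(generate_field(scene_spec(n_cells = 60, field_shape = c(64, 64),
                                         crowding_px = 30),
                              cal, noise_spec(seed = 1)),
               "spacing")
})

test_that("rendered intensities stay inside the detector range", {
  g <- generate_field(scene_spec(n_cells = 5, field_shape = c(96, 96),
                                 crowding_px = 30),
                      cal, noise_spec(bit_depth = 8, seed = 3))
  for (ch in g$field$channels) {
    expect_gte(min(ch), 0)
    expect_lte(max(ch), 255)
  }
})
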