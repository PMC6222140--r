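cal <- probe_calibration()

test_that("a plate written to disk reads back bit-identically", {
  dir <- withr::local_tempdir()
  g <- generate_field(scene_spec(n_cells = 5, field_shape = c(96, 96),
                                 crowding_px = 30), cal, noise_spec(seed = 21))
  g$field$well_id <- "B03"; g$field$field_index <- 2L
  write_field(g$field, dir)
  back <- read_plate(dir)
  expect_length(back, 1)
  expect_identical(back[[1]]$well_id, "B03")
  expect_identical(back[[1]]$field_index, 2L)
  for (ch in names(g$field$channels))
    expect_identical(back[[1]]$channels[[ch]], g$field$channels[[ch]] * 1)
})

test_that("a field missing its ex488 file fails naming the channel", {
  dir <- withr::local_tempdir()
  g <- generate_field(scene_spec(n_cells = 3, field_shape = c(64, 64),
                                 crowding_px = 25), cal, noise_spec(seed = 1))
  g$field$well_id <- "A01"
  paths <- write_field(g$field, dir)
  unlink(paths[grepl("ex488", paths)])
  expect_error(read_plate(dir), "ex488")
})

test_that("an empty directory yields an empty collection, not an error", {
  dir <- withr::local_tempdir()
  expect_length(read_plate(dir), 0)
})

test_that("layout wells without images warn rather than fail", {
  dir <- withr::local_tempdir()
  g <- generate_field(scene_spec(n_cells = 3, field_shape = c(64, 64),
                                 crowding_px = 25), cal, noise_spec(seed = 1))
  g$field$well_id <- "B01"
  write_field(g$field, dir)
  layout <- data.frame(well_id = c("B01", "B02"),
                       role = c("negative_control", "treatment"))
  expect_warning(read_plate(dir, layout), "B02")
})

test_that("cell tables roundtrip to 1e-9 and keep missing values missing", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "cells.csv")
  rec <- data.frame(well_id = "B01", field_index = 1L, timepoint_index = 1L,
                    cell_label = 1:3, area_px = c(120L, 88L, 75L),
                    mean_405 = c(101.123456789, 55.5, 80.25),
                    mean_488 = c(201.987654321, 150, 160),
                    mean_nuclear = c(400, 410, NA),
                    mean_tmrm = c(300, 310, 295),
                    granularity = c(0.41, 0.38, 0.44),
                    ratio = c(0.50312345678, NA, 0.51),
                    n_valid_ratio_px = c(118L, 0L, 70L))
  write_cell_table(rec, path)
  raw <- readLines(path)
  # missing ratio is an empty field, not a sentinel value
  expect_match(raw[3], ",,")
  back <- read_cell_table(path)
  expect_equal(back$mean_405, rec$mean_405, tolerance = 1e-9)
  expect_equal(back$ratio, rec$ratio, tolerance = 1e-9)
  expect_true(is.na(back$ratio[2]))
})

test_that("zero records give a header-only CSV", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "empty.csv")
  write_cell_table(NULL, path)
  expect_length(readLines(path), 1)
  expect_equal(nrow(read_cell_table(path)), 0)
})

test_that("ratio TIFFs roundtrip with the validity mask", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "ratio.tif")
  r <- matrix(runif(64, 0.3, 2.2), 8, 8)
  r[c(3, 17, 40)] <- NA
  write_ratio_tiff(r, path)
  back <- read_ratio_tiff(path)
  expect_equal(which(is.na(back)), which(is.na(r)))
  expect_equal(back[!is.na(r)], r[!is.na(r)], tolerance = 1e-6)
})

test_that("label maps roundtrip through 16-bit TIFF", {
  dir <- withr::local_tempdir()
  m <- matrix(0L, 16, 16); m[3:6, 3:6] <- 1L; m[10:14, 9:12] <- 2L
  path <- file.path(dir, "labels.tif")
  write_label_tiff(label_map(m, "nucleus"), path)
  back <- read_label_tiff(path, "nucleus")
  expect_identical(matrix(as.integer(back), 16, 16), m)
})

test_that("layout validation enforces roles and unique wells", {
  expect_error(read_layout(data.frame(well_id = "A1", role = "oops")), "role")
  expect_error(read_layout(data.frame(well_id = c("A1", "A1"),
                                      role = "treatment")), "duplicate")
  expect_error(read_layout(data.frame(role = "treatment")), "well_id")
})
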