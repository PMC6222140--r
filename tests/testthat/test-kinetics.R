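cal <- probe_calibration()

make_disc_map <- function(centers, shape = c(64, 64), r = 5) {
  m <- matrix(0L, shape[1], shape[2])
  for (k in seq_len(nrow(centers))) {
    d2 <- outer((seq_len(shape[1]) - centers[k, 1])^2,
                (seq_len(shape[2]) - centers[k, 2])^2, "+")
    m[d2 <= r^2] <- k
  }
  label_map(m, "nucleus")
}

test_that("static cells yield one full-length track each", {
  maps <- rep(list(make_disc_map(rbind(c(16, 16), c(48, 40)))), 5)
  tracks <- track_nuclei(maps, max_displacement_px = 5)
  expect_equal(length(unique(tracks$track_id)), 2)
  expect_true(all(table(tracks$track_id) == 5))
})

test_that("drifting cells keep their identity within the search radius", {
  centers0 <- rbind(c(12, 12), c(12, 40), c(40, 12), c(40, 40))
  maps <- lapply(0:5, function(t) make_disc_map(centers0 + 2 * t, c(72, 72)))
  tracks <- track_nuclei(maps, max_displacement_px = 5)
  expect_equal(length(unique(tracks$track_id)), 4)
  expect_true(all(table(tracks$track_id) == 6))
  # identity: each track keeps one ground-truth label throughout
  expect_true(all(tapply(tracks$cell_label, tracks$track_id,
                         function(x) length(unique(x))) == 1))
})

test_that("a vanished cell terminates its track without gap closing", {
  m2 <- make_disc_map(rbind(c(16, 16), c(48, 40)))
  m1 <- make_disc_map(rbind(c(16, 16)))
  tracks <- track_nuclei(list(m2, m2, m1, m1), max_displacement_px = 5)
  len <- table(tracks$track_id)
  expect_setequal(as.integer(len), c(4L, 2L))
})

test_that("noiseless biphasic trajectories are recovered exactly", {
  y <- c(rep(0.4, 19), rep(0.65, 20), rep(1.2, 41)) # changes at frames 20, 40
  ev <- detect_biphasic(y)
  expect_equal(ev$n_changepoints_detected, 2L)
  expect_equal(ev$t_surge, 20L)
  expect_equal(ev$t_secondary, 40L)
  expect_equal(ev$level_baseline, 0.4)
  expect_equal(ev$level_surge, 0.65)
  expect_equal(ev$level_final, 1.2)
})

test_that("constant trajectories yield zero change points", {
  ev <- detect_biphasic(rep(0.5, 30))
  expect_equal(ev$n_changepoints_detected, 0L)
  expect_equal(ev$level_baseline, 0.5)
  expect_error(detect_biphasic(rep(0.5, 5), min_segment_len = 3), "too short")
})

test_that("the detector equals exhaustive search on random trajectories", {
  for (s in 1:12) {
    set.seed(s)
    n <- sample(20:60, 1)
    c1 <- sample(5:(n - 10), 1); c2 <- sample((c1 + 4):(n - 4), 1)
    y <- c(rep(0.4, c1 - 1), rep(0.8, c2 - c1), rep(1.5, n - c2 + 1)) +
      rnorm(n, 0, 0.08)
    got <- detect_biphasic(y)
    want <- oracle_changepoints(y)
    expect_equal(got$n_changepoints_detected, want$m, label = paste("seed", s))
    if (want$m >= 1) expect_equal(got$t_surge, want$c1)
    if (want$m == 2) expect_equal(got$t_secondary, want$c2)
  }
})

test_that("detection is shift invariant and scale equivariant", {
  set.seed(3)
  y <- c(rep(0.4, 15), rep(0.7, 15), rep(1.3, 20)) + rnorm(50, 0, 0.05)
  base <- detect_biphasic(y)
  shifted <- detect_biphasic(y + 5)
  scaled <- detect_biphasic(y * 12)
  expect_equal(shifted$t_surge, base$t_surge)
  expect_equal(shifted$t_secondary, base$t_secondary)
  expect_equal(scaled$t_surge, base$t_surge)
  expect_equal(scaled$level_final, 12 * base$level_final, tolerance = 1e-9)
})

test_that("event ordering reports the signed lag", {
  traj <- data.frame(t = 1:30,
                     ratio = c(rep(0.4, 13), rep(2, 17)),
                     tmrm = c(rep(1, 9), rep(0.2, 21)))
  got <- order_events(traj)
  expect_equal(got$t_tmrm, 10)
  expect_equal(got$t_ratio, 14)
  expect_equal(got$lag, 4L)
  flat <- data.frame(t = 1:30, ratio = rep(0.4, 30), tmrm = rep(1, 30))
  expect_true(is.na(order_events(flat)$lag))
})

test_that("ring trajectories recover the rendered kinetic truth", {
  sc <- scene_spec(n_cells = 6, field_shape = c(160, 160), crowding_px = 34)
  k <- kinetic_params(t_surge = 6, t_release = 10, t_secondary = 14,
                      tmrm_half_loss_time = 4)
  tl <- generate_timelapse(sc, k, n_frames = 18, cal = cal,
                           noise = noise_spec(seed = 23))
  params <- segmentation_params()
  nucmaps <- lapply(tl$frames, function(fr)
    segment_nuclei(subtract_background(fr$field$channels$nuclear), params))
  rings <- lapply(nucmaps, ring_rois, params = params)
  ratios <- lapply(tl$frames, function(fr)
    ratio_image(subtract_background(fr$field$channels$ex405),
                subtract_background(fr$field$channels$ex488), 9))
  tracks <- track_nuclei(nucmaps, max_displacement_px = 5)
  trajs <- extract_trajectories(tracks, ratios, rings)
  full <- Filter(function(tr) nrow(tr) == 18, trajs)
  expect_gte(length(full), 5)
  for (tr in full) {
    truth <- tl$truth$true_ratio[, 1] # same kinetics for every cell
    rel <- abs(tr$ratio - truth) / truth
    expect_lt(median(rel), 0.05)
  }
})

test_that("constant scenes give constant trajectories and length-1 tracks work", {
  sc <- scene_spec(n_cells = 3, field_shape = c(96, 96), crowding_px = 30,
                   oxidized_fraction = 0.5)
  g <- generate_field(sc, cal, noise_spec(seed = 3), noiseless = TRUE)
  ring <- ring_rois(g$truth$nucleus_labels)
  ch <- lapply(g$field$channels, function(x) pmax(x - 100, 0))
  r <- ratio_image(ch$ex405, ch$ex488, 9)
  tracks <- data.frame(track_id = 1L, frame = 1L,
                       cell_label = 1L, row = 0, col = 0)
  trajs <- extract_trajectories(tracks, list(r), list(ring))
  expect_length(trajs, 1)
  expect_equal(nrow(trajs[[1]]), 1)
  expect_equal(trajs[[1]]$ratio, probe_ratio(0.5, cal), tolerance = 0.01)
})
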