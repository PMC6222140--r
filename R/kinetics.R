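#' Track nuclei across frames by greedy nearest-neighbour linking
#'
#' Links per-frame nucleus detections frame-to-frame by ascending centroid
#' distance; links beyond \code{max_displacement_px} are rejected,
#' unmatched detections start new tracks, and lost tracks terminate (no
#' gap closing — dying cells do not divide and fields are sparse in time).
#'
#' @param label_maps list of per-frame nucleus \code{\link{label_map}}s
#'   (>= 2 frames).
#' @param max_displacement_px maximum allowed centroid displacement
#'   between consecutive frames.
#' @return A \code{data.frame} with columns \code{track_id}, \code{frame},
#'   \code{cell_label}, \code{row}, \code{col}, frames contiguous within a
#'   track.
#' @export
track_nuclei <- function(label_maps, max_displacement_px = 5) {
  stopifnot(length(label_maps) >= 2, max_displacement_px > 0)
  cents <- lapply(label_maps, label_centroids)
  rows <- list()
  next_id <- 0L
  prev <- NULL # data.frame: track_id, label, row, col
  for (fr in seq_along(cents)) {
    cur <- cents[[fr]]
    assigned <- rep(NA_integer_, nrow(cur))
    if (!is.null(prev) && nrow(prev) && nrow(cur)) {
      d <- outer(prev$row, cur$row, "-")^2 + outer(prev$col, cur$col, "-")^2
      cand <- which(d <= max_displacement_px^2, arr.ind = TRUE)
      if (nrow(cand)) {
        # greedy by ascending distance; ties by (prev label, cur label)
        ord <- order(d[cand], prev$label[cand[, 1]], cur$label[cand[, 2]])
        used_p <- logical(nrow(prev)); used_c <- logical(nrow(cur))
        for (r in ord) {
          i <- cand[r, 1]; j <- cand[r, 2]
          if (!used_p[i] && !used_c[j]) {
            assigned[j] <- prev$track_id[i]
            used_p[i] <- TRUE; used_c[j] <- TRUE
          }
        }
      }
    }
    new <- is.na(assigned)
    if (any(new)) {
      assigned[new] <- next_id + seq_len(sum(new))
      next_id <- next_id + sum(new)
    }
    if (nrow(cur))
      rows[[fr]] <- data.frame(track_id = assigned, frame = fr,
                               cell_label = cur$label,
                               row = cur$row, col = cur$col)
    prev <- if (nrow(cur))
      data.frame(track_id = assigned, label = cur$label,
                 row = cur$row, col = cur$col)
    else NULL
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(track_id = integer(), frame = integer(),
                      cell_label = integer(), row = numeric(), col = numeric())
  out[order(out$track_id, out$frame), , drop = FALSE]
}

#' Extract per-track ratio/TMRM trajectories
#'
#' For each frame of each track, the trajectory value is the mean of the
#' valid ratio pixels over that frame's ring ROI of the tracked nucleus
#' (same for TMRM). A frame with no valid ratio pixels yields a missing
#' value.
#'
#' @param tracks output of \code{\link{track_nuclei}}.
#' @param ratio_images per-frame list of ratio matrices
#'   (\code{\link{ratio_image}}).
#' @param ring_maps per-frame list of ring \code{\link{label_map}}s whose
#'   labels match the nucleus labels.
#' @param tmrm_images optional per-frame list of background-corrected TMRM
#'   matrices.
#' @return A list of \code{trajectory} data.frames (columns \code{t},
#'   \code{ratio}, \code{tmrm}), one per track, named by track id.
#' @export
extract_trajectories <- function(tracks, ratio_images, ring_maps,
                                 tmrm_images = NULL) {
  n_frames <- length(ratio_images)
  stopifnot(length(ring_maps) == n_frames,
            is.null(tmrm_images) || length(tmrm_images) == n_frames)
  ids <- unique(tracks$track_id)
  out <- lapply(ids, function(id) {
    tr <- tracks[tracks$track_id == id, ]
    ratio <- vapply(seq_len(nrow(tr)), function(r) {
      px <- unmap(ring_maps[[tr$frame[r]]]) == tr$cell_label[r]
      v <- ratio_images[[tr$frame[r]]][px]
      v <- v[is.finite(v)]
      if (length(v)) mean(v) else NA_real_
    }, numeric(1))
    tmrm <- if (is.null(tmrm_images)) rep(NA_real_, nrow(tr)) else
      vapply(seq_len(nrow(tr)), function(r) {
        px <- unmap(ring_maps[[tr$frame[r]]]) == tr$cell_label[r]
        v <- tmrm_images[[tr$frame[r]]][px]
        if (length(v)) mean(v, na.rm = TRUE) else NA_real_
      }, numeric(1))
    traj <- data.frame(t = tr$frame, ratio = ratio, tmrm = tmrm)
    class(traj) <- c("trajectory", "data.frame")
    traj
  })
  names(out) <- ids
  out
}

# segment cost table for piecewise-constant least squares:
# cost(i, j) = sum_{i..j} (y - mean)^2, computed from cumulative sums
segment_cost_fns <- function(y) {
  s1 <- c(0, cumsum(y)); s2 <- c(0, cumsum(y^2))
  function(i, j) {
    n <- j - i + 1
    s <- s1[j + 1] - s1[i]
    (s2[j + 1] - s2[i]) - s^2 / n
  }
}

#' Biphasic change-point detection on a single-cell ratio trajectory
#'
#' Exhaustive least-squares piecewise-constant fit with 0, 1 or 2 change
#' points (a change point is the first frame of the new level); the model
#' order is chosen by BIC. Two change points capture the assay's biphasic
#' signature: the moderate pre-permeabilization surge and the drastic
#' secondary rise after reporter release. Ties in the least squares are
#' broken toward the earliest change point(s).
#'
#' @param traj a trajectory data.frame (or numeric ratio vector).
#' @param max_changepoints 0, 1 or 2.
#' @param min_segment_len minimum frames per fitted segment.
#' @return A list of class \code{redox_event}: \code{n_changepoints_detected},
#'   \code{t_surge}, \code{t_secondary} (frame indices into the
#'   trajectory, \code{NA} when not detected), and fitted
#'   \code{level_baseline}, \code{level_surge}, \code{level_final}.
#' @export
detect_biphasic <- function(traj, max_changepoints = 2, min_segment_len = 3) {
  y <- if (is.data.frame(traj)) traj$ratio else as.numeric(traj)
  stopifnot(max_changepoints %in% 0:2, min_segment_len >= 1)
  if (any(!is.finite(y))) stop("trajectory has missing ratio values")
  n <- length(y)
  if (n < 3 * min_segment_len)
    stop(sprintf("trajectory too short: need >= %d frames (3 x min_segment_len), got %d",
                 3 * min_segment_len, n))
  cost <- segment_cost_fns(y)
  msl <- min_segment_len

  rss0 <- cost(1, n)
  best1 <- list(rss = Inf, c1 = NA_integer_)
  if (max_changepoints >= 1) {
    for (c1 in (msl + 1):(n - msl + 1)) {
      r <- cost(1, c1 - 1) + cost(c1, n)
      if (r < best1$rss - 1e-12) best1 <- list(rss = r, c1 = c1)
    }
  }
  best2 <- list(rss = Inf, c1 = NA_integer_, c2 = NA_integer_)
  if (max_changepoints >= 2 && n >= 3 * msl) {
    for (c1 in (msl + 1):(n - 2 * msl + 1)) {
      left <- cost(1, c1 - 1)
      for (c2 in (c1 + msl):(n - msl + 1)) {
        r <- left + cost(c1, c2 - 1) + cost(c2, n)
        if (r < best2$rss - 1e-12) best2 <- list(rss = r, c1 = c1, c2 = c2)
      }
    }
  }
  # BIC with a scale-tracking floor so exact fits stay comparable
  floor_rss <- n * (1e-10 * max(abs(y))^2 + 1e-300)
  bic <- function(rss, m) n * log(max(rss, floor_rss) / n) + (2 * m + 1) * log(n)
  bics <- c(bic(rss0, 0),
            if (max_changepoints >= 1) bic(best1$rss, 1) else Inf,
            if (max_changepoints >= 2) bic(best2$rss, 2) else Inf)
  m <- which.min(bics) - 1L
  ev <- switch(as.character(m),
    "0" = list(n_changepoints_detected = 0L, t_surge = NA_integer_,
               t_secondary = NA_integer_, level_baseline = mean(y),
               level_surge = NA_real_, level_final = NA_real_),
    "1" = list(n_changepoints_detected = 1L, t_surge = best1$c1,
               t_secondary = NA_integer_,
               level_baseline = mean(y[1:(best1$c1 - 1)]),
               level_surge = NA_real_,
               level_final = mean(y[best1$c1:n])),
    "2" = list(n_changepoints_detected = 2L, t_surge = best2$c1,
               t_secondary = best2$c2,
               level_baseline = mean(y[1:(best2$c1 - 1)]),
               level_surge = mean(y[best2$c1:(best2$c2 - 1)]),
               level_final = mean(y[best2$c2:n])))
  structure(ev, class = "redox_event")
}

#' @export
print.redox_event <- function(x, ...) {
  cat(sprintf("<redox_event: %d change point(s)", x$n_changepoints_detected))
  if (x$n_changepoints_detected >= 1) cat(sprintf(", surge at frame %d", x$t_surge))
  if (x$n_changepoints_detected == 2) cat(sprintf(", secondary at frame %d", x$t_secondary))
  cat(">\n")
  invisible(x)
}

#' Order membrane-potential loss against the redox rise
#'
#' Event times: TMRM loss is the first frame at or below
#' \code{tmrm_loss_fraction} of the initial TMRM level (mean of the
#' baseline window); the ratio rise is the first frame strictly above
#' baseline mean + \code{ratio_rise_sd_mult} baseline sd (strict, so a
#' flat noiseless baseline never triggers its own gate). Both crossings
#' must persist for two consecutive frames — with the baseline sd
#' estimated from a handful of frames, single-frame noise excursions
#' otherwise fire the gate spuriously; the reported time is the first
#' frame of the persistent run. The signed lag
#' \code{t_ratio - t_tmrm} is positive when potential loss comes first —
#' the ordering the assay reports for drug-induced apoptosis.
#'
#' @param traj trajectory with both \code{ratio} and \code{tmrm}.
#' @param tmrm_loss_fraction loss threshold as a fraction of the initial
#'   TMRM level.
#' @param ratio_rise_sd_mult rise gate in baseline sds.
#' @param baseline_frames frames defining the baseline window (>= 5
#'   frames must exist).
#' @return List with \code{t_tmrm}, \code{t_ratio}, \code{lag} (frames;
#'   \code{NA} when either threshold is never crossed).
#' @export
order_events <- function(traj, tmrm_loss_fraction = 0.5,
                         ratio_rise_sd_mult = 3, baseline_frames = 5) {
  stopifnot(is.data.frame(traj), all(c("ratio", "tmrm") %in% names(traj)))
  if (nrow(traj) < baseline_frames)
    stop("trajectory shorter than the baseline window")
  base <- seq_len(baseline_frames)
  tmrm0 <- mean(traj$tmrm[base], na.rm = TRUE)
  r_mu <- mean(traj$ratio[base], na.rm = TRUE)
  r_sd <- stats::sd(traj$ratio[base], na.rm = TRUE)
  persistent_first <- function(hit) {
    hit[is.na(hit)] <- FALSE
    run <- hit & c(hit[-1], FALSE)
    which(run)[1]
  }
  t_tmrm <- persistent_first(traj$tmrm <= tmrm_loss_fraction * tmrm0)
  t_ratio <- persistent_first(traj$ratio > r_mu + ratio_rise_sd_mult * r_sd)
  lag <- if (is.na(t_tmrm) || is.na(t_ratio)) NA_integer_
  else as.integer(t_ratio - t_tmrm)
  list(t_tmrm = t_tmrm, t_ratio = t_ratio, lag = lag)
}
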