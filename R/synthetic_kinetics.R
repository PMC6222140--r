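#' Kinetic parameters of the biphasic single-cell redox trajectory
#'
#' Dying cells show a moderate pre-permeabilization surge of the 405/488
#' ratio, a progressive rise during release of the intermembrane-space
#' reporter, and a drastic secondary increase after release completes;
#' mitochondrial membrane potential (TMRM) is lost early. Defaults follow
#' the levels the assay reports for cisplatin-treated cells:
#' baseline 0.4, surge to 0.65, progressive rise to 1.2, then a secondary
#' plateau; TMRM half-loss precedes the surge.
#'
#' @param r_baseline,r_surge,r_released,r_secondary ratio levels, strictly
#'   increasing (\code{r_released <= r_secondary} allowed to be equal).
#' @param t_surge,t_release,t_secondary change times in frames (1-based,
#'   strictly increasing).
#' @param tmrm_half_loss_time frame at which TMRM crosses 50\% of its
#'   initial level (logistic decay); default before \code{t_surge} since
#'   potential loss is the early event.
#' @param tmrm_tau logistic time constant, frames.
#' @param trajectory_noise_sd per-frame additive Gaussian sd on the ratio.
#' @return An object of class \code{kinetic_params}.
#' @export
kinetic_params <- function(r_baseline = 0.4, r_surge = 0.65,
                           r_released = 1.2, r_secondary = 2.0,
                           t_surge = 20, t_release = 35, t_secondary = 50,
                           tmrm_half_loss_time = 12, tmrm_tau = 3,
                           trajectory_noise_sd = 0.04) {
  if (!(r_baseline < r_surge && r_surge < r_released &&
        r_released <= r_secondary))
    stop("need r_baseline < r_surge < r_released <= r_secondary")
  if (!(t_surge < t_release && t_release < t_secondary))
    stop("need t_surge < t_release < t_secondary")
  if (t_surge < 1) stop("change times must be positive frames")
  stopifnot(tmrm_tau > 0, trajectory_noise_sd >= 0)
  structure(list(r_baseline = r_baseline, r_surge = r_surge,
                 r_released = r_released, r_secondary = r_secondary,
                 t_surge = t_surge, t_release = t_release,
                 t_secondary = t_secondary,
                 tmrm_half_loss_time = tmrm_half_loss_time,
                 tmrm_tau = tmrm_tau,
                 trajectory_noise_sd = trajectory_noise_sd),
            class = "kinetic_params")
}

# noiseless piecewise ratio curve at 1-based frames t
piecewise_ratio <- function(t, k) {
  r <- numeric(length(t))
  r[t < k$t_surge] <- k$r_baseline
  seg2 <- t >= k$t_surge & t < k$t_release
  r[seg2] <- k$r_surge
  seg3 <- t >= k$t_release & t < k$t_secondary
  r[seg3] <- k$r_surge + (k$r_released - k$r_surge) *
    (t[seg3] - k$t_release) / (k$t_secondary - k$t_release)
  r[t >= k$t_secondary] <- k$r_secondary
  r
}

# monotone non-increasing logistic TMRM decay, value 0.5 at half-loss time
tmrm_decay <- function(t, k) {
  1 / (1 + exp((t - k$tmrm_half_loss_time) / k$tmrm_tau))
}

#' Simulate one single-cell redox/TMRM trajectory
#'
#' Piecewise trajectory on the ratio scale: constant at \code{r_baseline}
#' before \code{t_surge}; steps to \code{r_surge}; ramps linearly from
#' \code{r_surge} to \code{r_released} over
#' \code{[t_release, t_secondary)}; sits at \code{r_secondary} from
#' \code{t_secondary} on. TMRM follows a monotone non-increasing logistic
#' crossing 50\% of its initial plateau at \code{tmrm_half_loss_time}.
#' Gaussian noise of sd \code{trajectory_noise_sd} is added to the ratio
#' (and, scaled by the TMRM plateau, to TMRM).
#'
#' @param k a \code{\link{kinetic_params}}.
#' @param n_frames number of frames; must exceed \code{t_secondary}.
#' @param seed integer seed.
#' @return A \code{data.frame} (class \code{trajectory}) with columns
#'   \code{t}, \code{ratio}, \code{tmrm}, plus attribute \code{truth}
#'   holding the generating parameters.
#' @export
simulate_redox_trajectory <- function(k, n_frames, seed = 1L) {
  stopifnot(inherits(k, "kinetic_params"))
  if (n_frames <= k$t_secondary)
    stop("n_frames must exceed t_secondary")
  with_seed(seed, {
    t <- seq_len(n_frames)
    ratio <- piecewise_ratio(t, k) +
      stats::rnorm(n_frames, 0, k$trajectory_noise_sd)
    tmrm <- tmrm_decay(t, k) +
      stats::rnorm(n_frames, 0, k$trajectory_noise_sd)
    traj <- data.frame(t = t, ratio = ratio, tmrm = tmrm)
    attr(traj, "truth") <- k
    class(traj) <- c("trajectory", "data.frame")
    traj
  })
}

#' Render a time-lapse image sequence of dying cells
#'
#' Builds one static scene and renders it at each frame with per-cell
#' ratio levels taken from each cell's kinetic trajectory (converted to an
#' oxidized fraction through the calibration inverse) and TMRM scaled by
#' the logistic decay; cells optionally drift at a constant per-cell
#' velocity to exercise tracking.
#'
#' @param scene a \code{\link{scene_spec}}; its oxidized-fraction rule is
#'   ignored (kinetics drive oxidation).
#' @param kinetics a single \code{\link{kinetic_params}} applied to all
#'   cells, or a list of one per cell. Per-cell change times are jittered
#'   by \code{time_jitter_sd} frames (cells die asynchronously).
#' @param n_frames frames to render.
#' @param cal,noise calibration and noise model (the noise seed drives
#'   everything).
#' @param drift_px_per_frame magnitude of a constant whole-field (stage)
#'   drift; direction drawn once from the seed.
#' @param time_jitter_sd sd (frames) of the per-cell jitter applied to all
#'   three change times and the TMRM half-loss time.
#' @return A list with \code{frames} (list of per-frame
#'   \code{generate_field}-style lists) and \code{truth} (per-cell
#'   kinetic parameters, drift vectors, and the per-frame true ratio
#'   matrix, cells in columns).
#' @export
generate_timelapse <- function(scene, kinetics = kinetic_params(), n_frames = 60,
                               cal = probe_calibration(), noise = noise_spec(),
                               drift_px_per_frame = 0, time_jitter_sd = 0) {
  stopifnot(inherits(scene, "scene_spec"))
  n <- scene$n_cells
  seeds <- derive_seeds(noise$seed, n_frames + 2L)
  klist <- if (inherits(kinetics, "kinetic_params"))
    rep(list(kinetics), n) else kinetics
  stopifnot(length(klist) == n)

  base <- with_seed(seeds[1], {
    list(jit = stats::rnorm(n, 0, time_jitter_sd),
         ang = stats::runif(1, 0, 2 * pi))
  })
  if (time_jitter_sd > 0 || n > 0) {
    for (k in seq_len(n)) {
      kk <- klist[[k]]
      j <- round(base$jit[k])
      kk$t_surge <- max(2, kk$t_surge + j)
      kk$t_release <- max(kk$t_surge + 1, kk$t_release + j)
      kk$t_secondary <- max(kk$t_release + 1, kk$t_secondary + j)
      kk$tmrm_half_loss_time <- kk$tmrm_half_loss_time + j
      klist[[k]] <- kk
    }
  }
  drift <- c(row = drift_px_per_frame * sin(base$ang),
             col = drift_px_per_frame * cos(base$ang))

  true_ratio <- matrix(NA_real_, n_frames, max(n, 1))
  frames <- vector("list", n_frames)
  # the scene's own randomness (placement, radii, gains) must be identical
  # across frames: render frame 1 to fix geometry, then reuse its draws by
  # regenerating with the same sub-seed and per-frame oxidation values.
  for (tt in seq_len(n_frames)) {
    f_t <- vapply(seq_len(n), function(k)
      oxidized_fraction_for_ratio(
        min(piecewise_ratio(tt, klist[[k]]), probe_ratio(1, cal)), cal),
      numeric(1))
    tm_t <- vapply(seq_len(n), function(k)
      2 * tmrm_decay(tt, klist[[k]]), numeric(1))
    if (n > 0) true_ratio[tt, seq_len(n)] <-
      vapply(seq_len(n), function(k) piecewise_ratio(tt, klist[[k]]), numeric(1))
    sc <- scene
    sc$oxidized_fraction <- f_t
    sc$tmrm_level <- tm_t
    geom_noise <- noise
    geom_noise$seed <- seeds[2] # same geometry stream every frame
    fr <- generate_field_drifted(sc, cal, geom_noise, drift * (tt - 1),
                                 photon_seed = seeds[2L + tt])
    fr$field$timepoint_index <- tt
    frames[[tt]] <- fr
  }
  list(frames = frames,
       truth = list(kinetics = klist, drift = drift, true_ratio = true_ratio))
}

# generate_field with a fixed geometry seed but independent photon noise,
# and a whole-field offset (stage drift), applied at whole-pixel precision
generate_field_drifted <- function(scene, cal, noise, offset, photon_seed) {
  expected <- generate_field(scene, cal, noise_spec(
    photon_scale = noise$photon_scale, read_noise_sd = 0,
    bit_depth = noise$bit_depth, seed = noise$seed), noiseless = TRUE)
  sh <- round(offset)
  if (any(sh != 0)) {
    expected$field$channels <- lapply(expected$field$channels, shift_matrix,
                                      dr = sh["row"], dc = sh["col"],
                                      fill = scene$background_level)
    expected$truth$nucleus_labels <- label_map(
      shift_matrix(unmap(expected$truth$nucleus_labels), sh["row"], sh["col"], 0L),
      "nucleus")
    expected$truth$cell_labels <- label_map(
      shift_matrix(unmap(expected$truth$cell_labels), sh["row"], sh["col"], 0L),
      "cell")
    expected$truth$centers[, "row"] <- expected$truth$centers[, "row"] + sh["row"]
    expected$truth$centers[, "col"] <- expected$truth$centers[, "col"] + sh["col"]
  }
  with_seed(photon_seed, {
    expected$field$channels <- lapply(expected$field$channels, function(lambda) {
      x <- stats::rpois(length(lambda), lambda) +
        stats::rnorm(length(lambda), 0, noise$read_noise_sd)
      matrix(pmin(2^noise$bit_depth - 1, pmax(0, round(x))),
             nrow(lambda), ncol(lambda))
    })
  })
  expected
}

shift_matrix <- function(m, dr, dc, fill) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  src_r <- seq_len(nr) - dr; src_c <- seq_len(nc) - dc
  ok_r <- src_r >= 1 & src_r <= nr; ok_c <- src_c >= 1 & src_c <= nc
  out[ok_r, ok_c] <- m[src_r[ok_r], src_c[ok_c]]
  out
}
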