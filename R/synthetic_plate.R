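#' Default per-role oxidized-fraction samplers
#'
#' Study conditions of the simulated screen: mock-treated wells hold
#' resting cells at the calibration baseline (ratio 0.5); positive-control
#' wells hold a heterogeneous response — 80\% responders near full
#' oxidation, 20\% non-responders at baseline — matching the cell-to-cell
#' heterogeneity the assay's scatter plots show.
#'
#' @param cal a \code{\link{probe_calibration}}.
#' @param responder_fraction fraction of responding cells in positive wells.
#' @param responder_f mean oxidized fraction of responders.
#' @return Named list of \code{function(n)} samplers by role.
#' @export
role_oxidation_samplers <- function(cal = probe_calibration(),
                                    responder_fraction = 0.8,
                                    responder_f = 0.9) {
  clamp01 <- function(x) pmin(1, pmax(0, x))
  baseline <- function(n) clamp01(stats::rnorm(n, cal$f_baseline, 0.03))
  list(
    negative_control = baseline,
    positive_control = function(n) {
      resp <- stats::runif(n) < responder_fraction
      clamp01(ifelse(resp, stats::rnorm(n, responder_f, 0.04), baseline(n)))
    },
    treatment = function(n) {
      resp <- stats::runif(n) < responder_fraction
      clamp01(ifelse(resp, stats::rnorm(n, responder_f, 0.04), baseline(n)))
    })
}

#' Simulate a whole screening plate
#'
#' Generates one ground-truthed field set per non-empty well of the
#' layout, with per-well oxidation sampled by role. Optionally writes the
#' plate to disk (per-channel 16-bit TIFFs named
#' \code{{well}_{field}_{channel}.tif}, a per-cell ground-truth CSV, and
#' label-map TIFFs).
#'
#' @param layout plate layout (path or data.frame).
#' @param fields_per_well fields imaged per well.
#' @param scene a \code{\link{scene_spec}} (its oxidized-fraction rule is
#'   replaced per role).
#' @param cal,noise calibration and noise model; \code{noise$seed} is the
#'   master seed and every field gets a derived sub-seed, so fields are
#'   reproducible independently.
#' @param samplers per-role oxidation samplers
#'   (\code{\link{role_oxidation_samplers}}).
#' @param tmrm_by_role if \code{TRUE}, TMRM level tracks oxidation
#'   (responding cells lose membrane potential): per-cell level
#'   \code{2 * (1 - f)} plus jitter.
#' @param out_dir if non-\code{NULL}, write TIFFs and ground truth there.
#' @return Invisibly (when writing) or visibly a list of per-field
#'   \code{generate_field} results, each annotated with \code{well_id},
#'   \code{field_index} and \code{role}.
#' @export
generate_plate <- function(layout, fields_per_well = 1,
                           scene = scene_spec(), cal = probe_calibration(),
                           noise = noise_spec(),
                           samplers = role_oxidation_samplers(cal),
                           tmrm_by_role = TRUE, out_dir = NULL) {
  layout <- read_layout(layout)
  active <- layout[layout$role != "empty", ]
  n_fields <- nrow(active) * fields_per_well
  seeds <- derive_seeds(noise$seed, 2L * n_fields)
  out <- vector("list", n_fields)
  truth_rows <- list()
  i <- 0
  for (w in seq_len(nrow(active))) {
    sampler <- samplers[[active$role[w]]]
    if (is.null(sampler))
      stop("no oxidation sampler for role '", active$role[w], "'")
    for (fi in seq_len(fields_per_well)) {
      i <- i + 1
      sub_noise <- noise; sub_noise$seed <- seeds[2 * i - 1]
      sc <- scene
      # per-cell biology drawn from the field's companion sub-seed, then
      # passed as plain vectors so geometry is a function of the seed only
      sc$oxidized_fraction <- with_seed(seeds[2 * i], sampler(sc$n_cells))
      if (tmrm_by_role)
        # membrane-potential loss accompanies oxidation in dying cells
        sc$tmrm_level <- pmax(0, 2 * (1 - sc$oxidized_fraction) +
                                with_seed(seeds[2 * i] + 1L,
                                          stats::rnorm(sc$n_cells, 0, 0.1)))
      fr <- generate_field(sc, cal, sub_noise)
      fr$well_id <- active$well_id[w]
      fr$field_index <- fi
      fr$role <- active$role[w]
      fr$field$well_id <- active$well_id[w]
      fr$field$field_index <- fi
      out[[i]] <- fr
      n <- length(fr$truth$true_oxidized_fraction)
      if (n > 0)
        truth_rows[[i]] <- data.frame(
          well_id = active$well_id[w], field_index = fi,
          cell_label = seq_len(n),
          true_oxidized_fraction = fr$truth$true_oxidized_fraction,
          true_ratio = fr$truth$true_ratio,
          true_tmrm = fr$truth$true_tmrm)
    }
  }
  truth_table <- if (length(truth_rows)) do.call(rbind, truth_rows) else NULL
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    for (fr in out) write_field(fr$field, out_dir)
    for (fr in out) {
      stem <- sprintf("%s_%d", fr$well_id, fr$field_index)
      write_label_tiff(fr$truth$nucleus_labels,
                       file.path(out_dir, paste0(stem, "_truth_nuclei.tif")))
      write_label_tiff(fr$truth$cell_labels,
                       file.path(out_dir, paste0(stem, "_truth_cells.tif")))
    }
    if (!is.null(truth_table))
      write_atomic(truth_table, file.path(out_dir, "ground_truth.csv"))
    utils::write.csv(layout, file.path(out_dir, "layout.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  structure(out, truth_table = truth_table, layout = layout,
            class = "synthetic_plate")
}

#' Reference screening-plate conditions
#'
#' Builds the two study conditions used throughout the package's
#' validation:
#' \describe{
#'   \item{\code{crowded}}{a confluent epithelial monolayer — 45 cells per
#'     256x256 field at 17 px center spacing, so cell bodies overlap
#'     heavily while nuclei remain separable; positive-control wells show
#'     a heterogeneous response (80\% responders). This is the regime in
#'     which intensity-only segmentation merges and drops cells.}
#'   \item{\code{sparse}}{a subconfluent field — 16 cells per 256x256
#'     field at 36 px spacing, homogeneous maximum response — in which
#'     both segmentation strategies resolve every cell, so the two
#'     pipeline variants should agree.}
#' }
#'
#' @param kind \code{"crowded"} or \code{"sparse"}.
#' @param seed master seed for the plate.
#' @param n_wells_per_arm wells per control arm (default 10 crowded /
#'   6 sparse).
#' @param cal a \code{\link{probe_calibration}}.
#' @return A plate as returned by \code{\link{generate_plate}}, with the
#'   layout in attribute \code{layout}.
#' @export
demo_screen_plate <- function(kind = c("crowded", "sparse"), seed = 1L,
                              n_wells_per_arm = NULL,
                              cal = probe_calibration()) {
  kind <- match.arg(kind)
  if (is.null(n_wells_per_arm))
    n_wells_per_arm <- if (kind == "crowded") 10L else 6L
  n <- n_wells_per_arm
  layout <- data.frame(
    well_id = sprintf("%s%02d", rep(c("B", "C"), each = n), rep(seq_len(n), 2)),
    role = rep(c("negative_control", "positive_control"), each = n),
    treatment_label = rep(c("mock", "max_response"), each = n),
    concentration = "")
  scene <- if (kind == "crowded")
    scene_spec(n_cells = 45, field_shape = c(256, 256), crowding_px = 17)
  else
    scene_spec(n_cells = 16, field_shape = c(256, 256), crowding_px = 36)
  samplers <- role_oxidation_samplers(
    cal, responder_fraction = if (kind == "crowded") 0.8 else 1.0)
  generate_plate(layout, scene = scene, cal = cal,
                 noise = noise_spec(seed = seed), samplers = samplers)
}
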