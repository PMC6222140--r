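#' Per-pixel 405/488 ratio image
#'
#' Computes the dual-excitation ratio wherever the 488-excited denominator
#' is at or above \code{intensity_floor}; all other pixels are masked
#' invalid (\code{NA}), never 0 or infinite. Inputs must be
#' background-corrected; the ratio is invariant to a common gain on both
#' channels.
#'
#' @param ex405,ex488 background-corrected matrices of the same shape.
#' @param intensity_floor minimum acceptable denominator, counts. The
#'   default convention is 3x the camera read-noise sd (see
#'   \code{\link{default_intensity_floor}}).
#' @return Numeric matrix of ratios with \code{NA} at invalid pixels.
#' @export
ratio_image <- function(ex405, ex488, intensity_floor = 9) {
  if (!identical(dim(ex405), dim(ex488)))
    stop("ex405 and ex488 shapes differ")
  valid <- is.finite(ex488) & ex488 >= intensity_floor
  out <- matrix(NA_real_, nrow(ex405), ncol(ex405))
  out[valid] <- ex405[valid] / ex488[valid]
  out
}

#' Default denominator floor from the camera noise model
#'
#' Three read-noise standard deviations above zero after background
#' subtraction: below that, a 488 pixel is indistinguishable from noise
#' and its ratio is meaningless.
#'
#' @param noise a \code{\link{noise_spec}}.
#' @return Counts.
#' @export
default_intensity_floor <- function(noise) 3 * noise$read_noise_sd

#' Measure per-cell features over ROI label maps
#'
#' For every ROI label: pixel area, background-corrected mean intensity in
#' each channel, granularity, and the 405/488 ratio. The per-cell ratio is
#' the mean of the per-pixel ratios over the ROI's valid pixels (robust to
#' intra-ROI brightness variation); set
#' \code{ratio_of_means = TRUE} for the alternative convention
#' (ratio of the ROI mean intensities). Granularity is the coefficient of
#' variation (sd/mean) of ex488 pixel intensities within the ROI — a
#' simple, scale-free texture statistic.
#'
#' @param rois a \code{\link{label_map}} (kind cell or ring).
#' @param field a \code{\link{field_image}} with background-corrected
#'   channels.
#' @param ratio ratio image from \code{\link{ratio_image}} (same shape).
#' @param ratio_of_means use ratio-of-ROI-means instead of
#'   mean-of-pixel-ratios.
#' @return A \code{data.frame} of cell records, one row per label, columns
#'   as in \code{\link{write_cell_table}}. A cell with no valid ratio
#'   pixels has an \code{NA} ratio (missing, not zero).
#' @export
measure_rois <- function(rois, field, ratio = NULL, ratio_of_means = FALSE) {
  stopifnot(inherits(rois, "label_map"), inherits(field, "field_image"))
  shp <- dim(field$channels[[1]])
  if (!identical(dim(unmap(rois)), shp)) stop("ROI map shape differs from field")
  if (is.null(ratio))
    ratio <- ratio_image(field$channels$ex405, field$channels$ex488)
  labs <- map_labels(rois)
  n <- length(labs)
  lv <- as.integer(rois)
  sel <- lv > 0
  lf <- factor(lv[sel], levels = labs)
  ch_mean <- function(name) {
    if (is.null(field$channels[[name]])) return(rep(NA_real_, n))
    as.numeric(tapply(field$channels[[name]][sel], lf, mean))
  }
  m405 <- ch_mean("ex405"); m488 <- ch_mean("ex488")
  gran <- as.numeric(tapply(field$channels$ex488[sel], lf, function(x) {
    mu <- mean(x); if (mu == 0) NA_real_ else stats::sd(x) / mu
  }))
  rvals <- ratio[sel]
  nvalid <- as.integer(tapply(is.finite(rvals), lf, sum))
  rmean <- if (ratio_of_means) {
    # denominators below the floor are excluded from both means
    ok <- is.finite(rvals)
    num <- tapply(ifelse(ok, field$channels$ex405[sel], NA), lf, mean, na.rm = TRUE)
    den <- tapply(ifelse(ok, field$channels$ex488[sel], NA), lf, mean, na.rm = TRUE)
    as.numeric(num) / as.numeric(den)
  } else as.numeric(tapply(rvals, lf, mean, na.rm = TRUE))
  rmean[nvalid == 0] <- NA_real_
  data.frame(well_id = field$well_id, field_index = field$field_index,
             timepoint_index = field$timepoint_index, cell_label = labs,
             area_px = as.integer(tabulate(lv[sel])[labs]),
             mean_405 = m405, mean_488 = m488,
             mean_nuclear = ch_mean("nuclear"), mean_tmrm = ch_mean("tmrm"),
             granularity = gran, ratio = rmean, n_valid_ratio_px = nvalid)
}

#' Per-well summaries of cell records
#'
#' Aggregates cell records to wells: cell count, ratio mean/sd/median,
#' TMRM mean, and the fraction of cells above a high-ratio gate. The
#' default gate is the negative-control cell mean plus three control
#' standard deviations, recomputed per plate from the layout's
#' negative-control wells.
#'
#' @param records cell records (possibly several fields per well).
#' @param layout plate layout (path or data.frame); wells present in the
#'   layout but without cells are reported with \code{n_cells = 0}.
#' @param high_ratio_gate the gate; \code{NULL} computes the control-based
#'   default (requires negative-control wells with cells).
#' @return A \code{data.frame}, one row per well, with the gate used
#'   stored in attribute \code{high_ratio_gate}.
#' @export
well_summary <- function(records, layout, high_ratio_gate = NULL) {
  layout <- read_layout(layout)
  if (is.null(high_ratio_gate)) {
    neg <- layout$well_id[layout$role == "negative_control"]
    ctrl <- records$ratio[records$well_id %in% neg & is.finite(records$ratio)]
    if (length(ctrl) < 2)
      stop("cannot derive the high-ratio gate: need >= 2 control cells ",
           "with valid ratios in negative_control wells")
    high_ratio_gate <- mean(ctrl) + 3 * stats::sd(ctrl)
  }
  if (high_ratio_gate <= 0) stop("high_ratio_gate must be > 0")
  wells <- layout$well_id[layout$role != "empty"]
  rows <- lapply(wells, function(w) {
    r <- records$ratio[records$well_id == w]
    tm <- records$mean_tmrm[records$well_id == w]
    rv <- r[is.finite(r)]
    data.frame(well_id = w, n_cells = length(r),
               ratio_mean = if (length(rv)) mean(rv) else NA_real_,
               ratio_sd = if (length(rv) >= 2) stats::sd(rv) else NA_real_,
               ratio_median = if (length(rv)) stats::median(rv) else NA_real_,
               tmrm_mean = if (length(tm[is.finite(tm)]))
                 mean(tm[is.finite(tm)]) else NA_real_,
               fraction_high_ratio = if (length(rv))
                 mean(rv > high_ratio_gate) else NA_real_)
  })
  out <- do.call(rbind, rows)
  attr(out, "high_ratio_gate") <- high_ratio_gate
  out
}

#' Pearson correlation of two per-cell measurements
#'
#' Used for the TMRM-intensity vs ratio correlation index: dying cells
#' lose membrane potential as their ratio rises, giving a strong negative
#' correlation.
#'
#' @param x,y numeric vectors of equal length >= 3, finite values.
#' @return Pearson r in \code{[-1, 1]}.
#' @export
correlate <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < 3) stop("need at least 3 paired values")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("values must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: zero variance")
  stats::cor(x, y, method = "pearson")
}
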