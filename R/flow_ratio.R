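#' Per-event dual-excitation ratio
#'
#' Adds \code{ratio = i405 / i488} to a flow event table wherever the
#' 488-excited intensity is at or above \code{intensity_floor}; events
#' below the floor are flagged \code{excluded} (never an infinity).
#'
#' @param table event data.frame with columns \code{event_id},
#'   \code{i405}, \code{i488}, \code{marker}.
#' @param intensity_floor minimum acceptable i488.
#' @return The table with \code{ratio} and \code{excluded} columns added.
#' @export
compute_event_ratio <- function(table, intensity_floor = 1) {
  stopifnot(is.data.frame(table),
            all(c("event_id", "i405", "i488", "marker") %in% names(table)))
  if (anyDuplicated(table$event_id)) stop("event ids must be unique")
  if (any(table$i405 < 0) || any(table$i488 < 0))
    stop("intensities must be non-negative")
  ok <- table$i488 >= intensity_floor
  table$ratio <- ifelse(ok, table$i405 / table$i488, NA_real_)
  table$excluded <- !ok
  table
}

#' Quadrant gating of ratio against a second marker
#'
#' Partitions included events by a ratio threshold and a marker threshold
#' into four quadrant fractions ("high" means strictly above the
#' threshold). Fractions are over included events and sum to 1.
#'
#' @param table output of \code{\link{compute_event_ratio}}.
#' @param ratio_threshold,marker_threshold gate positions (> 0).
#' @return Named numeric vector:
#'   \code{ratio_low_marker_low}, \code{ratio_high_marker_low},
#'   \code{ratio_low_marker_high}, \code{ratio_high_marker_high}.
#' @export
quadrant_gate <- function(table, ratio_threshold, marker_threshold) {
  stopifnot(ratio_threshold > 0, marker_threshold > 0)
  if (!"ratio" %in% names(table))
    table <- compute_event_ratio(table)
  inc <- !table$excluded & is.finite(table$ratio)
  if (!any(inc)) stop("no included events to gate")
  hr <- table$ratio[inc] > ratio_threshold
  hm <- table$marker[inc] > marker_threshold
  c(ratio_low_marker_low = mean(!hr & !hm),
    ratio_high_marker_low = mean(hr & !hm),
    ratio_low_marker_high = mean(!hr & hm),
    ratio_high_marker_high = mean(hr & hm))
}

#' Control-derived default ratio gate
#'
#' Mean + 3 sd of the included control-sample ratios — the convention used
#' for the imaging high-ratio gate, applied to flow events.
#'
#' @param control_table a control sample's event table.
#' @param intensity_floor passed to \code{\link{compute_event_ratio}}.
#' @return Gate value.
#' @export
flow_ratio_gate <- function(control_table, intensity_floor = 1) {
  tab <- compute_event_ratio(control_table, intensity_floor)
  r <- tab$ratio[!tab$excluded & is.finite(tab$ratio)]
  if (length(r) < 2) stop("need >= 2 included control events")
  mean(r) + 3 * stats::sd(r)
}
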