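#' Segmentation parameters
#'
#' The knobs the assay optimizes for spatial distinction of cells:
#' threshold level, dilation width of the perinuclear band, and the
#' pre-dilation erosion of the nucleus.
#'
#' @param threshold_method \code{"otsu"} (default; scale-invariant) or
#'   \code{"fixed"}.
#' @param fixed_threshold counts, used when \code{threshold_method = "fixed"}.
#' @param min_object_area_px objects smaller than this are removed
#'   (suppresses noise specks).
#' @param ring_dilation_width_px width of the perinuclear ring band, pixels.
#' @param nucleus_erosion_px shrink applied to each nucleus before the
#'   ring dilation, pixels.
#' @param split_min_peak_distance_px minimum separation of distance-map
#'   peaks when splitting touching nuclei by watershed.
#' @param smooth_sigma_px Gaussian smoothing applied before thresholding
#'   (pixels; 0 disables). Bridges the mitochondrial speckle texture so a
#'   cell body thresholds as one object instead of fragments.
#' @return An object of class \code{segmentation_params}.
#' @export
segmentation_params <- function(threshold_method = c("otsu", "fixed"),
                                fixed_threshold = 0,
                                min_object_area_px = 50,
                                ring_dilation_width_px = 5,
                                nucleus_erosion_px = 0,
                                split_min_peak_distance_px = 5,
                                smooth_sigma_px = 1.5) {
  threshold_method <- match.arg(threshold_method)
  stopifnot(min_object_area_px >= 1, ring_dilation_width_px >= 0,
            nucleus_erosion_px >= 0, split_min_peak_distance_px >= 1,
            smooth_sigma_px >= 0)
  structure(list(threshold_method = threshold_method,
                 fixed_threshold = fixed_threshold,
                 min_object_area_px = min_object_area_px,
                 ring_dilation_width_px = ring_dilation_width_px,
                 nucleus_erosion_px = nucleus_erosion_px,
                 split_min_peak_distance_px = split_min_peak_distance_px,
                 smooth_sigma_px = smooth_sigma_px),
            class = "segmentation_params")
}

smooth_for_threshold <- function(image, params) {
  if (params$smooth_sigma_px <= 0) return(image)
  as.matrix(EBImage::gblur(EBImage::Image(image),
                           sigma = params$smooth_sigma_px))
}

#' Background subtraction
#'
#' With a background reference image: \code{max(image - reference, 0)}.
#' Without one, a robust scalar background is removed instead: the median
#' of pixels below the Otsu threshold, clamped at zero.
#'
#' @param image numeric intensity matrix.
#' @param reference optional reference matrix of the same shape.
#' @return Corrected matrix (never negative).
#' @export
subtract_background <- function(image, reference = NULL) {
  stopifnot(is.matrix(image))
  if (!is.null(reference)) {
    if (!identical(dim(image), dim(reference)))
      stop("background reference shape differs from image")
    return(pmax(image - reference, 0))
  }
  thr <- otsu_threshold(image)
  below <- image[image < thr]
  bg <- if (length(below)) stats::median(below) else 0
  pmax(image - bg, 0)
}

# Two-class Otsu threshold on the image's own [0, max] range
# (scale-invariant); returns the threshold in image units.
otsu_threshold <- function(image) {
  mx <- max(image)
  if (!is.finite(mx) || mx <= 0 || mx == min(image)) return(Inf)
  as.numeric(EBImage::otsu(EBImage::Image(image / mx), range = c(0, 1))) * mx
}

# Three-class Otsu (two thresholds maximizing between-class variance over
# 256 bins), returning the lower threshold: the middle class counts as
# foreground. With cell-to-cell expression spread the signal histogram is
# multimodal and a single Otsu cut lands between dim and bright cells,
# dropping dim ones; assigning the middle class to foreground keeps them.
# Scale-invariant by construction (bins span [0, max]).
otsu3_threshold <- function(image, levels = 256L) {
  mx <- max(image)
  if (!is.finite(mx) || mx <= 0 || mx == min(image)) return(Inf)
  h <- tabulate(pmin(levels, floor(as.numeric(image) / mx * levels) + 1L),
                nbins = levels)
  p <- h / sum(h)
  mids <- (seq_len(levels) - 0.5) / levels
  cw <- cumsum(p); cm <- cumsum(p * mids)
  best_v <- -Inf; best_t1 <- 1L
  for (t1 in 1:(levels - 2)) {
    w1 <- cw[t1]; m1 <- cm[t1]
    if (w1 == 0) next
    t2 <- (t1 + 1):(levels - 1)
    w2 <- cw[t2] - w1; w3 <- cw[levels] - cw[t2]
    m2 <- cm[t2] - m1; m3 <- cm[levels] - cm[t2]
    ok <- w2 > 0 & w3 > 0
    if (!any(ok)) next
    # global-mean term is constant, so maximize the class-mean sum alone
    v <- m1^2 / w1 + ifelse(ok, m2^2 / w2 + m3^2 / w3, -Inf)
    i <- which.max(v)
    if (v[i] > best_v) { best_v <- v[i]; best_t1 <- t1 }
  }
  best_t1 / levels * mx
}

threshold_value <- function(image, params) {
  if (params$threshold_method == "fixed") params$fixed_threshold
  else otsu3_threshold(image)
}

# drop objects below a minimum area, relabel sequentially in raster order
filter_small <- function(lab, min_area) {
  if (!any(lab > 0)) return(lab)
  counts <- tabulate(lab[lab > 0])
  drop <- which(counts < min_area)
  if (length(drop)) lab[lab %in% drop] <- 0L
  relabel_raster(lab)
}

relabel_raster <- function(lab) {
  pos <- which(lab > 0)
  if (!length(pos)) return(matrix(0L, nrow(lab), ncol(lab)))
  old <- lab[pos]
  first <- tapply(pos, old, min)
  map <- integer(max(old))
  map[as.integer(names(first))[order(first)]] <- seq_along(first)
  out <- matrix(0L, nrow(lab), ncol(lab))
  out[pos] <- map[old]
  out
}

#' Intensity-threshold segmentation on the roGFP channel
#'
#' The simpler of the two strategies: threshold the (background-corrected)
#' 405 nm image, remove small objects, and label 8-connected components.
#' On crowded monolayers, touching cells merge into single objects — the
#' failure mode that motivates nuclear-marker seeding.
#'
#' @param image background-corrected ex405 matrix.
#' @param params a \code{\link{segmentation_params}}.
#' @return A \code{\link{label_map}} of kind \code{cell} (empty for a
#'   blank image).
#' @export
segment_intensity <- function(image, params = segmentation_params()) {
  stopifnot(is.matrix(image))
  sm <- smooth_for_threshold(image, params)
  thr <- threshold_value(sm, params)
  mask <- sm > thr
  if (!any(mask)) return(label_map(matrix(0L, nrow(image), ncol(image)), "cell"))
  mask <- EBImage::fillHull(EBImage::Image(mask * 1)) > 0.5
  lab <- .label8_cpp(matrix(mask, nrow(image), ncol(image)))
  label_map(filter_small(lab, params$min_object_area_px), "cell")
}

#' Nuclear-marker segmentation with watershed splitting
#'
#' Threshold the nuclear (H2B marker) channel, fill holes, then split
#' touching nuclei by watershed on the negated Euclidean distance
#' transform, with basins whose peaks are closer than
#' \code{split_min_peak_distance_px} merged; small objects removed.
#'
#' @param image background-corrected nuclear-channel matrix.
#' @param params a \code{\link{segmentation_params}}.
#' @return A \code{\link{label_map}} of kind \code{nucleus}.
#' @export
segment_nuclei <- function(image, params = segmentation_params()) {
  stopifnot(is.matrix(image))
  sm <- smooth_for_threshold(image, params)
  thr <- threshold_value(sm, params)
  mask <- sm > thr
  if (!any(mask)) return(label_map(matrix(0L, nrow(image), ncol(image)), "nucleus"))
  mask <- EBImage::fillHull(EBImage::Image(mask * 1)) > 0.5
  dm <- EBImage::distmap(EBImage::Image(mask * 1))
  ws <- EBImage::watershed(dm, tolerance = 1,
                           ext = params$split_min_peak_distance_px)
  lab <- matrix(as.integer(EBImage::imageData(ws)), nrow(image), ncol(image))
  label_map(filter_small(lab, params$min_object_area_px), "nucleus")
}

#' Perinuclear ring ROIs
#'
#' For each nucleus k the ring is built by (optionally) eroding the
#' nucleus by \code{nucleus_erosion_px} and taking every non-nucleus pixel
#' whose exact Euclidean distance to the eroded nucleus is at most
#' \code{ring_dilation_width_px} — i.e. morphological dilation with the
#' Euclidean disc, minus all nuclei. A pixel reachable from several nuclei
#' is assigned to the nucleus at the smaller Euclidean distance; exact
#' ties go to the lower label id. Ring labels equal their nucleus labels.
#'
#' @param nuclei a nucleus \code{\link{label_map}}.
#' @param params a \code{\link{segmentation_params}}.
#' @return A \code{\link{label_map}} of kind \code{ring}; empty (with a
#'   warning) when \code{ring_dilation_width_px} is 0.
#' @export
ring_rois <- function(nuclei, params = segmentation_params()) {
  stopifnot(inherits(nuclei, "label_map"))
  if (params$ring_dilation_width_px == 0)
    warning("ring_dilation_width_px = 0: all rings are empty")
  ring <- .ring_rois_cpp(unmap(nuclei), params$ring_dilation_width_px,
                         params$nucleus_erosion_px)
  label_map(ring, "ring")
}

#' Match predicted objects to ground truth
#'
#' One-to-one greedy matching on descending intersection-over-union; a
#' pair counts as matched when its IoU exceeds the threshold. Returns
#' standard precision/recall/F1 plus the per-pair IoU table. When both
#' maps are empty, precision and recall are 1; when only one side is
#' empty they are 0.
#'
#' @param pred,truth \code{\link{label_map}}s of the same shape.
#' @param iou_threshold minimum IoU for a match (default 0.5).
#' @return A list with \code{precision}, \code{recall}, \code{f1},
#'   \code{n_matched}, and \code{iou_table} (pred label, truth label, IoU,
#'   matched flag).
#' @export
match_to_ground_truth <- function(pred, truth, iou_threshold = 0.5) {
  stopifnot(identical(dim(pred), dim(truth)))
  p <- as.integer(pred); t <- as.integer(truth)
  np <- length(unique(p[p > 0])); nt <- length(unique(t[t > 0]))
  if (np == 0 && nt == 0)
    return(list(precision = 1, recall = 1, f1 = 1, n_matched = 0L,
                iou_table = data.frame(pred = integer(), truth = integer(),
                                       iou = numeric(), matched = logical())))
  if (np == 0 || nt == 0)
    return(list(precision = 0, recall = 0, f1 = 0, n_matched = 0L,
                iou_table = data.frame(pred = integer(), truth = integer(),
                                       iou = numeric(), matched = logical())))
  both <- p > 0 & t > 0
  inter <- as.data.frame(table(pred = p[both], truth = t[both]),
                         stringsAsFactors = FALSE)
  inter <- inter[inter$Freq > 0, ]
  inter$pred <- as.integer(inter$pred); inter$truth <- as.integer(inter$truth)
  area_p <- tabulate(p[p > 0]); area_t <- tabulate(t[t > 0])
  inter$iou <- inter$Freq /
    (area_p[inter$pred] + area_t[inter$truth] - inter$Freq)
  ord <- order(-inter$iou, inter$pred, inter$truth)
  inter <- inter[ord, ]
  used_p <- logical(max(inter$pred)); used_t <- logical(max(inter$truth))
  inter$matched <- FALSE
  for (r in seq_len(nrow(inter))) {
    if (inter$iou[r] <= iou_threshold) break
    if (!used_p[inter$pred[r]] && !used_t[inter$truth[r]]) {
      inter$matched[r] <- TRUE
      used_p[inter$pred[r]] <- TRUE; used_t[inter$truth[r]] <- TRUE
    }
  }
  tp <- sum(inter$matched)
  precision <- tp / np; recall <- tp / nt
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  list(precision = precision, recall = recall, f1 = f1, n_matched = tp,
       iou_table = data.frame(pred = inter$pred, truth = inter$truth,
                              iou = inter$iou, matched = inter$matched))
}
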