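#' Read a plate layout table
#'
#' The layout CSV maps wells to their role in the screen. Columns:
#' \code{well_id}, \code{role} (one of \code{negative_control},
#' \code{positive_control}, \code{treatment}, \code{empty}),
#' \code{treatment_label}, \code{concentration}.
#'
#' @param path CSV path, or a data.frame already in layout form.
#' @return A validated layout \code{data.frame}.
#' @export
read_layout <- function(path) {
  layout <- if (is.data.frame(path)) path
  else utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("well_id", "role")
  missing <- setdiff(required, names(layout))
  if (length(missing))
    stop("layout lacks required column(s): ", paste(missing, collapse = ", "))
  if (!"treatment_label" %in% names(layout)) layout$treatment_label <- ""
  if (!"concentration" %in% names(layout)) layout$concentration <- ""
  roles <- c("negative_control", "positive_control", "treatment", "empty")
  bad <- setdiff(unique(layout$role), roles)
  if (length(bad))
    stop("unknown role(s) in layout: ", paste(bad, collapse = ", "),
         " (expected ", paste(roles, collapse = ", "), ")")
  if (anyDuplicated(layout$well_id))
    stop("duplicate well ids in layout")
  layout
}

INTENSITY_CHANNELS <- c("ex405", "ex488", "nuclear", "tmrm")

#' Write one field as per-channel 16-bit TIFF files
#'
#' Files are named \code{{well}_{field}_{channel}.tif} (or
#' \code{{well}_{field}_t{timepoint}_{channel}.tif} for time-lapse).
#' Intensities are stored as 16-bit unsigned grayscale; the roundtrip
#' through \code{\link{read_plate}} is bit-exact.
#'
#' @param field a \code{\link{field_image}} with integer-valued counts in
#'   \code{[0, 65535]}.
#' @param dir output directory (created if needed).
#' @param timelapse include the timepoint in the file name.
#' @return Invisibly, the written paths.
#' @export
write_field <- function(field, dir, timelapse = FALSE) {
  stopifnot(inherits(field, "field_image"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (ch in names(field$channels)) {
    stem <- if (timelapse)
      sprintf("%s_%d_t%03d_%s.tif", field$well_id, field$field_index,
              field$timepoint_index, ch)
    else sprintf("%s_%d_%s.tif", field$well_id, field$field_index, ch)
    p <- file.path(dir, stem)
    m <- field$channels[[ch]]
    if (any(m < 0 | m > 65535)) stop("channel '", ch, "' outside 16-bit range")
    tiff::writeTIFF(round(m) / 65535, p, bits.per.sample = 16L,
                    compression = "none")
    paths <- c(paths, p)
  }
  invisible(paths)
}

read_gray_tiff <- function(path) {
  x <- tiff::readTIFF(path)
  if (length(dim(x)) == 3) {
    if (dim(x)[3] != 1) stop("expected single-plane grayscale TIFF: ", path)
    x <- x[, , 1]
  }
  matrix(round(x * 65535), nrow(x), ncol(x))
}

#' Read a plate directory into field images
#'
#' Scans for files following the \code{{well}_{field}_{channel}.tif}
#' convention (with an optional \code{_tNNN} timepoint tag). Channel
#' identity comes from the file name, never from file order. Every
#' (well, field, timepoint) that has both an \code{ex405} and an
#' \code{ex488} file yields one \code{\link{field_image}}; missing
#' optional channels are tolerated, a missing required channel is an
#' error naming the field and channel.
#'
#' @param root_path directory holding the TIFFs.
#' @param layout optional layout (path or data.frame); wells present in
#'   the layout but absent on disk raise a warning, not an error.
#' @return A list of \code{\link{field_image}} objects.
#' @export
read_plate <- function(root_path, layout = NULL) {
  files <- list.files(root_path, pattern = "\\.tif$", full.names = FALSE)
  pat <- sprintf("^(.+)_([0-9]+)_(?:t([0-9]+)_)?(%s)\\.tif$",
                 paste(INTENSITY_CHANNELS, collapse = "|"))
  m <- regmatches(files, regexec(pat, files))
  keep <- lengths(m) == 5
  info <- do.call(rbind, lapply(m[keep], function(g)
    data.frame(file = g[1], well = g[2], field = as.integer(g[3]),
               timepoint = ifelse(g[4] == "", 1L, as.integer(g[4])),
               channel = g[5])))
  out <- list()
  if (!is.null(info) && nrow(info)) {
    info$key <- paste(info$well, info$field, info$timepoint, sep = "|")
    for (key in unique(info$key)) {
      grp <- info[info$key == key, ]
      chans <- list()
      for (r in seq_len(nrow(grp)))
        chans[[grp$channel[r]]] <- read_gray_tiff(file.path(root_path, grp$file[r]))
      for (req in c("ex405", "ex488"))
        if (is.null(chans[[req]]))
          stop(sprintf("field %s_%d (t %d) lacks required channel '%s'",
                       grp$well[1], grp$field[1], grp$timepoint[1], req))
      shp <- dim(chans[[1]])
      for (nm in names(chans))
        if (!identical(dim(chans[[nm]]), shp))
          stop(sprintf("field %s_%d: channel '%s' shape mismatch",
                       grp$well[1], grp$field[1], nm))
      chans <- chans[intersect(INTENSITY_CHANNELS, names(chans))]
      out[[length(out) + 1]] <- field_image(chans, well_id = grp$well[1],
                                            field_index = grp$field[1],
                                            timepoint_index = grp$timepoint[1])
    }
  }
  if (!is.null(layout)) {
    layout <- read_layout(layout)
    seen <- unique(vapply(out, function(f) f$well_id, character(1)))
    absent <- setdiff(layout$well_id[layout$role != "empty"], seen)
    if (length(absent))
      warning("layout wells with no images: ", paste(absent, collapse = ", "))
  }
  out
}

# canonical per-cell CSV column order
CELL_TABLE_COLUMNS <- c("well_id", "field_index", "timepoint_index",
                        "cell_label", "area_px", "mean_405", "mean_488",
                        "mean_nuclear", "mean_tmrm", "granularity", "ratio",
                        "n_valid_ratio_px")

#' Write / read the per-cell feature table
#'
#' One row per cell; missing values (e.g. a ratio with no valid pixels)
#' are written as empty fields, never as sentinel numbers. The write/read
#' roundtrip reproduces values to 1e-9 (15 significant digits stored).
#'
#' @param records data.frame of cell records (see \code{\link{measure_rois}}).
#' @param path CSV destination.
#' @return Invisibly, \code{path}.
#' @export
write_cell_table <- function(records, path) {
  if (is.null(records) || nrow(records) == 0)
    records <- as.data.frame(sapply(CELL_TABLE_COLUMNS, function(x) logical(0),
                                    simplify = FALSE))
  missing <- setdiff(CELL_TABLE_COLUMNS, names(records))
  if (length(missing))
    stop("cell records lack column(s): ", paste(missing, collapse = ", "))
  out <- records[, CELL_TABLE_COLUMNS]
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) {
    y <- formatC(x, digits = 15, format = "g")
    y[is.na(x)] <- ""
    y
  })
  write_atomic(out, path)
  invisible(path)
}

#' @rdname write_cell_table
#' @export
read_cell_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(well_id = "character"))
}

# atomic CSV write: never leaves a partially-written table behind
write_atomic <- function(df, path, row.names = FALSE) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".csv.tmp")
  utils::write.csv(df, tmp, row.names = row.names, quote = FALSE, na = "")
  file.rename(tmp, path)
}

RATIO_TIFF_SCALE <- 8

#' Write / read a ratio image as 32-bit float TIFF with a validity mask
#'
#' Float TIFF samples are stored normalized by a fixed scale of
#' \code{8} (ratios span about 0.25--2.2); invalid pixels are written as 0
#' and flagged in a sidecar 8-bit mask TIFF (\code{*_mask.tif}, 255 =
#' valid).
#'
#' @param ratio numeric matrix with \code{NA} at invalid pixels.
#' @param path output TIFF path.
#' @return Invisibly, \code{path}. \code{read_ratio_tiff} returns the
#'   matrix with \code{NA} restored.
#' @export
write_ratio_tiff <- function(ratio, path) {
  mask <- is.finite(ratio)
  x <- ifelse(mask, ratio / RATIO_TIFF_SCALE, 0)
  if (any(x > 1 | x < 0)) stop("ratio outside the storable range [0, 8]")
  tiff::writeTIFF(x, path, bits.per.sample = 32L, compression = "none")
  tiff::writeTIFF(ifelse(mask, 1, 0), sub("\\.tif$", "_mask.tif", path),
                  bits.per.sample = 8L, compression = "none")
  invisible(path)
}

#' @rdname write_ratio_tiff
#' @export
read_ratio_tiff <- function(path) {
  x <- tiff::readTIFF(path) * RATIO_TIFF_SCALE
  mpath <- sub("\\.tif$", "_mask.tif", path)
  if (file.exists(mpath)) {
    mask <- tiff::readTIFF(mpath) > 0.5
    x[!mask] <- NA_real_
  }
  matrix(x, nrow(x), ncol(x))
}

#' Write a label map as 16-bit TIFF
#' @param labels a \code{\link{label_map}} (labels must fit in 16 bits).
#' @param path destination.
#' @return Invisibly, \code{path}.
#' @export
write_label_tiff <- function(labels, path) {
  m <- unmap(labels)
  if (any(m > 65535)) stop("labels exceed the 16-bit range")
  tiff::writeTIFF(m / 65535, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' @rdname write_label_tiff
#' @param kind label kind for the returned map.
#' @export
read_label_tiff <- function(path, kind = "cell") {
  label_map(read_gray_tiff(path), kind)
}
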