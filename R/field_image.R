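#' Construct a multichannel field image
#'
#' One imaged field: a named set of equally-shaped 2-D intensity arrays
#' (photon counts). The roGFP channels are named \code{ex405} and
#' \code{ex488} (required by downstream quantification); \code{nuclear}
#' (H2B marker) and \code{tmrm} are optional.
#'
#' @param channels named list of numeric matrices, all the same shape.
#' @param well_id,field_index,timepoint_index identifiers.
#' @param pixel_size_um optional pixel size in micrometres.
#' @return An object of class \code{field_image}.
#' @export
field_image <- function(channels, well_id = NA_character_, field_index = 1L,
                        timepoint_index = 1L, pixel_size_um = NA_real_) {
  stopifnot(is.list(channels), length(channels) >= 1,
            !is.null(names(channels)), all(nzchar(names(channels))))
  shp <- dim(channels[[1]])
  for (nm in names(channels)) {
    ch <- channels[[nm]]
    if (!is.matrix(ch)) stop("channel '", nm, "' is not a matrix")
    if (!identical(dim(ch), shp))
      stop("channel '", nm, "' shape differs from '", names(channels)[1], "'")
    if (any(ch < 0, na.rm = TRUE)) stop("channel '", nm, "' has negative intensities")
  }
  structure(list(channels = channels, well_id = well_id,
                 field_index = as.integer(field_index),
                 timepoint_index = as.integer(timepoint_index),
                 pixel_size_um = pixel_size_um),
            class = "field_image")
}

#' @export
print.field_image <- function(x, ...) {
  shp <- dim(x$channels[[1]])
  cat(sprintf("<field_image %s field %d t %d: %dx%d, channels: %s>\n",
              x$well_id, x$field_index, x$timepoint_index, shp[1], shp[2],
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

# Run code under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive reproducible sub-seeds (< 2^31) from one master seed.
derive_seeds <- function(master_seed, n) {
  with_seed(master_seed, sample.int(.Machine$integer.max - 1L, n))
}
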