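#' Construct a label map
#'
#' A label map is an integer matrix assigning each pixel to an object
#' (labels > 0) or to background (0). Coordinates are 0-based (row, col)
#' with row 0 at the image top when reported as centroids.
#'
#' @param labels integer matrix, values >= 0.
#' @param kind one of \code{"nucleus"}, \code{"cell"}, \code{"ring"}.
#' @return The matrix with class \code{label_map} and a \code{kind} attribute.
#' @export
label_map <- function(labels, kind = c("cell", "nucleus", "ring")) {
  kind <- match.arg(kind)
  stopifnot(is.matrix(labels))
  labels <- matrix(as.integer(round(labels)), nrow(labels), ncol(labels))
  if (any(labels < 0)) stop("label maps are non-negative")
  structure(labels, class = c("label_map", "matrix"), kind = kind)
}

#' @export
print.label_map <- function(x, ...) {
  l <- sort(unique(as.integer(x[x > 0])))
  cat(sprintf("<label_map kind=%s %dx%d, %d object(s)>\n",
              attr(x, "kind"), nrow(x), ncol(x), length(l)))
  invisible(x)
}

#' Labels present in a label map
#' @param x a \code{\link{label_map}}.
#' @return Sorted integer vector of positive labels.
#' @export
map_labels <- function(x) sort(unique(as.integer(x[x > 0])))

# strip class for arithmetic with plain matrices
unmap <- function(x) {
  attr(x, "kind") <- NULL
  class(x) <- NULL
  matrix(as.integer(x), nrow(x), ncol(x))
}

# centroids in 0-based (row, col); one row per label
label_centroids <- function(x) {
  labs <- map_labels(x)
  if (length(labs) == 0)
    return(data.frame(label = integer(), row = numeric(), col = numeric()))
  idx <- which(x > 0, arr.ind = TRUE)
  l <- as.integer(x[x > 0])
  data.frame(label = labs,
             row = as.numeric(tapply(idx[, 1] - 1, l, mean)[as.character(labs)]),
             col = as.numeric(tapply(idx[, 2] - 1, l, mean)[as.character(labs)]))
}
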