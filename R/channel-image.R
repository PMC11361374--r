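#' Single-channel intensity image
#'
#' The basic raster container of the pipeline: a 2D matrix of finite,
#' non-negative intensities (unitless counts) plus a channel name and an
#' optional physical pixel size. Coordinates throughout the package are
#' 1-based `(row, col)`.
#'
#' @param pixels Numeric matrix (rows = image height, columns = width) of
#'   finite, non-negative intensities.
#' @param channel Channel name, e.g. `"dapi"`, `"laminB1"`, `"cgas"`.
#' @param pixel_size Physical units per pixel, or `NA` when uncalibrated
#'   (the default; all measurements are then in pixel units).
#' @return An object of class `channel_image`.
#' @examples
#' img <- channel_image(matrix(0, 32, 32), channel = "dapi")
#' dim(img$pixels)
#' @export
channel_image <- function(pixels, channel = "unknown", pixel_size = NA_real_) {
  pixels <- as_base_matrix(pixels)
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  if (nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop("image must have at least one row and one column", call. = FALSE)
  if (!all(is.finite(pixels)))
    stop("image intensities must be finite", call. = FALSE)
  if (any(pixels < 0))
    stop("image intensities must be non-negative", call. = FALSE)
  structure(
    list(pixels = pixels, channel = as.character(channel)[1],
         pixel_size = as.numeric(pixel_size)[1]),
    class = "channel_image"
  )
}

#' @export
print.channel_image <- function(x, ...) {
  cat(sprintf("<channel_image> channel=%s  %d x %d px  range [%g, %g]\n",
              x$channel, nrow(x$pixels), ncol(x$pixels),
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Integer-labeled object mask
#'
#' A dense label raster sharing geometry with its source image: 0 is
#' background, objects are labeled `1..n_objects` and every label owns at
#' least one pixel.
#'
#' @param labels Integer matrix of object labels (0 = background).
#' @return An object of class `labeled_mask` with fields `labels` and
#'   `n_objects`.
#' @export
labeled_mask <- function(labels) {
  labels <- as_base_matrix(labels)
  if (!is.matrix(labels))
    stop("`labels` must be a matrix", call. = FALSE)
  storage.mode(labels) <- "integer"
  if (any(is.na(labels)) || any(labels < 0L))
    stop("labels must be non-negative integers", call. = FALSE)
  n <- max(labels, 0L)
  present <- sort(unique(labels[labels > 0L]))
  if (n > 0L && !identical(present, seq_len(n)))
    stop("labels must be the contiguous set 1..n_objects (0 = background)",
         call. = FALSE)
  structure(list(labels = labels, n_objects = n), class = "labeled_mask")
}

#' @export
print.labeled_mask <- function(x, ...) {
  cat(sprintf("<labeled_mask> %d x %d px, %d object(s)\n",
              nrow(x$labels), ncol(x$labels), x$n_objects))
  invisible(x)
}

# Internal: strip S4 Image wrappers (EBImage results) down to a base matrix.
as_base_matrix <- function(x) {
  if (isS4(x)) x <- EBImage::imageData(x)
  if (is.matrix(x)) {
    attributes(x) <- list(dim = dim(x))
    return(x)
  }
  x
}
nepheno_imagedata <- as_base_matrix

# Internal: coerce channel_image | matrix to a plain matrix.
as_pixels <- function(img) {
  if (inherits(img, "channel_image")) return(img$pixels)
  if (is.matrix(img) && is.numeric(img)) return(img)
  stop("expected a channel_image or numeric matrix", call. = FALSE)
}

# Internal: coerce labeled_mask | matrix to an integer label matrix.
as_labels <- function(mask) {
  if (inherits(mask, "labeled_mask")) return(mask$labels)
  if (is.matrix(mask)) {
    storage.mode(mask) <- "integer"
    return(mask)
  }
  stop("expected a labeled_mask or integer matrix", call. = FALSE)
}

# Internal: error unless mask and image share geometry.
check_same_shape <- function(a, b, what = "mask and image") {
  if (!identical(dim(a), dim(b)))
    stop(sprintf("%s must share the same shape (%s vs %s)", what,
                 paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x")),
         call. = FALSE)
  invisible(TRUE)
}

# Internal: relabel connected components in raster-scan (row-major) order of
# each component's first pixel, so labelings are reproducible across backends.
relabel_raster_order <- function(labels) {
  storage.mode(labels) <- "integer"
  ids <- sort(unique(labels[labels > 0L]))
  if (length(ids) == 0L) return(labels)
  h <- nrow(labels); w <- ncol(labels)
  # row-major linear index of every pixel
  rowmaj <- (row(labels) - 1L) * w + col(labels)
  first <- vapply(ids, function(l) min(rowmaj[labels == l]), numeric(1))
  ord <- ids[order(first)]
  out <- labels
  for (k in seq_along(ord)) out[labels == ord[k]] <- k
  out
}
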