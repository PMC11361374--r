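#' Read a single-plane grayscale TIFF as a channel image
#'
#' Intensities are loaded losslessly: for 8- and 16-bit integer TIFFs the
#' native integer scale is preserved (0..255 / 0..65535). Multi-plane and
#' RGB/multi-sample files are rejected.
#'
#' @param path Path to a TIFF file.
#' @param channel Channel name to attach to the image.
#' @param pixel_size Optional physical pixel size.
#' @return A [channel_image()].
#' @seealso [write_image()]
#' @export
read_image <- function(path, channel = "unknown", pixel_size = NA_real_) {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  planes <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (length(planes) != 1L)
    stop("unsupported format: multi-plane TIFF (expected a single plane)",
         call. = FALSE)
  px <- planes[[1]]
  if (length(dim(px)) == 3L)
    stop("unsupported format: RGB/multi-sample TIFF (expected grayscale)",
         call. = FALSE)
  storage.mode(px) <- "double"
  channel_image(px, channel = channel, pixel_size = pixel_size)
}

#' Write a channel image as a single-plane grayscale TIFF
#'
#' Intensities are rounded to the nearest integer and written at the
#' requested bit depth; values outside `[0, 2^bits - 1]` are clipped.
#'
#' @param img A [channel_image()] or numeric matrix.
#' @param path Output path.
#' @param bits Bits per sample, 8 or 16 (default).
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path, bits = 16L) {
  px <- as_pixels(img)
  if (!bits %in% c(8L, 16L)) stop("`bits` must be 8 or 16", call. = FALSE)
  top <- 2^bits - 1
  px <- pmin(pmax(round(px), 0), top)
  tiff::writeTIFF(px / top, path, bits.per.sample = as.integer(bits))
  invisible(path)
}

#' Write / read a measurement table as CSV
#'
#' Measurement tables are plain data frames keyed by `(image, label)` where
#' those columns are present; numeric columns round-trip to at least 1e-12
#' relative precision (values are written with full double precision).
#'
#' @param table A data frame.
#' @param path CSV path.
#' @return For `write_table`, `path` invisibly; for `read_table`, a data
#'   frame.
#' @export
write_table <- function(table, path) {
  if (!is.data.frame(table)) stop("`table` must be a data frame", call. = FALSE)
  if (all(c("image", "label") %in% names(table))) {
    key <- paste(table$image, table$label)
    if (anyDuplicated(key))
      stop("duplicate (image, label) keys in measurement table", call. = FALSE)
  }
  utils::write.csv(format_table_full_precision(table), path,
                   row.names = FALSE, quote = TRUE)
  invisible(path)
}

# format numerics at 17 significant digits so read.csv recovers them exactly
format_table_full_precision <- function(table) {
  for (j in seq_along(table)) {
    if (is.double(table[[j]]))
      table[[j]] <- formatC(table[[j]], digits = 17, format = "g")
  }
  table
}

#' @rdname write_table
#' @export
read_table <- function(path) {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  out <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8"),
    error = function(e) stop(sprintf("failed to parse CSV %s: %s",
                                     path, conditionMessage(e)), call. = FALSE),
    warning = function(w) stop(sprintf("failed to parse CSV %s: %s",
                                       path, conditionMessage(w)), call. = FALSE)
  )
  if (all(c("image", "label") %in% names(out))) {
    key <- paste(out$image, out$label)
    if (anyDuplicated(key))
      stop("duplicate (image, label) keys in measurement table", call. = FALSE)
  }
  out
}
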