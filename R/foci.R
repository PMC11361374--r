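#' Parameters for focus (puncta) detection
#'
#' @param feature_size Radius in px of the disk structuring element used by
#'   the white top-hat speckle enhancement; match it to the expected focus
#'   size. Defaults differ by marker convention only (cGAS and PLA share
#'   the detector).
#' @param detection_k Per-nucleus threshold is `median + k * sigma_MAD` of
#'   the enhanced signal inside that nucleus, where `sigma_MAD` is the
#'   normal-consistent median absolute deviation. Robust location/scale is
#'   used (rather than mean/SD) because the foci themselves inflate the
#'   moments: a handful of bright puncta can push `mean + k * SD` above
#'   their own peaks, making bright foci undetectable. Raising `k` never
#'   increases any count.
#' @param min_focus_area,max_focus_area Area gate on candidate components,
#'   px^2 (inclusive).
#' @return A validated parameter object (class `foci_params`).
#' @export
foci_params <- function(feature_size = 5, detection_k = 5,
                        min_focus_area = 2, max_focus_area = 200) {
  p <- list(feature_size = as.numeric(feature_size),
            detection_k = as.numeric(detection_k),
            min_focus_area = as.numeric(min_focus_area),
            max_focus_area = as.numeric(max_focus_area))
  if (p$feature_size < 1) stop("feature_size must be >= 1", call. = FALSE)
  if (p$min_focus_area >= p$max_focus_area)
    stop("min_focus_area must be smaller than max_focus_area", call. = FALSE)
  class(p) <- "foci_params"
  p
}

#' Enhance speckle-like features by white top-hat filtering
#'
#' `img - opening(img, disk(feature_size))`: structures smaller than the
#' disk survive, smooth background (including any constant offset and
#' gentle ramps) maps to ~0. Output is non-negative.
#'
#' @param img A [channel_image()] or numeric matrix.
#' @param feature_size Disk radius in px; the structuring element
#'   (`2 * feature_size + 1` across) must fit inside the image.
#' @return A [channel_image()] of the enhanced signal.
#' @export
enhance_speckles <- function(img, feature_size = 5) {
  px <- as_pixels(img)
  k <- 2 * ceiling(feature_size) + 1
  if (k > min(dim(px)))
    stop("feature_size too large for this image", call. = FALSE)
  brush <- EBImage::makeBrush(k, shape = "disc")
  # EBImage grayscale morphology expects intensities in [0, 1]
  top <- max(px, 1)
  enh <- nepheno_imagedata(EBImage::whiteTopHat(EBImage::Image(px / top), brush)) * top
  channel_image(pmax(enh, 0),
                channel = paste0(if (inherits(img, "channel_image"))
                  img$channel else "img", "_tophat"))
}

#' Detect foci within each nucleus
#'
#' Within every nucleus label, pixels of the enhanced image above that
#' nucleus's own `median + k * sigma_MAD` form candidates; connected
#' components are
#' gated by `[min_focus_area, max_focus_area]` and counted. Nuclei smaller
#' than 10 px are too small for stable statistics and get a missing (`NA`)
#' count rather than 0. Two foci closer than the resolution of the
#' enhancement merge into one component and count once.
#'
#' @param enhanced Output of [enhance_speckles()] (or any channel image).
#' @param nuclei A [labeled_mask()] of nuclei.
#' @param params A [foci_params()].
#' @return A list: `counts` — data frame (`label`, `count`, `NA` for
#'   sub-10-px nuclei); `foci` — data frame (`label`, `area`,
#'   `centroid_row`, `centroid_col`).
#' @export
detect_foci <- function(enhanced, nuclei, params = foci_params()) {
  stopifnot(inherits(params, "foci_params"))
  px <- as_pixels(enhanced)
  lab <- as_labels(nuclei)
  check_same_shape(lab, px, "nuclei mask and enhanced image")
  ids <- sort(unique(lab[lab > 0L]))
  count_rows <- list(); focus_rows <- list()
  for (l in ids) {
    sel <- lab == l
    if (sum(sel) < 10L) {
      count_rows[[length(count_rows) + 1L]] <-
        data.frame(label = l, count = NA_integer_)
      next
    }
    vals <- px[sel]
    thr <- stats::median(vals) + params$detection_k * stats::mad(vals)
    rr <- range(row(lab)[sel]); cc <- range(col(lab)[sel])
    crop_sel <- sel[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
    crop_px <- px[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
    cand <- crop_sel & crop_px > thr
    n <- 0L
    if (any(cand)) {
      comp <- nepheno_imagedata(EBImage::bwlabel(EBImage::Image(cand * 1)))
      storage.mode(comp) <- "integer"
      for (b in sort(unique(comp[comp > 0L]))) {
        bsel <- comp == b
        barea <- sum(bsel)
        if (barea < params$min_focus_area || barea > params$max_focus_area)
          next
        # intensity-weighted centroid within the component
        wts <- crop_px[bsel]
        n <- n + 1L
        focus_rows[[length(focus_rows) + 1L]] <- data.frame(
          label = l, area = barea,
          centroid_row = sum(row(comp)[bsel] * wts) / sum(wts) + rr[1] - 1,
          centroid_col = sum(col(comp)[bsel] * wts) / sum(wts) + cc[1] - 1)
      }
    }
    count_rows[[length(count_rows) + 1L]] <- data.frame(label = l, count = n)
  }
  counts <- if (length(count_rows)) do.call(rbind, count_rows) else
    data.frame(label = integer(), count = integer())
  foci <- if (length(focus_rows)) do.call(rbind, focus_rows) else
    data.frame(label = integer(), area = numeric(),
               centroid_row = numeric(), centroid_col = numeric())
  list(counts = counts, foci = foci)
}

#' Percentage of foci-positive nuclei
#'
#' @param counts Data frame with a `count` column (one row per nucleus) or
#'   the `counts` element of [detect_foci()] output; `NA` counts (nuclei
#'   too small to score) are excluded from the denominator.
#' @return Percentage of nuclei with at least one focus.
#' @export
percent_foci_positive <- function(counts) {
  counts <- extract_counts(counts)
  ok <- !is.na(counts)
  if (!any(ok)) stop("all focus counts are missing", call. = FALSE)
  100 * mean(counts[ok] >= 1L)
}

#' Distribution summary of per-nucleus focus counts
#'
#' @inheritParams percent_foci_positive
#' @return A list with `n`, `mean`, `sd` and the vector of non-missing
#'   per-nucleus `counts`.
#' @export
foci_per_nucleus <- function(counts) {
  counts <- extract_counts(counts)
  ok <- !is.na(counts)
  if (!any(ok)) stop("all focus counts are missing", call. = FALSE)
  x <- counts[ok]
  list(n = length(x), mean = mean(x), sd = stats::sd(x), counts = x)
}

extract_counts <- function(counts) {
  if (is.list(counts) && !is.data.frame(counts) && !is.null(counts$counts))
    counts <- counts$counts
  if (is.data.frame(counts)) counts <- counts$count
  as.numeric(counts)
}
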