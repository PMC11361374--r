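#' Parameters for nucleus segmentation
#'
#' Controls the identify-primary-objects stage: Gaussian smoothing, global
#' thresholding (Otsu by default — applied to the smoothed image over its
#' own intensity range, so segmentation of a bimodal image is invariant to
#' constant offsets), hole filling, an object-area gate, and exclusion of
#' border-touching objects ("touching" means any object pixel in the first
#' or last row or column).
#'
#' @param smoothing_sigma Gaussian sigma in px applied before thresholding
#'   (0 disables smoothing).
#' @param threshold_method `"otsu"` (default) or `"fixed"`.
#' @param fixed_threshold Intensity threshold, required when
#'   `threshold_method = "fixed"`; foreground is strictly above it.
#' @param min_area,max_area Object area gate in px^2 (inclusive bounds).
#' @param exclude_border Drop objects touching the image border.
#' @param fill_holes Fill holes before area filtering, so ring-like lamin
#'   staining segments as a full nucleus.
#' @param declump Apply a distance-transform watershed to split touching
#'   objects (off by default; touching nuclei are otherwise merged).
#' @return A validated parameter object (class `segmentation_params`).
#' @export
segmentation_params <- function(smoothing_sigma = 1,
                                threshold_method = c("otsu", "fixed"),
                                fixed_threshold = NULL,
                                min_area = 200, max_area = 50000,
                                exclude_border = TRUE,
                                fill_holes = TRUE,
                                declump = FALSE) {
  threshold_method <- match.arg(threshold_method)
  p <- list(smoothing_sigma = as.numeric(smoothing_sigma),
            threshold_method = threshold_method,
            fixed_threshold = fixed_threshold,
            min_area = as.numeric(min_area), max_area = as.numeric(max_area),
            exclude_border = isTRUE(exclude_border),
            fill_holes = isTRUE(fill_holes),
            declump = isTRUE(declump))
  if (p$smoothing_sigma < 0)
    stop("smoothing_sigma must be >= 0", call. = FALSE)
  if (p$min_area >= p$max_area)
    stop("min_area must be smaller than max_area", call. = FALSE)
  if (threshold_method == "fixed" && is.null(fixed_threshold))
    stop("fixed_threshold is required when threshold_method = 'fixed'",
         call. = FALSE)
  class(p) <- "segmentation_params"
  p
}

#' Segment nuclei from a grayscale channel
#'
#' Smooths, thresholds, fills holes, labels connected components, applies
#' the area gate, and (optionally) removes border-touching objects. Labels
#' are assigned in raster-scan (row-major) order of each component's first
#' pixel. An all-constant image yields zero objects, not an error.
#'
#' @param img A [channel_image()] or numeric matrix (typically DAPI; lamin
#'   works as a fallback thanks to hole filling).
#' @param params A [segmentation_params()].
#' @return A [labeled_mask()].
#' @export
segment_nuclei <- function(img, params = segmentation_params()) {
  stopifnot(inherits(params, "segmentation_params"))
  px <- as_pixels(img)
  sm <- if (params$smoothing_sigma > 0)
    nepheno_imagedata(EBImage::gblur(px, sigma = params$smoothing_sigma)) else px
  rng <- range(sm)
  if (params$threshold_method == "otsu") {
    if (rng[1] == rng[2])
      return(labeled_mask(matrix(0L, nrow(px), ncol(px))))
    scaled <- (sm - rng[1]) / (rng[2] - rng[1])
    thr01 <- EBImage::otsu(EBImage::Image(scaled), range = c(0, 1), levels = 256)
    binary <- scaled > thr01
  } else {
    binary <- sm > params$fixed_threshold
  }
  if (!any(binary))
    return(labeled_mask(matrix(0L, nrow(px), ncol(px))))
  bin_img <- EBImage::Image(binary * 1)
  if (params$fill_holes) bin_img <- EBImage::fillHull(bin_img)
  lab <- if (params$declump) {
    nepheno_imagedata(EBImage::watershed(EBImage::distmap(bin_img)))
  } else {
    nepheno_imagedata(EBImage::bwlabel(bin_img))
  }
  storage.mode(lab) <- "integer"
  # area gate (inclusive) and border exclusion
  areas <- tabulate(lab[lab > 0L])
  drop <- which(areas < params$min_area | areas > params$max_area)
  if (params$exclude_border) {
    h <- nrow(lab); w <- ncol(lab)
    border_labels <- unique(c(lab[1, ], lab[h, ], lab[, 1], lab[, w]))
    drop <- union(drop, border_labels[border_labels > 0L])
  }
  if (length(drop)) lab[lab %in% drop] <- 0L
  labeled_mask(relabel_raster_order(lab))
}

#' Retain only nuclei positive for a marker channel
#'
#' Mirrors GFP-positive nucleus gating: a nucleus is kept when its mean
#' marker intensity reaches `min_mean_intensity`. Surviving labels keep
#' their original numbers (no renumbering), so records computed before and
#' after gating stay joinable.
#'
#' @param mask A [labeled_mask()] of nuclei.
#' @param marker A [channel_image()] sharing the mask's geometry.
#' @param min_mean_intensity Gate on the per-nucleus mean marker intensity.
#' @return A [labeled_mask()]-like object whose label set is a subset of
#'   the input's (class `gated_mask`, carrying the retained labels).
#' @export
gate_positive_nuclei <- function(mask, marker, min_mean_intensity) {
  lab <- as_labels(mask)
  px <- as_pixels(marker)
  check_same_shape(lab, px, "mask and marker")
  ids <- sort(unique(lab[lab > 0L]))
  if (length(ids)) {
    means <- vapply(ids, function(l) mean(px[lab == l]), numeric(1))
    drop <- ids[means < min_mean_intensity]
    if (length(drop)) lab[lab %in% drop] <- 0L
  }
  structure(list(labels = lab,
                 n_objects = length(unique(lab[lab > 0L])),
                 retained = sort(unique(lab[lab > 0L]))),
            class = c("gated_mask", "labeled_mask"))
}
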