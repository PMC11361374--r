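#' Nuclear form factor
#'
#' Circularity metric `4 * pi * A / P^2`: 1 for a perfect circle
#' (`A = pi r^2`, `P = 2 pi r`) and below 1 for deformed nuclei.
#'
#' @param A Area (px^2 or any consistent unit), > 0.
#' @param P Perimeter (same length unit), > 0.
#' @return The dimensionless form factor. Vectorized over `A` and `P`.
#' @examples
#' form_factor(pi * 50^2, 2 * pi * 50)  # exactly 1
#' form_factor(1, 4)                    # unit square: pi/4
#' @export
form_factor <- function(A, P) {
  if (any(!is.finite(A)) || any(!is.finite(P)) || any(A <= 0) || any(P <= 0))
    stop("area and perimeter must be finite and > 0", call. = FALSE)
  4 * pi * A / P^2
}

#' Crofton perimeter of a binary mask
#'
#' Integral-geometry perimeter estimator: 2x2 pixel configurations of the
#' padded mask are histogrammed and weighted by Crofton intercept
#' coefficients over 4 directions (horizontal, vertical, both diagonals).
#' Unlike naive boundary-pixel counting — which overestimates a circle's
#' perimeter by ~27% and drags the form factor down to ~0.63 — this
#' estimator is within ~1% of `2 pi r` for rasterized disks of radius
#' >= 20 px, preserving the circle-has-form-factor-1 anchor.
#'
#' @param mask Logical or 0/1 matrix; all nonzero pixels count as object.
#' @return Estimated total perimeter of all objects, in pixel units.
#' @export
perimeter_crofton <- function(mask) {
  m <- (as_pixels_or_logical(mask)) > 0
  h <- nrow(m); w <- ncol(m)
  # zero-pad so boundary configurations are counted
  p <- matrix(0L, h + 2L, w + 2L)
  p[2:(h + 1L), 2:(w + 1L)] <- m
  # 2x2 configuration code at (i, j): pixel + 4*left + 2*up + 8*up-left
  hp <- nrow(p); wp <- ncol(p)
  code <- p
  code[, 2:wp] <- code[, 2:wp] + 4L * p[, 1:(wp - 1L)]
  code[2:hp, ] <- code[2:hp, ] + 2L * p[1:(hp - 1L), ]
  code[2:hp, 2:wp] <- code[2:hp, 2:wp] + 8L * p[1:(hp - 1L), 1:(wp - 1L)]
  counts <- tabulate(code + 1L, nbins = 16L)
  r2 <- sqrt(2)
  coefs <- c(0, pi / 4 * (1 + 1 / r2), pi / (4 * r2), pi / (2 * r2),
             0, pi / 4 * (1 + 1 / r2), 0, pi / (4 * r2),
             pi / 4, pi / 2, pi / (4 * r2), pi / (4 * r2),
             pi / 4, pi / 2, 0, 0)
  sum(coefs * counts)
}

as_pixels_or_logical <- function(x) {
  if (is.logical(x)) return(x * 1)
  as_pixels(x)
}

#' Per-nucleus morphometry and channel intensities
#'
#' For every labeled nucleus: area (pixel count), Crofton perimeter, form
#' factor, centroid, a border-touching flag, and the mean intensity of each
#' supplied channel inside the nucleus mask (e.g. nuclear LEMD2 intensity
#' measured inside the DAPI mask).
#'
#' @param mask A [labeled_mask()].
#' @param channels Named list of [channel_image()]s (or a single one);
#'   names default to each image's channel field.
#' @param image_id Identifier copied into the `image` column.
#' @return A data frame with one row per nucleus: `image`, `label`, `area`,
#'   `perimeter`, `form_factor`, `centroid_row`, `centroid_col`,
#'   `border_touching`, and one `mean_<channel>` column per channel.
#' @export
measure_nuclei <- function(mask, channels = list(), image_id = "image") {
  lab <- as_labels(mask)
  if (inherits(channels, "channel_image")) channels <- list(channels)
  ch_names <- names(channels)
  if (is.null(ch_names) && length(channels))
    ch_names <- vapply(channels, function(c) c$channel, character(1))
  for (ch in channels) check_same_shape(lab, as_pixels(ch), "mask and channel")
  ids <- sort(unique(lab[lab > 0L]))
  if (!length(ids)) {
    out <- data.frame(image = character(), label = integer(), area = numeric(),
                      perimeter = numeric(), form_factor = numeric(),
                      centroid_row = numeric(), centroid_col = numeric(),
                      border_touching = logical())
    for (nm in ch_names) out[[paste0("mean_", nm)]] <- numeric()
    return(out)
  }
  h <- nrow(lab); w <- ncol(lab)
  rows <- lapply(ids, function(l) {
    sel <- lab == l
    rr <- range(row(lab)[sel]); cc <- range(col(lab)[sel])
    crop <- sel[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
    A <- sum(sel)
    P <- perimeter_crofton(crop)
    rec <- data.frame(
      image = image_id, label = l, area = A, perimeter = P,
      form_factor = form_factor(A, P),
      centroid_row = mean(row(lab)[sel]), centroid_col = mean(col(lab)[sel]),
      border_touching = rr[1] == 1L || rr[2] == h || cc[1] == 1L || cc[2] == w)
    for (k in seq_along(channels))
      rec[[paste0("mean_", ch_names[k])]] <- mean(as_pixels(channels[[k]])[sel])
    rec
  })
  do.call(rbind, rows)
}

#' Parameters for bleb calling
#'
#' @param min_bleb_area Minimum bleb area in px^2; smaller candidate
#'   components are discarded as false blebs (filter is inclusive: area >=
#'   `min_bleb_area` survives).
#' @param edge_margin Candidates lying entirely within this distance (px)
#'   of the lamin boundary are discarded as edge slivers.
#' @return A validated parameter object (class `bleb_params`).
#' @export
bleb_params <- function(min_bleb_area = 50, edge_margin = 2) {
  p <- list(min_bleb_area = as.numeric(min_bleb_area),
            edge_margin = as.numeric(edge_margin))
  if (p$min_bleb_area < 0 || p$edge_margin < 0)
    stop("min_bleb_area and edge_margin must be >= 0", call. = FALSE)
  class(p) <- "bleb_params"
  p
}

# Greedy maximal-overlap matching of DAPI nuclei to lamin nuclei;
# ties broken by smaller label pair. Returns data.frame(dapi, lamin).
match_nuclei <- function(dapi_lab, lamin_lab) {
  both <- dapi_lab > 0L & lamin_lab > 0L
  if (!any(both)) return(data.frame(dapi = integer(), lamin = integer()))
  ov <- as.data.frame(table(dapi = dapi_lab[both], lamin = lamin_lab[both]),
                      stringsAsFactors = FALSE)
  ov <- ov[ov$Freq > 0, ]
  ov$dapi <- as.integer(ov$dapi); ov$lamin <- as.integer(ov$lamin)
  ov <- ov[order(-ov$Freq, ov$dapi, ov$lamin), ]
  used_d <- integer(); used_l <- integer()
  keep <- logical(nrow(ov))
  for (i in seq_len(nrow(ov))) {
    if (!(ov$dapi[i] %in% used_d) && !(ov$lamin[i] %in% used_l)) {
      keep[i] <- TRUE
      used_d <- c(used_d, ov$dapi[i]); used_l <- c(used_l, ov$lamin[i])
    }
  }
  ov[keep, c("dapi", "lamin")]
}

#' Call nuclear blebs by DAPI-minus-lamin mask subtraction
#'
#' Nuclei are matched across the two channel masks by maximal pixel
#' overlap. For each matched nucleus the lamin object is hole-filled (the
#' lamina is a rim; its interior counts as inside), and the bleb candidate
#' region is the DAPI object minus the filled lamin object — chromatin
#' protruding past the lamina. Candidates are split into connected
#' components; components smaller than `min_bleb_area` or lying entirely
#' within `edge_margin` of the lamin boundary are discarded.
#'
#' @param dapi_mask,lamin_mask [labeled_mask()]s from the two channels.
#' @param params A [bleb_params()].
#' @return A list: `nuclei` — one row per matched DAPI nucleus (`label`,
#'   `lamin_label`, `n_blebs`, `bleb_area_total`); `blebs` — one row per
#'   called bleb (`label`, `area`, `centroid_row`, `centroid_col`);
#'   `unmatched` — DAPI labels with no lamin partner, excluded from bleb
#'   statistics.
#' @export
detect_blebs <- function(dapi_mask, lamin_mask, params = bleb_params()) {
  stopifnot(inherits(params, "bleb_params"))
  dl <- as_labels(dapi_mask); ll <- as_labels(lamin_mask)
  check_same_shape(dl, ll, "DAPI and lamin masks")
  matches <- match_nuclei(dl, ll)
  dapi_ids <- sort(unique(dl[dl > 0L]))
  unmatched <- setdiff(dapi_ids, matches$dapi)
  h <- nrow(dl); w <- ncol(dl)
  nuc_rows <- list(); bleb_rows <- list()
  brush <- if (params$edge_margin > 0)
    EBImage::makeBrush(2 * ceiling(params$edge_margin) + 1, shape = "disc")
  for (i in seq_len(nrow(matches))) {
    d <- matches$dapi[i]; l <- matches$lamin[i]
    sel <- dl == d | ll == l
    rr <- range(row(dl)[sel]); cc <- range(col(dl)[sel])
    # pad the crop so dilation near the box edge behaves
    pad <- ceiling(params$edge_margin) + 1L
    r1 <- max(1L, rr[1] - pad); r2 <- min(h, rr[2] + pad)
    c1 <- max(1L, cc[1] - pad); c2 <- min(w, cc[2] + pad)
    dcrop <- dl[r1:r2, c1:c2, drop = FALSE] == d
    lcrop <- ll[r1:r2, c1:c2, drop = FALSE] == l
    lfill <- nepheno_imagedata(EBImage::fillHull(EBImage::Image(lcrop * 1))) > 0
    cand <- dcrop & !lfill
    if (!any(cand)) {
      nuc_rows[[length(nuc_rows) + 1L]] <-
        data.frame(label = d, lamin_label = l, n_blebs = 0L, bleb_area_total = 0)
      next
    }
    comp <- nepheno_imagedata(EBImage::bwlabel(EBImage::Image(cand * 1)))
    storage.mode(comp) <- "integer"
    near_edge <- if (params$edge_margin > 0)
      nepheno_imagedata(EBImage::dilate(EBImage::Image(lfill * 1), brush)) > 0
    else lfill
    ids <- sort(unique(comp[comp > 0L]))
    kept <- 0L; kept_area <- 0
    for (b in ids) {
      bsel <- comp == b
      barea <- sum(bsel)
      if (barea < params$min_bleb_area) next
      if (all(near_edge[bsel])) next    # sliver hugging the lamin boundary
      kept <- kept + 1L; kept_area <- kept_area + barea
      bleb_rows[[length(bleb_rows) + 1L]] <- data.frame(
        label = d, area = barea,
        centroid_row = mean(row(comp)[bsel]) + r1 - 1,
        centroid_col = mean(col(comp)[bsel]) + c1 - 1)
    }
    nuc_rows[[length(nuc_rows) + 1L]] <-
      data.frame(label = d, lamin_label = l, n_blebs = kept,
                 bleb_area_total = kept_area)
  }
  nuclei <- if (length(nuc_rows)) do.call(rbind, nuc_rows) else
    data.frame(label = integer(), lamin_label = integer(),
               n_blebs = integer(), bleb_area_total = numeric())
  blebs <- if (length(bleb_rows)) do.call(rbind, bleb_rows) else
    data.frame(label = integer(), area = numeric(),
               centroid_row = numeric(), centroid_col = numeric())
  list(nuclei = nuclei[order(nuclei$label), , drop = FALSE],
       blebs = blebs, unmatched = unmatched)
}

#' Percentage of blebbed nuclei
#'
#' A nucleus counts as blebbed when it carries at least one called bleb.
#'
#' @param records Data frame with an `n_blebs` column (one row per
#'   nucleus), or the `nuclei` element of [detect_blebs()] output.
#' @return Percentage in `[0, 100]`.
#' @export
percent_blebbing <- function(records) {
  if (is.list(records) && !is.data.frame(records) && !is.null(records$nuclei))
    records <- records$nuclei
  if (!is.data.frame(records) || !nrow(records))
    stop("need at least one nucleus record", call. = FALSE)
  100 * mean(records$n_blebs >= 1L)
}

#' Summarize morphometry per replicate and condition
#'
#' Computes the replicate-level mean form factor and percentage of blebbing
#' first, then pools replicates into a per-condition mean and SD — the
#' aggregation used for "n = 3 with >300 cells per experiment" designs.
#'
#' @param records Per-nucleus data frame with columns `form_factor`,
#'   `n_blebs` (optional), `condition` and `replicate`.
#' @return A list: `replicate` — per (condition, replicate) means;
#'   `condition` — per condition mean and SD across replicates.
#' @export
summarize_morphometry <- function(records) {
  if (!nrow(records)) stop("need at least one nucleus record", call. = FALSE)
  if (!all(c("condition", "replicate") %in% names(records)))
    stop("records need condition and replicate columns", call. = FALSE)
  sp <- split(records, list(records$condition, records$replicate), drop = TRUE)
  rep_df <- do.call(rbind, lapply(sp, function(d) data.frame(
    condition = d$condition[1], replicate = d$replicate[1],
    n_nuclei = nrow(d),
    mean_form_factor = mean(d$form_factor),
    pct_blebbing = if ("n_blebs" %in% names(d))
      100 * mean(d$n_blebs >= 1L) else NA_real_)))
  rownames(rep_df) <- NULL
  cs <- split(rep_df, rep_df$condition)
  cond_df <- do.call(rbind, lapply(cs, function(d) data.frame(
    condition = d$condition[1], n_replicates = nrow(d),
    mean_form_factor = mean(d$mean_form_factor),
    sd_form_factor = stats::sd(d$mean_form_factor),
    mean_pct_blebbing = mean(d$pct_blebbing),
    sd_pct_blebbing = stats::sd(d$pct_blebbing))))
  rownames(cond_df) <- NULL
  list(replicate = rep_df, condition = cond_df)
}
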