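#' Specification for synthetic two-channel nucleus images
#'
#' Describes the imaging conditions emulated by [make_nucleus_image()] and
#' [make_foci_image()]: elliptical nuclei carrying a lamin-B1 boundary ring,
#' optional chromatin blebs protruding past the ring (DAPI-positive,
#' lamin-negative), optional diffraction-limited marker foci, Gaussian blur
#' and additive Gaussian noise. All geometry is in pixel units.
#'
#' @param image_size `c(height, width)` in pixels.
#' @param n_nuclei Number of nuclei to place (without overlap).
#' @param radius_range `c(min, max)` mean radius of the nuclear ellipse, px.
#'   The semi-axes are `a = r / s`, `b = r * s` with
#'   `s = (1 - ecc^2)^(1/4)`, so the area stays `pi * r^2` at any
#'   eccentricity.
#' @param eccentricity_range `c(min, max)` ellipse eccentricity in `[0, 1)`.
#' @param ring_width Width of the lamin-B1 ring, px; must be smaller than
#'   `min(radius_range)`.
#' @param blebs_per_nucleus Number of blebs planted on each blebbed nucleus.
#' @param bleb_prob Probability that a nucleus carries blebs at all; with
#'   `blebs_per_nucleus = 1` this is the planted blebbing rate.
#' @param bleb_radius_range `c(min, max)` bleb disk radius, px.
#' @param foci_per_nucleus Number of marker foci per nucleus, or a function
#'   `function(n)` returning `n` integer counts (e.g. a Poisson sampler).
#' @param focus_sigma Gaussian sigma of a planted focus, px.
#' @param focus_amplitude Realized (post-blur) peak intensity of a planted
#'   focus above the diffuse marker background; the generator
#'   pre-compensates for blur attenuation, so `focus_amplitude / noise_sd`
#'   is the signal-to-noise ratio of a focus as imaged.
#' @param marker_diffuse Diffuse marker intensity inside nuclei (the
#'   non-punctate pool).
#' @param blur_sigma Gaussian blur applied to both channels, px (0 = none).
#' @param noise_sd SD of additive Gaussian noise (0 = noiseless).
#' @param background_level Constant background intensity.
#' @param nucleus_intensity DAPI intensity inside the nucleus (and blebs).
#' @param ring_intensity Lamin intensity on the ring.
#' @param margin Minimum distance from any nucleus extent to the image
#'   border, px; set to keep synthetic nuclei away from the border unless a
#'   border-touching object is wanted.
#' @param max_place_tries Rejection-sampling retries per nucleus before
#'   placement failure is signaled.
#' @param seed Integer seed; identical spec + seed gives bit-identical
#'   output.
#' @return A validated spec object (class `nucleus_image_spec`).
#' @export
nucleus_image_spec <- function(image_size = c(512L, 512L),
                               n_nuclei = 12L,
                               radius_range = c(18, 26),
                               eccentricity_range = c(0, 0.6),
                               ring_width = 3,
                               blebs_per_nucleus = 0L,
                               bleb_prob = 1,
                               bleb_radius_range = c(6, 9),
                               foci_per_nucleus = 0L,
                               focus_sigma = 1.5,
                               focus_amplitude = 1500,
                               marker_diffuse = 300,
                               blur_sigma = 1,
                               noise_sd = 30,
                               background_level = 200,
                               nucleus_intensity = 3000,
                               ring_intensity = 4000,
                               margin = 4,
                               max_place_tries = 1000L,
                               seed = NULL) {
  radius_range <- rep_len(as.numeric(radius_range), 2L)
  bleb_radius_range <- rep_len(as.numeric(bleb_radius_range), 2L)
  eccentricity_range <- rep_len(as.numeric(eccentricity_range), 2L)
  spec <- list(image_size = as.integer(image_size), n_nuclei = as.integer(n_nuclei),
               radius_range = radius_range,
               eccentricity_range = eccentricity_range,
               ring_width = as.numeric(ring_width),
               blebs_per_nucleus = as.integer(blebs_per_nucleus),
               bleb_prob = as.numeric(bleb_prob),
               bleb_radius_range = bleb_radius_range,
               foci_per_nucleus = foci_per_nucleus,
               focus_sigma = as.numeric(focus_sigma),
               focus_amplitude = as.numeric(focus_amplitude),
               marker_diffuse = as.numeric(marker_diffuse),
               blur_sigma = as.numeric(blur_sigma),
               noise_sd = as.numeric(noise_sd),
               background_level = as.numeric(background_level),
               nucleus_intensity = as.numeric(nucleus_intensity),
               ring_intensity = as.numeric(ring_intensity),
               margin = as.numeric(margin),
               max_place_tries = as.integer(max_place_tries),
               seed = seed)
  if (length(spec$image_size) != 2L || any(spec$image_size < 8L))
    stop("image_size must be c(height, width) with both >= 8", call. = FALSE)
  if (spec$n_nuclei < 0L) stop("n_nuclei must be >= 0", call. = FALSE)
  if (radius_range[1] > radius_range[2] || radius_range[1] <= 0)
    stop("radius_range must be positive and increasing", call. = FALSE)
  if (radius_range[1] <= spec$ring_width)
    stop("min radius must exceed ring_width", call. = FALSE)
  if (eccentricity_range[1] < 0 || eccentricity_range[2] >= 1)
    stop("eccentricity_range must lie in [0, 1)", call. = FALSE)
  if (spec$bleb_prob < 0 || spec$bleb_prob > 1)
    stop("bleb_prob must be a probability", call. = FALSE)
  if (spec$noise_sd < 0 || spec$blur_sigma < 0)
    stop("noise_sd and blur_sigma must be >= 0", call. = FALSE)
  if (spec$nucleus_intensity <= spec$background_level)
    stop("nucleus_intensity must exceed background_level", call. = FALSE)
  class(spec) <- "nucleus_image_spec"
  spec
}

# Logical mask of an ellipse (center cy,cx; semi-axes a,b; orientation theta).
ellipse_mask <- function(h, w, cy, cx, a, b, theta = 0) {
  yy <- matrix(seq_len(h), h, w) - cy
  xx <- matrix(seq_len(w), h, w, byrow = TRUE) - cx
  u <- xx * cos(theta) + yy * sin(theta)
  v <- -xx * sin(theta) + yy * cos(theta)
  (u / a)^2 + (v / b)^2 <= 1
}

# Logical mask of a disk.
disk_mask <- function(h, w, cy, cx, r) {
  yy <- matrix(seq_len(h), h, w) - cy
  xx <- matrix(seq_len(w), h, w, byrow = TRUE) - cx
  yy^2 + xx^2 <= r^2
}

# Rejection-sample non-overlapping nucleus placements.
place_nuclei <- function(spec) {
  h <- spec$image_size[1]; w <- spec$image_size[2]
  bleb_extent <- if (spec$blebs_per_nucleus > 0L && spec$bleb_prob > 0)
    2 * spec$bleb_radius_range[2] else 0
  out <- vector("list", spec$n_nuclei)
  for (i in seq_len(spec$n_nuclei)) {
    placed <- FALSE
    for (try in seq_len(spec$max_place_tries)) {
      r <- stats::runif(1, spec$radius_range[1], spec$radius_range[2])
      ecc <- stats::runif(1, spec$eccentricity_range[1], spec$eccentricity_range[2])
      s <- (1 - ecc^2)^(1 / 4)
      a <- r / s; b <- r * s
      theta <- stats::runif(1, 0, pi)
      ext <- a + bleb_extent          # furthest possible object pixel
      if (2 * (ext + spec$margin) >= min(h, w)) next
      cy <- stats::runif(1, ext + spec$margin, h - ext - spec$margin)
      cx <- stats::runif(1, ext + spec$margin, w - ext - spec$margin)
      ok <- TRUE
      for (p in out[seq_len(i - 1L)]) {
        if (sqrt((cy - p$cy)^2 + (cx - p$cx)^2) < p$ext + ext + 2) { ok <- FALSE; break }
      }
      if (ok) {
        out[[i]] <- list(cy = cy, cx = cx, a = a, b = b, theta = theta,
                         r = r, ecc = ecc, ext = ext)
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop(sprintf("placement failure: could not place nucleus %d in %d tries",
                   i, spec$max_place_tries), call. = FALSE)
  }
  out
}

# Gaussian blur + additive noise applied to a raw intensity raster.
degrade_image <- function(px, spec) {
  if (spec$blur_sigma > 0)
    px <- nepheno_imagedata(EBImage::gblur(px, sigma = spec$blur_sigma))
  if (spec$noise_sd > 0)
    px <- px + matrix(stats::rnorm(length(px), sd = spec$noise_sd),
                      nrow(px), ncol(px))
  pmax(px, 0)
}

#' Generate a two-channel (DAPI + lamin B1) nucleus image with ground truth
#'
#' The DAPI channel is the union of nucleus ellipses and bleb disks attached
#' just outside the ellipse boundary; the lamin channel carries only the
#' elliptical boundary ring, so blebs sit over lamina gaps exactly as bleb
#' calling by DAPI-minus-lamin subtraction assumes. With `blur_sigma = 0`
#' and `noise_sd = 0`, thresholding DAPI strictly above `background_level`
#' recovers the true nucleus-plus-bleb masks pixel for pixel.
#'
#' @param spec A [nucleus_image_spec()].
#' @return A list with `dapi` and `lamin` ([channel_image()]s) and `truth`,
#'   which carries `nucleus_mask` and `bleb_mask` (label matrices, blebs
#'   labeled by owning nucleus), a per-nucleus data frame `nuclei`
#'   (center, semi-axes, `n_blebs`, `border_touching`), and `blebs`
#'   (one row per planted bleb with its true pixel area).
#' @export
make_nucleus_image <- function(spec) {
  stopifnot(inherits(spec, "nucleus_image_spec"))
  run <- function() {
    h <- spec$image_size[1]; w <- spec$image_size[2]
    placements <- place_nuclei(spec)
    nucleus_lab <- matrix(0L, h, w)
    bleb_lab <- matrix(0L, h, w)
    ring_mask <- matrix(FALSE, h, w)
    bleb_rows <- list()
    nuc_rows <- list()
    for (i in seq_along(placements)) {
      p <- placements[[i]]
      outer <- ellipse_mask(h, w, p$cy, p$cx, p$a, p$b, p$theta)
      inner <- ellipse_mask(h, w, p$cy, p$cx,
                            max(p$a - spec$ring_width, 1),
                            max(p$b - spec$ring_width, 1), p$theta)
      nucleus_lab[outer] <- i
      ring_mask <- ring_mask | (outer & !inner)
      n_blebs <- 0L
      if (spec$blebs_per_nucleus > 0L &&
          stats::runif(1) < spec$bleb_prob) {
        n_blebs <- spec$blebs_per_nucleus
        phis <- stats::runif(n_blebs, 0, 2 * pi)
        for (k in seq_len(n_blebs)) {
          rb <- stats::runif(1, spec$bleb_radius_range[1], spec$bleb_radius_range[2])
          # boundary point of the ellipse at parametric angle phi, pushed
          # outward along the boundary normal so most of the disk protrudes
          phi <- phis[k]
          bx <- p$a * cos(phi); by <- p$b * sin(phi)
          nx <- cos(phi) / p$a; ny <- sin(phi) / p$b
          nn <- sqrt(nx^2 + ny^2); nx <- nx / nn; ny <- ny / nn
          bx <- bx + 0.6 * rb * nx; by <- by + 0.6 * rb * ny
          cyk <- p$cy + bx * sin(p$theta) + by * cos(p$theta)
          cxk <- p$cx + bx * cos(p$theta) - by * sin(p$theta)
          disk <- disk_mask(h, w, cyk, cxk, rb)
          bleb_px <- disk & !outer            # protruding chromatin only
          bleb_lab[bleb_px] <- i
          bleb_rows[[length(bleb_rows) + 1L]] <-
            data.frame(nucleus = i, radius = rb,
                       center_row = cyk, center_col = cxk,
                       area = sum(bleb_px))
        }
      }
      touches <- any(outer[1, ]) || any(outer[h, ]) ||
        any(outer[, 1]) || any(outer[, w])
      nuc_rows[[i]] <- data.frame(
        nucleus = i, center_row = p$cy, center_col = p$cx,
        semi_major = p$a, semi_minor = p$b, theta = p$theta,
        radius = p$r, eccentricity = p$ecc,
        area = sum(outer), n_blebs = n_blebs, border_touching = touches)
    }
    dapi_raw <- matrix(spec$background_level, h, w)
    dapi_raw[nucleus_lab > 0L | bleb_lab > 0L] <- spec$nucleus_intensity
    lamin_raw <- matrix(spec$background_level, h, w)
    lamin_raw[ring_mask] <- spec$ring_intensity
    truth <- list(
      nucleus_mask = nucleus_lab,
      bleb_mask = bleb_lab,
      ring_mask = ring_mask,
      nuclei = do.call(rbind, nuc_rows),
      blebs = if (length(bleb_rows)) do.call(rbind, bleb_rows) else
        data.frame(nucleus = integer(), radius = numeric(),
                   center_row = numeric(), center_col = numeric(),
                   area = integer())
    )
    list(dapi = channel_image(degrade_image(dapi_raw, spec), "dapi"),
         lamin = channel_image(degrade_image(lamin_raw, spec), "laminB1"),
         truth = truth)
  }
  if (is.null(spec$seed)) run() else withr::with_seed(spec$seed, run())
}

#' Generate a marker-foci image (cGAS / PLA style) with ground truth
#'
#' Nuclei are drawn as in [make_nucleus_image()] (without blebs); the marker
#' channel carries a diffuse intra-nuclear pool plus Gaussian puncta of
#' `focus_sigma` at the planted coordinates. The signal-to-noise ratio of a
#' focus is `focus_amplitude / noise_sd`.
#'
#' @param spec A [nucleus_image_spec()]; `foci_per_nucleus` may be a fixed
#'   count or a sampling function.
#' @return A list with `marker` and `dapi` channels and `truth` carrying
#'   `nucleus_mask`, per-nucleus `counts`, and `foci` (one row per planted
#'   focus: nucleus, row, col).
#' @export
make_foci_image <- function(spec) {
  stopifnot(inherits(spec, "nucleus_image_spec"))
  run <- function() {
    h <- spec$image_size[1]; w <- spec$image_size[2]
    base <- nucleus_image_spec_copy_noblebs(spec)
    placements <- place_nuclei(base)
    nucleus_lab <- matrix(0L, h, w)
    foci_rows <- list()
    marker_raw <- matrix(spec$background_level, h, w)
    for (i in seq_along(placements)) {
      p <- placements[[i]]
      outer <- ellipse_mask(h, w, p$cy, p$cx, p$a, p$b, p$theta)
      nucleus_lab[outer] <- i
      marker_raw[outer] <- marker_raw[outer] + spec$marker_diffuse
      n_foci <- if (is.function(spec$foci_per_nucleus))
        as.integer(spec$foci_per_nucleus(1L)) else as.integer(spec$foci_per_nucleus)
      if (n_foci > 0L) {
        # sample focus centers well inside the nucleus so centroids stay
        # within the mask even after blur
        shrink <- max(3 * spec$focus_sigma, 2)
        for (k in seq_len(n_foci)) {
          placed_focus <- FALSE
          for (try in seq_len(spec$max_place_tries)) {
            phi <- stats::runif(1, 0, 2 * pi)
            rho <- sqrt(stats::runif(1))
            by <- rho * max(p$b - shrink, 1) * sin(phi)
            bx <- rho * max(p$a - shrink, 1) * cos(phi)
            fy <- p$cy + bx * sin(p$theta) + by * cos(p$theta)
            fx <- p$cx + bx * cos(p$theta) - by * sin(p$theta)
            fr <- round(fy); fc <- round(fx)
            if (fr < 1 || fr > h || fc < 1 || fc > w ||
                nucleus_lab[fr, fc] != i) next
            # minimum spacing so planted foci stay resolvable
            near <- vapply(foci_rows, function(z)
              z$nucleus == i &&
                (z$row - fy)^2 + (z$col - fx)^2 < (6 * spec$focus_sigma)^2,
              logical(1))
            if (!any(near)) { placed_focus <- TRUE; break }
          }
          if (!placed_focus)
            stop(sprintf("placement failure: focus %d in nucleus %d", k, i),
                 call. = FALSE)
          foci_rows[[length(foci_rows) + 1L]] <-
            data.frame(nucleus = i, row = fy, col = fx)
          yy <- matrix(seq_len(h), h, w) - fy
          xx <- matrix(seq_len(w), h, w, byrow = TRUE) - fx
          amp <- spec$focus_amplitude *
            focus_blur_compensation(spec$focus_sigma, spec$blur_sigma)
          marker_raw <- marker_raw + amp *
            exp(-(yy^2 + xx^2) / (2 * spec$focus_sigma^2))
        }
      }
    }
    foci <- if (length(foci_rows)) do.call(rbind, foci_rows) else
      data.frame(nucleus = integer(), row = numeric(), col = numeric())
    counts <- data.frame(nucleus = seq_along(placements),
                         count = as.integer(tabulate(foci$nucleus,
                                                     nbins = length(placements))))
    dapi_raw <- matrix(spec$background_level, h, w)
    dapi_raw[nucleus_lab > 0L] <- spec$nucleus_intensity
    list(marker = channel_image(degrade_image(marker_raw, spec), "marker"),
         dapi = channel_image(degrade_image(dapi_raw, spec), "dapi"),
         truth = list(nucleus_mask = nucleus_lab, counts = counts, foci = foci))
  }
  if (is.null(spec$seed)) run() else withr::with_seed(spec$seed, run())
}

# foci images never carry blebs; drop them so placement margins stay tight
nucleus_image_spec_copy_noblebs <- function(spec) {
  spec$blebs_per_nucleus <- 0L
  spec
}

# Blur attenuates a Gaussian spot's peak by sigma_f^2 / (sigma_f^2 + sigma_b^2)
# (2D convolution of Gaussians); pre-compensate so `focus_amplitude` is the
# realized post-blur peak height and amplitude/noise_sd is the true SNR.
focus_blur_compensation <- function(focus_sigma, blur_sigma) {
  (focus_sigma^2 + blur_sigma^2) / focus_sigma^2
}
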