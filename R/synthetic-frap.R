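#' Single-exponential FRAP recovery model
#'
#' `y = y0 + (a - y0) * (1 - exp(-b * x))`: `y0` is the normalized intensity
#' immediately after the bleach (`x = 0`), `a` the asymptotic plateau, and
#' `b` the recovery rate per second. At `x = log(2)/b` the curve reaches the
#' midpoint `(y0 + a)/2` exactly, which is why the half-time of recovery is
#' `t1/2 = ln(2)/b`.
#'
#' @param x Time since the bleach, seconds (>= 0).
#' @param y0,a,b Model parameters.
#' @return Normalized intensity at `x`.
#' @export
frap_model <- function(x, y0, a, b) y0 + (a - y0) * (1 - exp(-b * x))

#' Specification for simulated FRAP traces
#'
#' Defaults mirror a confocal protocol of 3 pre-bleach scans followed by 90
#' recovery scans at 1 s intervals (93 frames in total), with an
#' instantaneous bleach between frames 3 and 4. The pre-bleach plateau is
#' normalized to 1. Acquisition photobleaching is modeled as an exponential
#' decay (rate `reference_decay_rate`) applied to both the ROI and the
#' unbleached reference region, so dividing by the reference cancels it.
#'
#' @param y0 Normalized intensity at the first post-bleach instant.
#' @param a Asymptotic plateau (>= `y0`).
#' @param b Recovery rate, per second (> 0).
#' @param n_prebleach Pre-bleach frames (default 3).
#' @param n_postbleach Recovery frames (default 90).
#' @param interval Frame interval, seconds (default 1).
#' @param reference_decay_rate Acquisition-photobleaching rate, per second.
#' @param noise_sd SD of additive Gaussian noise on the normalized ROI
#'   intensity.
#' @param roi0,ref0 Raw intensity scales of ROI and reference regions.
#' @param seed Integer seed for the noise.
#' @return A validated spec (class `frap_sim_spec`).
#' @export
frap_sim_spec <- function(y0 = 0.2, a = 0.7, b = 0.1,
                          n_prebleach = 3L, n_postbleach = 90L, interval = 1,
                          reference_decay_rate = 0, noise_sd = 0,
                          roi0 = 1000, ref0 = 1000, seed = NULL) {
  spec <- list(y0 = y0, a = a, b = b,
               n_prebleach = as.integer(n_prebleach),
               n_postbleach = as.integer(n_postbleach),
               interval = as.numeric(interval),
               reference_decay_rate = as.numeric(reference_decay_rate),
               noise_sd = as.numeric(noise_sd),
               roi0 = as.numeric(roi0), ref0 = as.numeric(ref0), seed = seed)
  if (spec$b <= 0) stop("b must be > 0", call. = FALSE)
  if (spec$y0 < 0 || spec$y0 > spec$a)
    stop("require 0 <= y0 <= a", call. = FALSE)
  if (spec$n_prebleach < 1L || spec$n_postbleach < 1L || spec$interval <= 0)
    stop("frame counts must be >= 1 and interval > 0", call. = FALSE)
  if (spec$noise_sd < 0 || spec$reference_decay_rate < 0)
    stop("noise_sd and reference_decay_rate must be >= 0", call. = FALSE)
  class(spec) <- "frap_sim_spec"
  spec
}

#' FRAP trace container
#'
#' @param t Frame times, seconds, strictly increasing.
#' @param roi ROI intensity per frame.
#' @param reference Unbleached-reference intensity per frame.
#' @param n_prebleach Number of leading pre-bleach frames (>= 1).
#' @return An object of class `frap_trace`.
#' @export
frap_trace <- function(t, roi, reference, n_prebleach) {
  if (length(t) != length(roi) || length(t) != length(reference))
    stop("t, roi and reference must have equal length", call. = FALSE)
  if (any(diff(t) <= 0)) stop("t must be strictly increasing", call. = FALSE)
  n_prebleach <- as.integer(n_prebleach)
  if (n_prebleach < 1L || n_prebleach >= length(t))
    stop("n_prebleach must be in [1, n_frames - 1]", call. = FALSE)
  structure(list(t = as.numeric(t), roi = as.numeric(roi),
                 reference = as.numeric(reference), n_prebleach = n_prebleach),
            class = "frap_trace")
}

#' Simulate a FRAP trace with known kinetics
#'
#' Pre-bleach frames sit at the normalized plateau 1; post-bleach frames
#' follow [frap_model()] with recovery time restarting at 0 at the first
#' post-bleach frame. Both regions decay at `reference_decay_rate`, and
#' Gaussian noise of `noise_sd` (normalized units) is added to the ROI.
#'
#' @param spec A [frap_sim_spec()].
#' @return A [frap_trace()] of `n_prebleach + n_postbleach` frames.
#' @export
simulate_frap <- function(spec) {
  stopifnot(inherits(spec, "frap_sim_spec"))
  run <- function() {
    n <- spec$n_prebleach + spec$n_postbleach
    t <- (seq_len(n) - 1) * spec$interval
    x <- c(rep(NA_real_, spec$n_prebleach),
           (seq_len(spec$n_postbleach) - 1) * spec$interval)
    y <- c(rep(1, spec$n_prebleach),
           frap_model(x[-seq_len(spec$n_prebleach)], spec$y0, spec$a, spec$b))
    fade <- exp(-spec$reference_decay_rate * t)
    roi <- y * spec$roi0 * fade
    if (spec$noise_sd > 0)
      roi <- roi + stats::rnorm(n, sd = spec$noise_sd * spec$roi0) * fade
    reference <- spec$ref0 * fade
    frap_trace(t, roi, reference, spec$n_prebleach)
  }
  if (is.null(spec$seed)) run() else withr::with_seed(spec$seed, run())
}
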