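#' Bleach-correct and normalize a FRAP trace
#'
#' Double normalization: the ROI intensity is divided frame-by-frame by the
#' unbleached reference region (cancelling acquisition photobleaching),
#' then scaled so the mean of the pre-bleach corrected values is 1. The
#' returned series contains only post-bleach frames, with recovery time `x`
#' restarting at 0 at the first post-bleach frame. Correcting an
#' already-corrected series (unit reference) changes nothing.
#'
#' @param trace A [frap_trace()].
#' @return A data frame with columns `x` (s since bleach) and `y`
#'   (normalized intensity), with attribute `prebleach` holding the
#'   normalized pre-bleach values.
#' @export
bleach_correct <- function(trace) {
  stopifnot(inherits(trace, "frap_trace"))
  if (any(trace$reference <= 0))
    stop("reference intensities must be > 0", call. = FALSE)
  corr <- trace$roi / trace$reference
  pre <- seq_len(trace$n_prebleach)
  scale <- mean(corr[pre])
  if (scale <= 0) stop("pre-bleach mean must be > 0", call. = FALSE)
  y <- corr / scale
  post <- (trace$n_prebleach + 1L):length(corr)
  out <- data.frame(x = trace$t[post] - trace$t[post[1]], y = y[post])
  attr(out, "prebleach") <- y[pre]
  out
}

#' Fit the exponential FRAP recovery model
#'
#' Nonlinear least squares of `y = y0 + (a - y0) * (1 - exp(-b * x))` over
#' a bleach-corrected series, with bounds `y0, a` in `[0, 1.5]` and `b > 0`.
#' Start values: `y0` = first post-bleach value, `a` = mean of the last 5
#' values, `b` from a log-linear fit of the residual fraction
#' `(a - y)/(a - y0)`. Derived quantities: half-time `t1/2 = ln(2)/b`
#' (always, for converged fits) and the immobile fraction percentage —
#' `a * 100` under the `"paper"` convention, `(1 - a) * 100` under the
#' `"conventional"` one (for a 0-to-1-normalized curve the plateau `a` is
#' conventionally the mobile fraction; both are exposed).
#'
#' @param corrected Data frame with columns `x`, `y` (see
#'   [bleach_correct()]); at least 10 post-bleach points.
#' @param immobile_convention `"paper"` (default) or `"conventional"`.
#' @return An object of class `frap_fit`: `y0`, `a`, `b`,
#'   `immobile_fraction_pct`, `t_half`, `rss`, `converged`. When the
#'   optimizer fails, `converged` is `FALSE` and derived fields are `NA`.
#' @export
fit_recovery <- function(corrected,
                         immobile_convention = c("paper", "conventional")) {
  immobile_convention <- match.arg(immobile_convention)
  x <- corrected$x; y <- corrected$y
  if (length(x) < 10L)
    stop("need at least 10 post-bleach points", call. = FALSE)
  y0_init <- min(max(y[1], 0), 1.5)
  a_init <- min(max(mean(utils::tail(y, 5)), y0_init + 1e-3), 1.5)
  frac <- (a_init - y) / max(a_init - y0_init, 1e-6)
  usable <- frac > 1e-3 & x > 0
  b_init <- if (sum(usable) >= 2) {
    sl <- unname(stats::coef(stats::lm(log(frac[usable]) ~ x[usable]))[2])
    if (is.finite(sl) && sl < 0) -sl else 0.1
  } else 0.1
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ y0 + (a - y0) * (1 - exp(-b * x)),
      start = list(y0 = y0_init, a = a_init, b = b_init),
      lower = c(0, 0, 1e-9), upper = c(1.5, 1.5, Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(y0 = NA_real_, a = NA_real_, b = NA_real_,
                          immobile_fraction_pct = NA_real_, t_half = NA_real_,
                          rss = NA_real_, converged = FALSE,
                          immobile_convention = immobile_convention),
                     class = "frap_fit"))
  }
  cf <- stats::coef(fit)
  if_pct <- if (immobile_convention == "paper") 100 * cf[["a"]]
  else 100 * (1 - cf[["a"]])
  structure(list(y0 = cf[["y0"]], a = cf[["a"]], b = cf[["b"]],
                 immobile_fraction_pct = if_pct,
                 t_half = log(2) / cf[["b"]],
                 rss = sum(stats::resid(fit)^2), converged = TRUE,
                 immobile_convention = immobile_convention),
            class = "frap_fit")
}

#' @export
print.frap_fit <- function(x, ...) {
  if (x$converged)
    cat(sprintf(
      "<frap_fit> y0=%.4f a=%.4f b=%.4f /s  IF%%=%.1f  t1/2=%.2f s (rss %.3g)\n",
      x$y0, x$a, x$b, x$immobile_fraction_pct, x$t_half, x$rss))
  else cat("<frap_fit> not converged\n")
  invisible(x)
}

#' Summarize FRAP fits per condition
#'
#' Mean and SD of the immobile-fraction percentage and half-time over
#' converged fits per condition; non-converged fits are excluded and
#' counted. With exactly two conditions, a two-tailed unpaired t test
#' compares them on both quantities.
#'
#' @param fits List of [fit_recovery()] results.
#' @param condition Condition label per fit.
#' @return A list: `summary` — per-condition data frame (`n`,
#'   `n_converged`, mean/SD of `immobile_fraction_pct` and `t_half`);
#'   `tests` — t-test results for two-condition designs, else `NULL`.
#' @export
summarize_frap <- function(fits, condition) {
  if (length(fits) != length(condition))
    stop("one condition label per fit required", call. = FALSE)
  conv <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
  if (!any(conv)) stop("no converged fits", call. = FALSE)
  df <- data.frame(
    condition = as.character(condition),
    converged = conv,
    immobile_fraction_pct = vapply(fits, function(f) f$immobile_fraction_pct,
                                   numeric(1)),
    t_half = vapply(fits, function(f) f$t_half, numeric(1)))
  sp <- split(df, df$condition)
  summary <- do.call(rbind, lapply(sp, function(d) {
    dc <- d[d$converged, ]
    data.frame(condition = d$condition[1], n = nrow(d),
               n_converged = nrow(dc),
               mean_if_pct = mean(dc$immobile_fraction_pct),
               sd_if_pct = stats::sd(dc$immobile_fraction_pct),
               mean_t_half = mean(dc$t_half),
               sd_t_half = stats::sd(dc$t_half))
  }))
  rownames(summary) <- NULL
  tests <- NULL
  conds <- unique(df$condition)
  if (length(conds) == 2L) {
    d1 <- df[df$condition == conds[1] & df$converged, ]
    d2 <- df[df$condition == conds[2] & df$converged, ]
    if (nrow(d1) >= 2 && nrow(d2) >= 2) {
      tests <- list(
        immobile_fraction = t_test(d1$immobile_fraction_pct,
                                   d2$immobile_fraction_pct, paired = FALSE),
        t_half = t_test(d1$t_half, d2$t_half, paired = FALSE))
    }
  }
  list(summary = summary, tests = tests)
}
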