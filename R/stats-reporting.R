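#' Significance stars
#'
#' Legend convention: ns > 0.05, * < 0.05, ** < 0.01, *** < 0.001,
#' **** < 0.0001.
#'
#' @param p P-value(s) in `[0, 1]`.
#' @return Character vector of star codes.
#' @export
significance_stars <- function(p) {
  vapply(p, function(pi) {
    if (is.na(pi)) return(NA_character_)
    if (pi < 1e-4) "****" else if (pi < 1e-3) "***" else if (pi < 1e-2) "**"
    else if (pi < 0.05) "*" else "ns"
  }, character(1))
}

#' Two-tailed two-sample t test
#'
#' Student's pooled-variance unpaired test by default (matching the named
#' test of the figure legends), paired test on request, Welch's correction
#' behind the `welch` flag. Degenerate data (zero variance everywhere) is
#' resolved by convention: equal means give p = 1, unequal means p = 0.
#'
#' @param x,y Numeric vectors (>= 2 values each; equal lengths when
#'   `paired`).
#' @param paired Paired test?
#' @param welch Use Welch's unequal-variance correction (unpaired only)?
#' @return A `test_result` list: `test`, `statistic`, `df`, `p_value`,
#'   `stars`, `estimate` (mean difference).
#' @export
t_test <- function(x, y, paired = FALSE, welch = FALSE) {
  if (length(x) < 2L || length(y) < 2L)
    stop("each group needs at least 2 values", call. = FALSE)
  if (paired && length(x) != length(y))
    stop("paired test requires equal-length groups", call. = FALSE)
  degenerate <- if (paired) stats::var(x - y) == 0 else
    stats::var(x) == 0 && stats::var(y) == 0
  if (degenerate) {
    delta <- if (paired) mean(x - y) else mean(x) - mean(y)
    p <- if (isTRUE(all.equal(delta, 0))) 1 else 0
    return(new_test_result(
      test = if (paired) "paired t" else "unpaired t",
      statistic = if (p == 1) 0 else sign(delta) * Inf,
      df = NA_real_, p_value = p, estimate = delta))
  }
  ht <- stats::t.test(x, y, paired = paired,
                      var.equal = !paired && !welch,
                      alternative = "two.sided")
  new_test_result(
    test = if (paired) "paired t" else if (welch) "welch t" else "unpaired t",
    statistic = unname(ht$statistic), df = unname(ht$parameter),
    p_value = ht$p.value,
    estimate = if (paired) unname(ht$estimate) else
      unname(ht$estimate[1] - ht$estimate[2]))
}

new_test_result <- function(test, statistic, df, p_value, estimate,
                            comparison = NA_character_) {
  structure(list(test = test, statistic = statistic, df = df,
                 p_value = p_value, stars = significance_stars(p_value),
                 estimate = estimate, comparison = comparison),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<%s> statistic=%.4g df=%s p=%.4g %s\n", x$test, x$statistic,
              format(x$df), x$p_value, x$stars))
  invisible(x)
}

#' One-way ANOVA with Tukey's post hoc test
#'
#' Fits a one-way ANOVA over >= 3 groups and follows with Tukey's honest
#' significant difference over all pairs (studentized-range adjusted
#' p-values). With zero residual variance the F statistic is undefined;
#' the result is then flagged invalid rather than raising an error.
#'
#' @param values Numeric vector of measurements.
#' @param groups Group labels, same length; >= 3 groups with >= 2 values
#'   each.
#' @return A list: `valid`; `anova` (`F`, `df1`, `df2`, `p_value`);
#'   `pairwise` — data frame of Tukey comparisons (`comparison`, `diff`,
#'   `p_adj`, `stars`).
#' @export
anova_tukey <- function(values, groups) {
  groups <- as.factor(groups)
  if (nlevels(groups) < 3L)
    stop("need at least 3 groups (use t_test for two)", call. = FALSE)
  if (length(values) != length(groups))
    stop("values and groups must have equal length", call. = FALSE)
  if (min(table(groups)) < 2L)
    stop("each group needs at least 2 values", call. = FALSE)
  d <- data.frame(value = values, group = groups)
  fit <- stats::aov(value ~ group, data = d)
  an <- summary(fit)[[1]]
  ms_resid <- an["Residuals", "Mean Sq"]
  # zero total variance leaves only rounding noise in the mean squares
  degenerate <- stats::var(values) == 0 || !is.finite(ms_resid) ||
    ms_resid == 0
  if (degenerate) {
    return(list(valid = FALSE, anova = NULL, pairwise = NULL,
                reason = "zero residual variance: F undefined"))
  }
  tk <- stats::TukeyHSD(fit)$group
  pairwise <- data.frame(comparison = rownames(tk),
                         diff = tk[, "diff"],
                         p_adj = tk[, "p adj"],
                         stars = significance_stars(tk[, "p adj"]),
                         row.names = NULL)
  list(valid = TRUE,
       anova = list(F = an["group", "F value"],
                    df1 = an["group", "Df"], df2 = an["Residuals", "Df"],
                    p_value = an["group", "Pr(>F)"]),
       pairwise = pairwise)
}

#' Replicate-first aggregation of single-cell measurements
#'
#' Computes the chosen statistic per (condition, replicate) first, then
#' summarizes conditions as mean and SD over replicate values — so that
#' condition-level tests use the number of independent experiments as n,
#' not the pooled cell count (which would pseudo-replicate). With exactly
#' two conditions and >= 2 replicates each, a two-tailed unpaired t test on
#' the replicate values is attached.
#'
#' @param measurements Data frame with columns `value`, `condition`,
#'   `replicate`.
#' @param statistic Function mapping a replicate's values to one number
#'   (default `mean`; use e.g. `function(v) 100 * mean(v >= 1)` for a
#'   percentage).
#' @return A list: `replicate` — per (condition, replicate) statistic;
#'   `condition` — mean/SD over replicates (`sd` is `NA` with a single
#'   replicate); `test` — [t_test()] result or `NULL`.
#' @export
aggregate_replicates <- function(measurements, statistic = mean) {
  need <- c("value", "condition", "replicate")
  if (!all(need %in% names(measurements)))
    stop("measurements need value, condition and replicate columns",
         call. = FALSE)
  if (!nrow(measurements)) stop("no measurements", call. = FALSE)
  sp <- split(measurements, list(measurements$condition,
                                 measurements$replicate), drop = TRUE)
  rep_df <- do.call(rbind, lapply(sp, function(d) data.frame(
    condition = d$condition[1], replicate = d$replicate[1],
    n = nrow(d), value = statistic(d$value))))
  rep_df <- rep_df[order(rep_df$condition, rep_df$replicate), ]
  rownames(rep_df) <- NULL
  cond_df <- do.call(rbind, lapply(split(rep_df, rep_df$condition),
                                   function(d) data.frame(
    condition = d$condition[1], n_replicates = nrow(d),
    mean = mean(d$value),
    sd = if (nrow(d) > 1) stats::sd(d$value) else NA_real_)))
  rownames(cond_df) <- NULL
  test <- NULL
  conds <- unique(rep_df$condition)
  if (length(conds) == 2L) {
    v1 <- rep_df$value[rep_df$condition == conds[1]]
    v2 <- rep_df$value[rep_df$condition == conds[2]]
    if (length(v1) >= 2 && length(v2) >= 2) test <- t_test(v1, v2)
  }
  list(replicate = rep_df, condition = cond_df, test = test)
}
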