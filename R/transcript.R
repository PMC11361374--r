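#' Median-of-ratios size factors
#'
#' The per-sample size factor is the median, over usable genes, of the
#' ratio of that sample's count to the gene's geometric mean across
#' samples. Usable genes are those with strictly positive counts in every
#' sample (their geometric mean is positive). Scaling one sample's counts
#' by `c` scales its factor by `c` and no other.
#'
#' @param counts Non-negative integer matrix, genes x samples (>= 2
#'   samples).
#' @return Positive numeric vector of length `ncol(counts)`, named by
#'   sample.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2L) stop("need at least 2 samples", call. = FALSE)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  logc <- log(counts)
  loggeo <- rowMeans(logc)
  usable <- is.finite(loggeo)
  if (!any(usable))
    stop("no usable genes: every gene has a zero count in some sample",
         call. = FALSE)
  sf <- apply(logc[usable, , drop = FALSE], 2,
              function(col) exp(stats::median(col - loggeo[usable])))
  stats::setNames(sf, colnames(counts))
}

#' Per-gene fold change and p-value (pluggable default test)
#'
#' A deliberately simple default DE engine: counts are normalized by the
#' supplied (or computed) size factors; the log2 fold change contrasts
#' group-2 vs group-1 normalized means with a pseudocount of 0.5, and the
#' p-value comes from a two-sided Welch t test on `log2(normalized + 0.5)`
#' per gene. Any externally computed table with `gene`, `log2fc`, `pvalue`
#' columns can be used downstream instead ([bh_adjust()], [de_subset()]
#' are table-in/table-out).
#'
#' @param counts Genes x samples matrix of non-negative counts.
#' @param groups Two-level factor (or coercible) of length `ncol(counts)`,
#'   >= 2 samples per group.
#' @param sf Optional size factors; computed by [size_factors()] when
#'   `NULL`.
#' @return Data frame: `gene`, `base_mean` (mean normalized count),
#'   `log2fc`, `pvalue`.
#' @export
per_gene_test <- function(counts, groups, sf = NULL) {
  counts <- as.matrix(counts)
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L)
    stop("exactly two groups required", call. = FALSE)
  if (length(groups) != ncol(counts))
    stop("one group label per sample required", call. = FALSE)
  if (min(table(groups)) < 2L)
    stop("each group needs at least 2 samples", call. = FALSE)
  if (is.null(sf)) sf <- size_factors(counts)
  norm <- sweep(counts, 2, sf, `/`)
  g1 <- groups == levels(groups)[1]
  m1 <- rowMeans(norm[, g1, drop = FALSE])
  m2 <- rowMeans(norm[, !g1, drop = FALSE])
  log2fc <- log2((m2 + 0.5) / (m1 + 0.5))
  logn <- log2(norm + 0.5)
  pvalue <- apply(logn, 1, function(v) {
    x <- v[g1]; y <- v[!g1]
    if (stats::var(x) == 0 && stats::var(y) == 0)
      return(if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
    stats::t.test(x, y)$p.value
  })
  data.frame(gene = rownames(counts) %||% sprintf("gene_%05d", seq_len(nrow(counts))),
             base_mean = (m1 + m2) / 2, log2fc = log2fc, pvalue = unname(pvalue))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment: sorted ascending,
#' `padj_(i) = min over k >= i of p_(k) * m / k`, capped at 1, returned in
#' the input order.
#'
#' @param pvalues Numeric vector in `[0, 1]`, no missing values.
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0) || any(pvalues > 1))
    stop("p-values must lie in [0, 1] with no missing values", call. = FALSE)
  stats::p.adjust(pvalues, method = "BH")
}

#' Subset significantly regulated genes
#'
#' The published filter: adjusted p-value strictly below `padj_max` and
#' |log2 fold change| strictly above `lfc_min` (genes exactly at either
#' threshold are excluded). Up- and down-regulated lists are disjoint by
#' construction.
#'
#' @param results Data frame with `gene`, `log2fc`, `padj` columns (if
#'   `padj` is absent but `pvalue` is present, BH adjustment is applied).
#' @param padj_max Adjusted-p cutoff (default 0.001).
#' @param lfc_min Absolute log2-fold-change cutoff (default 2).
#' @return A list: `up` and `down` gene vectors, plus `results` with
#'   `padj` and a `call` column in `{"up", "down", "ns"}`.
#' @export
de_subset <- function(results, padj_max = 0.001, lfc_min = 2) {
  if (!all(c("gene", "log2fc") %in% names(results)))
    stop("results need gene and log2fc columns", call. = FALSE)
  if (!"padj" %in% names(results)) {
    if (!"pvalue" %in% names(results))
      stop("results need a padj (or pvalue) column", call. = FALSE)
    results$padj <- bh_adjust(results$pvalue)
  }
  up <- results$padj < padj_max & results$log2fc > lfc_min
  down <- results$padj < padj_max & results$log2fc < -lfc_min
  results$call <- ifelse(up, "up", ifelse(down, "down", "ns"))
  list(up = results$gene[up], down = results$gene[down], results = results)
}
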