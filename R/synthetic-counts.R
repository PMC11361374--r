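#' Specification for simulated RNA-seq count matrices
#'
#' Two-group negative-binomial count matrices with sample-specific size
#' factors and a planted set of differentially expressed genes. The NB is
#' parameterized by mean and dispersion with variance `mu + dispersion *
#' mu^2`; `dispersion = 0` collapses to Poisson. Baseline gene means are
#' log-normal.
#'
#' @param n_genes Number of genes.
#' @param n_samples_per_group Samples in each of the two groups.
#' @param size_factors Positive per-sample scaling factors (length
#'   `2 * n_samples_per_group`); default all 1.
#' @param mean_meanlog,mean_sdlog Log-normal parameters of baseline gene
#'   means.
#' @param dispersion Shared NB dispersion (>= 0).
#' @param de_fraction Fraction of genes planted as differentially
#'   expressed (group 2 mean scaled by `2^planted_log2fc`).
#' @param planted_log2fc Planted log2 fold change (group 2 vs group 1).
#' @param seed Integer seed.
#' @return A validated spec (class `count_sim_spec`).
#' @export
count_sim_spec <- function(n_genes = 5000L, n_samples_per_group = 3L,
                           size_factors = NULL,
                           mean_meanlog = log(100), mean_sdlog = 1.5,
                           dispersion = 0.05,
                           de_fraction = 0, planted_log2fc = 2,
                           seed = NULL) {
  n_samples <- 2L * as.integer(n_samples_per_group)
  if (is.null(size_factors)) size_factors <- rep(1, n_samples)
  spec <- list(n_genes = as.integer(n_genes),
               n_samples_per_group = as.integer(n_samples_per_group),
               size_factors = as.numeric(size_factors),
               mean_meanlog = mean_meanlog, mean_sdlog = mean_sdlog,
               dispersion = as.numeric(dispersion),
               de_fraction = as.numeric(de_fraction),
               planted_log2fc = as.numeric(planted_log2fc),
               seed = seed)
  if (spec$n_genes < 1L || spec$n_samples_per_group < 1L)
    stop("need at least 1 gene and 1 sample per group", call. = FALSE)
  if (length(spec$size_factors) != n_samples || any(spec$size_factors <= 0))
    stop("size_factors must be positive, one per sample", call. = FALSE)
  if (spec$dispersion < 0) stop("dispersion must be >= 0", call. = FALSE)
  if (spec$de_fraction < 0 || spec$de_fraction > 1)
    stop("de_fraction must lie in [0, 1]", call. = FALSE)
  class(spec) <- "count_sim_spec"
  spec
}

#' Simulate a two-group count matrix with planted DE genes
#'
#' @param spec A [count_sim_spec()].
#' @return A list: `counts` (genes x samples integer matrix), `groups`
#'   (factor of length n samples), `size_factors` used, and `truth` — a
#'   data frame with one row per gene (`gene`, `base_mean`, `is_de`,
#'   `log2fc`).
#' @export
simulate_counts <- function(spec) {
  stopifnot(inherits(spec, "count_sim_spec"))
  run <- function() {
    g <- spec$n_genes
    ns <- spec$n_samples_per_group
    groups <- factor(rep(c("group1", "group2"), each = ns))
    base_mean <- stats::rlnorm(g, spec$mean_meanlog, spec$mean_sdlog)
    n_de <- round(spec$de_fraction * g)
    is_de <- rep(FALSE, g)
    if (n_de > 0) is_de[sample.int(g, n_de)] <- TRUE
    lfc <- ifelse(is_de, spec$planted_log2fc, 0)
    mu <- cbind(matrix(base_mean, g, ns),
                matrix(base_mean * 2^lfc, g, ns))
    mu <- sweep(mu, 2, spec$size_factors, `*`)
    counts <- if (spec$dispersion == 0) {
      matrix(stats::rpois(length(mu), lambda = mu), g, 2L * ns)
    } else {
      matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / spec$dispersion),
             g, 2L * ns)
    }
    gene <- sprintf("gene_%05d", seq_len(g))
    dimnames(counts) <- list(gene,
                             paste0(rep(c("g1_s", "g2_s"), each = ns),
                                    rep(seq_len(ns), 2)))
    list(counts = counts, groups = groups, size_factors = spec$size_factors,
         truth = data.frame(gene = gene, base_mean = base_mean,
                            is_de = is_de, log2fc = lfc))
  }
  if (is.null(spec$seed)) run() else withr::with_seed(spec$seed, run())
}
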