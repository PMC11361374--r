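test_that("median-of-ratios size factors behave on exact inputs", {
  counts <- matrix(rpois(400, 50) + 1, 100, 4)
  # two identical samples get equal factors
  eq <- size_factors(cbind(counts[, 1], counts[, 1]))
  expect_equal(eq[1], eq[2], ignore_attr = TRUE)
  # exact 3x scaling shows up as a 3x factor ratio
  sc <- size_factors(cbind(s1 = counts[, 1], s2 = 3 * counts[, 1]))
  expect_equal(unname(sc["s2"] / sc["s1"]), 3)
  expect_error(size_factors(matrix(c(0, 1, 1, 0), 2, 2)), "no usable genes")
  expect_error(size_factors(matrix(1, 3, 1)), "2 samples")
})

test_that("planted size factors are recovered within 5% at 5000 genes", {
  sf_true <- c(1, 1.5, 2, 0.8)
  sim <- simulate_counts(count_sim_spec(
    n_genes = 5000, n_samples_per_group = 2, size_factors = sf_true,
    dispersion = 0.05, mean_meanlog = log(200), seed = 13))
  sf <- size_factors(sim$counts)
  sf <- sf / exp(mean(log(sf)))              # normalize scale as usual
  target <- sf_true / exp(mean(log(sf_true)))
  expect_lt(max(abs(sf - target) / target), 0.05)
})

test_that("size factors agree with the established median-of-ratios tool", {
  skip_if_not_installed("DESeq2")
  sim <- simulate_counts(count_sim_spec(
    n_genes = 2000, n_samples_per_group = 3,
    size_factors = c(1, 1.2, 0.9, 1.1, 0.7, 1.4), seed = 17))
  ours <- size_factors(sim$counts)
  theirs <- DESeq2::estimateSizeFactorsForMatrix(sim$counts)
  expect_equal(unname(ours), unname(theirs), tolerance = 1e-10)
})

test_that("size factors are equivariant up to the geometric-mean rescale", {
  # scaling sample j by c also scales every gene's geometric mean by
  # c^(1/n), so the invariant holds on factor ratios: sample j's factor
  # grows 4x relative to every other sample, and the other samples'
  # relative factors are untouched
  sim <- simulate_counts(count_sim_spec(n_genes = 800, seed = 19))
  base <- size_factors(sim$counts)
  scaled <- sim$counts
  scaled[, 2] <- scaled[, 2] * 4
  sf <- size_factors(scaled)
  expect_equal((sf[2] / sf[1]) / (base[2] / base[1]), 4,
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(sf[-2] / sf[1], base[-2] / base[1], tolerance = 1e-12)
})

test_that("per-gene test is null on identical groups, sharp on planted DE", {
  sim <- simulate_counts(count_sim_spec(n_genes = 300,
                                        n_samples_per_group = 4,
                                        de_fraction = 0, seed = 23))
  res <- per_gene_test(sim$counts, sim$groups)
  expect_lt(stats::median(abs(res$log2fc)), 0.3)
  # planted lfc = 3 at high expression, low dispersion
  sim2 <- simulate_counts(count_sim_spec(
    n_genes = 500, n_samples_per_group = 6, de_fraction = 0.1,
    planted_log2fc = 3, dispersion = 0.005,
    mean_meanlog = log(1000), mean_sdlog = 0.5, seed = 29))
  res2 <- per_gene_test(sim2$counts, sim2$groups)
  de <- sim2$truth$is_de
  expect_lt(max(abs(res2$log2fc[de] - 3)), 0.2)
  expect_error(per_gene_test(sim$counts, rep("a", 8)), "two groups")
  expect_error(per_gene_test(sim$counts[, c(1, 2, 5)], c("a", "a", "b")),
               "at least 2")
})

test_that("null p-values are approximately uniform", {
  sim <- simulate_counts(count_sim_spec(
    n_genes = 5000, n_samples_per_group = 10, de_fraction = 0,
    dispersion = 0.05, mean_meanlog = log(500), mean_sdlog = 0.8, seed = 31))
  res <- per_gene_test(sim$counts, sim$groups)
  ks <- suppressWarnings(stats::ks.test(res$pvalue, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("BH adjustment matches hand-worked cases and validates input", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)),
               brute_force_bh(c(0.01, 0.02, 0.03)))
  expect_equal(brute_force_bh(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_identical(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.07, 5)), rep(0.07, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.5, NA)), "\\[0, 1\\]")
})

test_that("BH equals the brute-force step-up on random vectors", {
  withr::with_seed(37, {
    for (i in 1:50) {
      p <- stats::runif(sample(1:200, 1))
      expect_equal(bh_adjust(p), brute_force_bh(p))
    }
  })
})

test_that("DE subsetting applies strict thresholds and stays disjoint", {
  res <- data.frame(gene = paste0("g", 1:6),
                    log2fc = c(3, 2, -3, -2, 5, -5),
                    padj = c(1e-5, 1e-5, 1e-5, 1e-5, 0.001, 0.01))
  sub <- de_subset(res, padj_max = 0.001, lfc_min = 2)
  # boundary cases: padj == 0.001 and |lfc| == 2 are excluded
  expect_identical(sub$up, "g1")
  expect_identical(sub$down, "g3")
  expect_length(intersect(sub$up, sub$down), 0)
  expect_identical(sub$results$call, c("up", "ns", "down", "ns", "ns", "ns"))
  # padj computed from pvalue when absent
  res2 <- data.frame(gene = "g", log2fc = 4, pvalue = 1e-8)
  expect_identical(de_subset(res2)$up, "g")
  expect_error(de_subset(data.frame(gene = "g", log2fc = 1)), "padj")
})
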