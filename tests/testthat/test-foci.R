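test_that("top-hat enhancement flattens smooth structure, keeps spots", {
  # constant image -> all zeros
  flat <- enhance_speckles(channel_image(matrix(500, 64, 64)), 5)
  expect_true(all(flat$pixels == 0))
  # a spot on a linear ramp stays the global maximum after enhancement
  ramp <- matrix(rep(seq(0, 300, length.out = 96), each = 96), 96, 96)
  yy <- matrix(1:96, 96, 96) - 48; xx <- t(yy)
  spot <- 400 * exp(-(yy^2 + xx^2) / (2 * 1.5^2))
  enh <- enhance_speckles(channel_image(ramp + spot), 5)
  expect_identical(which.max(enh$pixels), which.max(spot))
  expect_error(enhance_speckles(channel_image(matrix(1, 8, 8)), 10),
               "too large")
})

test_that("planted foci are counted with centroids within 1 px", {
  spec <- nucleus_image_spec(n_nuclei = 1, foci_per_nucleus = 5,
                             focus_amplitude = 1500, noise_sd = 150,
                             seed = 71)
  im <- make_foci_image(spec)
  seg <- segment_nuclei(im$dapi)
  det <- detect_foci(enhance_speckles(im$marker, 5), seg)
  expect_identical(det$counts$count, 5L)
  tru <- im$truth$foci
  for (j in seq_len(nrow(tru))) {
    d <- sqrt(min((det$foci$centroid_row - tru$row[j])^2 +
                    (det$foci$centroid_col - tru$col[j])^2))
    expect_lt(d, 1)
  }
})

test_that("foci merging below the resolution limit counts once", {
  # mild background noise keeps the per-nucleus robust threshold
  # meaningful (a perfectly flat background has MAD 0)
  withr::with_seed(73, {
    img <- matrix(100 + abs(stats::rnorm(96 * 96, sd = 30)), 96, 96)
  })
  yy <- matrix(1:96, 96, 96); xx <- t(yy)
  for (c0 in c(47, 48.5)) {   # two spots ~1.5 px apart
    img <- img + 800 * exp(-((yy - 48)^2 + (xx - c0)^2) / (2 * 1.2^2))
  }
  mask <- matrix(0L, 96, 96)
  mask[nepheno:::disk_mask(96, 96, 48, 48, 30)] <- 1L
  det <- detect_foci(enhance_speckles(channel_image(img), 5),
                     labeled_mask(mask))
  expect_identical(det$counts$count, 1L)
})

test_that("no planted foci means zero counts everywhere", {
  spec <- nucleus_image_spec(n_nuclei = 3, foci_per_nucleus = 0, seed = 81)
  im <- make_foci_image(spec)
  seg <- segment_nuclei(im$dapi)
  det <- detect_foci(enhance_speckles(im$marker, 5), seg)
  expect_true(all(det$counts$count == 0L))
})

test_that("raising detection_k never increases any count", {
  spec <- nucleus_image_spec(n_nuclei = 3, foci_per_nucleus = 4,
                             noise_sd = 300, seed = 91)
  im <- make_foci_image(spec)
  seg <- segment_nuclei(im$dapi)
  enh <- enhance_speckles(im$marker, 5)
  prev <- NULL
  for (k in c(2, 5, 8, 20)) {
    cnt <- detect_foci(enh, seg, foci_params(detection_k = k))$counts$count
    if (!is.null(prev)) expect_true(all(cnt <= prev))
    prev <- cnt
  }
})

test_that("counts are invariant to constant intensity offsets", {
  spec <- nucleus_image_spec(n_nuclei = 2, foci_per_nucleus = 3,
                             noise_sd = 150, seed = 101)
  im <- make_foci_image(spec)
  seg <- segment_nuclei(im$dapi)
  c0 <- detect_foci(enhance_speckles(im$marker, 5), seg)$counts$count
  shifted <- channel_image(im$marker$pixels + 750)
  c1 <- detect_foci(enhance_speckles(shifted, 5), seg)$counts$count
  expect_identical(c0, c1)
})

test_that("tiny nuclei report missing counts, and summaries respect that", {
  mask <- matrix(0L, 64, 64)
  mask[5:6, 5:6] <- 1L                      # 4 px: too small to score
  mask[nepheno:::disk_mask(64, 64, 40, 40, 10)] <- 2L
  det <- detect_foci(channel_image(matrix(1, 64, 64)), labeled_mask(mask))
  expect_identical(det$counts$count, c(NA_integer_, 0L))
  expect_identical(percent_foci_positive(det), 0)
  expect_error(percent_foci_positive(data.frame(count = NA_integer_)),
               "missing")
})

test_that("percentages and distribution summaries follow the definitions", {
  expect_identical(percent_foci_positive(data.frame(count = c(0, 0, 0))), 0)
  expect_identical(percent_foci_positive(data.frame(count = c(2, 0, 1, 0))), 50)
  fp <- foci_per_nucleus(data.frame(count = c(2, 0, 1, 0)))
  expect_identical(fp$n, 4L)
  expect_equal(fp$mean, 0.75)
})

test_that("Poisson-planted foci counts average to the planted rate", {
  # 300 nuclei across images, lambda = 3
  counts <- integer()
  for (s in 1:15) {
    spec <- nucleus_image_spec(image_size = c(640, 640), n_nuclei = 20,
                               radius_range = c(16, 20),
                               foci_per_nucleus = function(n)
                                 stats::rpois(n, 3),
                               focus_sigma = 1.2,
                               focus_amplitude = 1500, noise_sd = 100,
                               seed = 900 + s)
    im <- make_foci_image(spec)
    seg <- segment_nuclei(im$dapi)
    det <- detect_foci(enhance_speckles(im$marker, 5), seg)
    counts <- c(counts, det$counts$count)
  }
  counts <- counts[!is.na(counts)]
  expect_gte(length(counts), 290)
  se <- sqrt(3 / length(counts))
  expect_lt(abs(mean(counts) - 3), 3 * se + 0.05)
})
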