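test_that("form factor reproduces its analytic anchors", {
  r <- 50
  expect_identical(form_factor(pi * r^2, 2 * pi * r), 1)
  # square of side s
  expect_equal(form_factor(4^2, 4 * 4), pi / 4)
  # 2:1 ellipse, perimeter from numerical arc-length integration:
  # A = 2*pi, P = 9.688448, so 4*pi*A/P^2 = 0.841165
  P <- ellipse_perimeter_numeric(2, 1)
  expect_equal(P, 9.688448, tolerance = 1e-6)
  expect_equal(form_factor(2 * pi, P), 0.841165, tolerance = 1e-5)
  expect_error(form_factor(0, 1), "> 0")
  expect_error(form_factor(1, -2), "> 0")
})

test_that("Crofton perimeter keeps rasterized disks near 2*pi*r", {
  for (r in c(20, 35, 50)) {
    m <- raster_disk(r)
    ff <- form_factor(sum(m), perimeter_crofton(m))
    expect_gt(ff, 0.95)
    expect_lt(ff, 1.05)
  }
})

test_that("measure_nuclei reports geometry and channel means per label", {
  m <- raster_disk(50)
  mask <- labeled_mask(m * 1L)
  uniform <- channel_image(matrix(7, nrow(m), ncol(m)), "marker")
  rec <- measure_nuclei(mask, list(marker = uniform), image_id = "imgA")
  expect_identical(nrow(rec), 1L)
  expect_identical(rec$area, sum(m))
  expect_gt(rec$form_factor, 0.95); expect_lt(rec$form_factor, 1.05)
  expect_identical(rec$mean_marker, 7)
  expect_false(rec$border_touching)
  expect_error(measure_nuclei(mask, list(channel_image(matrix(1, 3, 3)))),
               "shape")
})

test_that("form factor decreases strictly as ellipses elongate", {
  h <- 301; w <- 301
  ff <- vapply(c(0, 0.5, 0.8, 0.95), function(ecc) {
    s <- (1 - ecc^2)^(1 / 4)          # area-preserving semi-axes
    m <- nepheno:::ellipse_mask(h, w, 151, 151, 60 / s, 60 * s, 0)
    form_factor(sum(m), perimeter_crofton(m))
  }, numeric(1))
  expect_true(all(diff(ff) < 0))
})

test_that("bleb calling recovers planted blebs and filters small ones", {
  spec <- nucleus_image_spec(n_nuclei = 3, blebs_per_nucleus = 1,
                             bleb_radius_range = c(8, 8),
                             noise_sd = 0, blur_sigma = 0, seed = 51)
  im <- make_nucleus_image(spec)
  p0 <- segmentation_params(smoothing_sigma = 0)
  segd <- segment_nuclei(im$dapi, p0)
  segl <- segment_nuclei(im$lamin, p0)
  bl <- detect_blebs(segd, segl, bleb_params(min_bleb_area = 50))
  expect_identical(bl$nuclei$n_blebs, rep(1L, 3))
  # areas within 15% of the planted truth (matched by nucleus order)
  tru <- im$truth$blebs[order(im$truth$blebs$nucleus), ]
  got <- bl$blebs[order(bl$blebs$label), ]
  expect_lt(max(abs(got$area - tru$area) / tru$area), 0.15)
  # a filter larger than every planted bleb removes them all
  big <- detect_blebs(segd, segl, bleb_params(min_bleb_area = 1000))
  expect_identical(big$nuclei$n_blebs, rep(0L, 3))
})

test_that("identical DAPI and lamin masks give zero blebs", {
  m <- raster_disk(30) * 1L
  bl <- detect_blebs(labeled_mask(m), labeled_mask(m))
  expect_identical(bl$nuclei$n_blebs, 0L)
  expect_identical(nrow(bl$blebs), 0L)
})

test_that("unmatched DAPI nuclei are flagged, not scored", {
  m <- matrix(0L, 128, 128)
  m[nepheno:::disk_mask(128, 128, 30, 30, 15)] <- 1L
  m[nepheno:::disk_mask(128, 128, 90, 90, 15)] <- 2L
  lam <- matrix(0L, 128, 128)
  lam[nepheno:::disk_mask(128, 128, 30, 30, 15)] <- 1L
  bl <- detect_blebs(labeled_mask(m), labeled_mask(lam))
  expect_identical(bl$unmatched, 2L)
  expect_false(2L %in% bl$nuclei$label)
})

test_that("bleb calling is monotone in min_bleb_area", {
  spec <- nucleus_image_spec(n_nuclei = 6, blebs_per_nucleus = 2,
                             bleb_radius_range = c(4, 9), noise_sd = 0,
                             seed = 61)
  im <- make_nucleus_image(spec)
  segd <- segment_nuclei(im$dapi)
  segl <- segment_nuclei(im$lamin)
  counts <- vapply(c(0, 20, 50, 120, 400), function(a)
    sum(detect_blebs(segd, segl, bleb_params(min_bleb_area = a))$nuclei$n_blebs),
    numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("percent blebbing and summaries follow the definitions", {
  rec <- data.frame(n_blebs = c(2L, 0L, 1L, 0L, 0L, 0L, 0L, 0L, 1L, 0L))
  expect_identical(percent_blebbing(rec), 30)
  expect_identical(percent_blebbing(data.frame(n_blebs = rep(0L, 5))), 0)
  expect_error(percent_blebbing(data.frame(n_blebs = integer())), "at least")
  rec$form_factor <- seq(0.5, 0.95, length.out = 10)
  rec$condition <- rep(c("wt", "mut"), each = 5)
  rec$replicate <- 1L
  sm <- summarize_morphometry(rec)
  expect_identical(nrow(sm$replicate), 2L)
  expect_identical(sort(sm$condition$condition), c("mut", "wt"))
})

test_that("planted blebbing rate is recovered within the binomial CI", {
  # 200 nuclei, 40% planted blebbing, noiseless
  n_blebbed <- 0L; n_total <- 0L
  for (s in 1:10) {
    spec <- nucleus_image_spec(image_size = c(640, 640), n_nuclei = 20,
                               radius_range = c(14, 18),
                               blebs_per_nucleus = 1, bleb_prob = 0.4,
                               bleb_radius_range = c(6, 8),
                               noise_sd = 0, seed = 700 + s)
    im <- make_nucleus_image(spec)
    segd <- segment_nuclei(im$dapi)
    segl <- segment_nuclei(im$lamin)
    bl <- detect_blebs(segd, segl)
    n_blebbed <- n_blebbed + sum(bl$nuclei$n_blebs >= 1L)
    n_total <- n_total + nrow(bl$nuclei)
  }
  ci <- stats::binom.test(n_blebbed, n_total, p = 0.4)$conf.int
  expect_true(ci[1] <= 0.4 && 0.4 <= ci[2])
})
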