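# Independent oracles and small fixture builders shared across the suite.

# Literal step-up Benjamini-Hochberg, written from the definition:
# sort ascending, padj_(i) = min_{k >= i} p_(k) * m / k, cap at 1,
# return in input order.
brute_force_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(1, min(ps[i:m] * m / (i:m)))
  }
  out <- numeric(m)
  out[ord] <- adj
  out
}

# Exact ellipse perimeter by numerical integration of the arc length
# integral: P = 4 a int_0^{pi/2} sqrt(1 - e^2 sin^2 t) dt.
ellipse_perimeter_numeric <- function(a, b) {
  e2 <- 1 - (b / a)^2
  4 * a * stats::integrate(function(t) sqrt(1 - e2 * sin(t)^2), 0, pi / 2,
                           rel.tol = 1e-12)$value
}

# Rasterized disk mask, centered with a margin.
raster_disk <- function(r, margin = 10) {
  n <- 2 * r + 2 * margin + 1
  c0 <- r + margin + 1
  nepheno:::disk_mask(n, n, c0, c0, r + 0.5)
}

# Greedy centroid matching of detections to planted objects within `tol`
# px; returns c(tp, fp, fn).
match_detections <- function(det_rows, det_cols, true_rows, true_cols, tol = 3) {
  used <- rep(FALSE, length(det_rows))
  tp <- 0L; fn <- 0L
  for (j in seq_along(true_rows)) {
    d2 <- (det_rows - true_rows[j])^2 + (det_cols - true_cols[j])^2
    k <- which(!used & d2 < tol^2)
    if (length(k)) {
      used[k[which.min(d2[k])]] <- TRUE
      tp <- tp + 1L
    } else fn <- fn + 1L
  }
  c(tp = tp, fp = sum(!used), fn = fn)
}

# One full bleb-scoring pass over a generated two-channel image: returns
# per-image c(tp, fp, fn) comparing called blebs to planted ones.
score_bleb_image <- function(spec, params = bleb_params()) {
  im <- make_nucleus_image(spec)
  segd <- segment_nuclei(im$dapi)
  segl <- segment_nuclei(im$lamin)
  bl <- detect_blebs(segd, segl, params)
  tru <- im$truth
  tp <- 0L; fp <- 0L; fn <- 0L
  for (i in seq_len(nrow(tru$nuclei))) {
    lab <- segd$labels[round(tru$nuclei$center_row[i]),
                       round(tru$nuclei$center_col[i])]
    ntrue <- tru$nuclei$n_blebs[i]
    ndet <- if (lab > 0 && lab %in% bl$nuclei$label)
      bl$nuclei$n_blebs[bl$nuclei$label == lab] else 0L
    tp <- tp + min(ntrue, ndet)
    fp <- fp + max(0L, ndet - ntrue)
    fn <- fn + max(0L, ntrue - ndet)
  }
  c(tp = tp, fp = fp, fn = fn)
}
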