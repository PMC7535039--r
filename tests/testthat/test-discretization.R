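mk_pair_from_values <- function(x_rec, x_non) {
  n <- length(x_rec) + length(x_non)
  dims <- c(n, 1L, 1L)
  img <- image_volume(array(c(x_rec, x_non), dim = dims))
  gtv <- roi_mask(array(1L, dim = dims), role = "GTV")
  gtvr_arr <- array(0L, dim = dims)
  gtvr_arr[seq_along(x_rec)] <- 1L
  pair <- make_habitats(gtv, roi_mask(gtvr_arr, role = "GTVr"), "s")
  list(img = img, pair = pair)
}

test_that("paired histograms share edges and normalize to density", {
  v <- mk_pair_from_values(rep(c(1, 2, 3), 4), rep(c(1, 2, 3), 4))
  h <- paired_histograms(v$img, v$pair, n_bins = 8)
  expect_equal(sum(h$density_rec), 1, tolerance = 1e-9)
  expect_equal(sum(h$density_nonrec), 1, tolerance = 1e-9)
  expect_identical(h$density_rec, h$density_nonrec)

  # swapping the ROIs swaps densities, not edges
  v2 <- mk_pair_from_values(c(1, 1, 2, 5), c(3, 3, 4, 4))
  h2 <- paired_histograms(v2$img, v2$pair, n_bins = 4)
  v2s <- mk_pair_from_values(c(3, 3, 4, 4), c(1, 1, 2, 5))
  h2s <- paired_histograms(v2s$img, v2s$pair, n_bins = 4)
  expect_identical(h2$bin_edges, h2s$bin_edges)
  expect_identical(h2$density_rec, h2s$density_nonrec)
})

test_that("a shifted recurrent ROI concentrates mass in upper bins", {
  set.seed(2)
  base <- runif(200, 0, 50)
  v <- mk_pair_from_values(base + 100, base)
  h <- paired_histograms(v$img, v$pair, n_bins = 10)
  # brute-force check of the binning itself
  edges <- h$bin_edges
  manual <- sapply(seq_len(10), function(b) {
    lo <- edges[b]; hi <- edges[b + 1]
    mean(base + 100 >= lo & if (b == 10) base + 100 <= hi else base + 100 < hi)
  })
  expect_equal(h$density_rec, manual, tolerance = 1e-12)
  upper_rec <- sum(h$density_rec[6:10])
  upper_non <- sum(h$density_nonrec[6:10])
  expect_gt(upper_rec, 0.99)
  expect_lt(upper_non, 0.01)
})

test_that("single-bin and degenerate histograms are handled", {
  v <- mk_pair_from_values(c(1, 2, 3, 9), c(4, 5, 6, 7))
  h1 <- paired_histograms(v$img, v$pair, n_bins = 1)
  expect_equal(h1$density_rec, 1)
  expect_equal(h1$density_nonrec, 1)

  vc <- mk_pair_from_values(rep(5, 4), rep(5, 4))
  hc <- paired_histograms(vc$img, vc$pair, n_bins = 16)
  expect_true(hc$degenerate)
  expect_equal(hc$density_rec, 1)
})

test_that("Lloyd-Max gives the exact codebook when d <= Ng", {
  q <- lloyd_max_quantize(c(10, 10, 20, 20), ng = 2)
  expect_equal(q$centroids, c(10, 20))
  expect_equal(q$mse, 0)
  expect_equal(sort(unique(q$levels)), c(1L, 2L))

  qc <- lloyd_max_quantize(rep(7, 50), ng = 8)
  expect_equal(qc$mse, 0)
  expect_equal(length(unique(qc$levels)), 1L)
  expect_true(all(diff(qc$boundaries) > 0))
})

test_that("Lloyd-Max approaches the analytic uniform quantizer", {
  set.seed(4)
  x <- runif(1000)
  q <- lloyd_max_quantize(x, ng = 4)
  expect_lt(max(abs(q$boundaries - c(0.25, 0.5, 0.75))), 0.02)
  expect_lt(max(abs(q$centroids - c(0.125, 0.375, 0.625, 0.875))), 0.02)
  # MSE within 2% of the analytic uniform-quantizer distortion 1/(12*16)
  expect_lt(abs(q$mse - 1 / 192) / (1 / 192), 0.02)
})

test_that("Lloyd-Max MSE is monotone non-increasing per iteration", {
  set.seed(8)
  for (x in list(rnorm(500), rexp(500), runif(300)^2)) {
    q <- lloyd_max_quantize(x, ng = 16)
    expect_true(all(diff(q$mse_trace) <= 1e-12))
    expect_true(all(diff(q$boundaries) > 0))
    expect_true(all(q$levels >= 1 & q$levels <= 16))
  }
})

test_that("quantization is invariant to input ordering", {
  set.seed(12)
  x <- rnorm(400)
  q1 <- lloyd_max_quantize(x, ng = 8)
  perm <- sample(length(x))
  q2 <- lloyd_max_quantize(x[perm], ng = 8)
  expect_equal(q1$centroids, q2$centroids)
  expect_equal(q1$levels[perm], q2$levels)
})

test_that("habitat quantization is per-ROI and beats a uniform codebook", {
  cfg <- small_phantom_config(seed = 31)
  ph <- generate_phantom(cfg, 1)
  pair <- make_habitats(ph$gtv, ph$gtvr, ph$subject_id)
  qs <- quantize_habitats(ph$volume, pair, ng = 64)
  for (q in qs) {
    expect_true(all(q$levels >= 1 & q$levels <= 64))
  }
  # Lloyd-Max MSE is below the equal-width uniform quantizer's MSE
  x <- ph$volume$data[pair$recurrent$data == 1L]
  edges <- seq(min(x), max(x), length.out = 65)
  mids <- (edges[-1] + edges[-65]) / 2
  lev <- findInterval(x, edges[-c(1, 65)]) + 1
  mse_uniform <- mean((x - mids[lev])^2)
  expect_lt(qs$recurrent$mse, mse_uniform)

  # d distinct values <= Ng: every distinct value gets its own level
  v <- mk_pair_from_values(rep(1:25, 2), rep(2:26, 2))
  qs2 <- quantize_habitats(v$img, v$pair, ng = 64)
  expect_equal(qs2$recurrent$mse, 0)
  expect_equal(length(unique(qs2$recurrent$levels)), 25L)
})
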