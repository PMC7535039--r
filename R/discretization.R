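#' Paired intensity histograms on a shared scale
#'
#' Computes relative-frequency histograms of the two habitats' raw
#' intensities over a common set of bin edges spanning the union of both
#' ranges, so the two distributions are directly comparable.
#'
#' @param img An [image_volume()].
#' @param pair A `habitat_pair` from [make_habitats()].
#' @param n_bins Number of bins; default 64.
#' @return A `habitat_histogram`: list with `bin_edges`, `density_rec`,
#'   `density_nonrec`, `degenerate` (TRUE when the joint intensity range is
#'   zero and a single bin is used).
#' @export
paired_histograms <- function(img, pair, n_bins = 64) {
  stopifnot(inherits(img, "image_volume"), inherits(pair, "habitat_pair"))
  x_rec <- img$data[pair$recurrent$data == 1L]
  x_non <- img$data[pair$nonrecurrent$data == 1L]
  if (length(x_rec) == 0L || length(x_non) == 0L) {
    abort("both habitats must be nonempty.")
  }
  rng <- range(c(x_rec, x_non))
  degenerate <- diff(rng) == 0
  if (degenerate || n_bins == 1L) {
    edges <- c(rng[1] - 0.5, rng[2] + 0.5)
    if (n_bins > 1L && !degenerate) {
      edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
    }
  } else {
    edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  }
  bin_of <- function(x) {
    b <- findInterval(x, edges, rightmost.closed = TRUE, all.inside = TRUE)
    tabulate(b, nbins = length(edges) - 1L)
  }
  structure(
    list(
      bin_edges = edges,
      density_rec = bin_of(x_rec) / length(x_rec),
      density_nonrec = bin_of(x_non) / length(x_non),
      degenerate = degenerate,
      subject_id = pair$subject_id
    ),
    class = "habitat_histogram"
  )
}

#' Lloyd-Max scalar quantization
#'
#' MSE-optimal scalar quantizer: alternates centroid updates (conditional
#' mean within each cell) and boundary updates (midpoints of adjacent
#' centroids), starting from an equally spaced codebook over the data
#' range, until the
#' maximum centroid move falls below `tol` or `max_iter` iterations. When
#' the number of distinct values d <= `ng`, each distinct value gets its own
#' level and the MSE is exactly 0. Empty cells inherit the midpoint of their
#' neighbors' centroids so the level count stays fixed.
#'
#' @param x Numeric vector of ROI intensities (nonempty).
#' @param ng Number of gray levels, >= 2.
#' @param tol Convergence tolerance on the maximum centroid move.
#' @param max_iter Iteration cap.
#' @return A `quantized_roi`: list with `levels` (integer 1..ng per input
#'   value, input order preserved), `ng`, `centroids`, `boundaries`
#'   (strictly increasing), `mse`, `mse_trace`, `n_iter`.
#' @export
lloyd_max_quantize <- function(x, ng = 256L, tol = 1e-8, max_iter = 500L) {
  x <- as.numeric(x)
  if (length(x) == 0L) abort("empty ROI: nothing to quantize.")
  if (any(!is.finite(x))) abort("intensities must be finite.")
  ng <- as.integer(ng)
  if (ng < 2L) abort("`ng` must be >= 2.")

  ux <- sort(unique(x))
  d <- length(ux)
  span <- max(diff(range(x)), 1)

  if (d <= ng) {
    # exact codebook: one level per distinct value; unused levels padded
    # above the data range so their cells stay empty
    pad <- if (d < ng) max(ux) + span * 1e-6 * seq_len(ng - d) else numeric(0)
    centroids <- c(ux, pad)
    boundaries <- (centroids[-ng] + centroids[-1]) / 2
    levels <- match(x, ux)
    return(structure(
      list(levels = as.integer(levels), ng = ng, centroids = centroids,
           boundaries = boundaries, mse = 0, mse_trace = 0, n_iter = 0L),
      class = "quantized_roi"
    ))
  }

  # equally spaced codebook over the data range: the first iteration then
  # evaluates the equal-width quantizer, and monotone MSE descent
  # guarantees the converged codebook never does worse than it
  rng <- range(x)
  centroids <- rng[1] + (seq_len(ng) - 0.5) * diff(rng) / ng
  centroids <- force_increasing(centroids, span)
  mse_trace <- numeric(0)
  assign_levels <- function(boundaries) {
    findInterval(x, boundaries) + 1L
  }
  n_iter <- 0L
  repeat {
    n_iter <- n_iter + 1L
    boundaries <- (centroids[-ng] + centroids[-1]) / 2
    lev <- assign_levels(boundaries)
    sums <- rowsum_fast(x, lev, ng)
    cnts <- tabulate(lev, nbins = ng)
    newc <- centroids
    occ <- cnts > 0L
    newc[occ] <- sums[occ] / cnts[occ]
    if (any(!occ)) {
      lo <- c(min(x), newc[-ng])
      hi <- c(newc[-1], max(x))
      newc[!occ] <- (lo[!occ] + hi[!occ]) / 2
    }
    newc <- force_increasing(newc, span)
    mse_trace <- c(mse_trace, mean((x - newc[lev])^2))
    move <- max(abs(newc - centroids))
    centroids <- newc
    if (move < tol || n_iter >= max_iter) break
  }
  boundaries <- (centroids[-ng] + centroids[-1]) / 2
  lev <- assign_levels(boundaries)
  structure(
    list(levels = as.integer(lev), ng = ng, centroids = centroids,
         boundaries = boundaries, mse = mean((x - centroids[lev])^2),
         mse_trace = mse_trace, n_iter = n_iter),
    class = "quantized_roi"
  )
}

rowsum_fast <- function(x, g, ng) {
  out <- numeric(ng)
  rs <- rowsum(x, g)
  out[as.integer(rownames(rs))] <- rs[, 1]
  out
}

force_increasing <- function(v, span) {
  eps <- span * 1e-12
  for (i in seq_along(v)[-1]) {
    if (v[i] <= v[i - 1]) v[i] <- v[i - 1] + eps
  }
  v
}

#' @export
print.quantized_roi <- function(x, ...) {
  cat(sprintf(
    "<quantized_roi> %d values -> %d levels (%d occupied), MSE %.4g, %d iter\n",
    length(x$levels), x$ng, length(unique(x$levels)), x$mse, x$n_iter
  ))
  invisible(x)
}

#' Quantize both habitats of a subject
#'
#' Each habitat is quantized independently with its own Lloyd-Max codebook
#' built from its own intensity distribution.
#'
#' @inheritParams paired_histograms
#' @param ng Gray-level count; default 256.
#' @param ... Passed on to [lloyd_max_quantize()].
#' @return List with elements `recurrent` and `nonrecurrent`, each a
#'   `quantized_roi` whose `levels` follow the column-major order of
#'   `which(mask == 1)`.
#' @export
quantize_habitats <- function(img, pair, ng = 256L, ...) {
  stopifnot(inherits(img, "image_volume"), inherits(pair, "habitat_pair"))
  list(
    recurrent = lloyd_max_quantize(
      img$data[pair$recurrent$data == 1L], ng = ng, ...
    ),
    nonrecurrent = lloyd_max_quantize(
      img$data[pair$nonrecurrent$data == 1L], ng = ng, ...
    )
  )
}

# Level grid: NA outside the mask, integer gray level inside. The input
# `levels` vector must follow which(mask == 1) order (column-major), as
# produced by quantize_habitats().
level_grid <- function(q, mask) {
  stopifnot(inherits(q, "quantized_roi"), inherits(mask, "roi_mask"))
  grid <- array(NA_integer_, dim = dim(mask$data))
  idx <- which(mask$data == 1L)
  if (length(idx) != length(q$levels)) {
    abort("mask voxel count does not match quantized level count.")
  }
  grid[idx] <- q$levels
  grid
}
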