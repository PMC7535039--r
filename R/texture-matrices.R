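# Texture matrix construction on the quantized level grid.
#
# All four families operate on a 3D integer level grid (NA outside the ROI)
# with 13-direction / 26-neighborhood geometry at Chebyshev distance 1,
# aggregated into a single matrix per family. Texture is computed on the
# voxel grid, ignoring physical anisotropy.

# the 13 unique 3D offsets (one per direction pair)
texture_offsets <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  keep <- g[, 1] > 0 |
    (g[, 1] == 0 & g[, 2] > 0) |
    (g[, 1] == 0 & g[, 2] == 0 & g[, 3] > 0)
  unname(g[keep, , drop = FALSE])
}

# crop a level grid to the ROI bounding box (+1 voxel pad); all texture
# statistics are translation-invariant, so this only saves work
crop_to_roi <- function(grid) {
  idx <- which(!is.na(grid))
  if (length(idx) == 0L) return(grid)
  co <- arrayInd(idx, dim(grid))
  lo <- pmax(apply(co, 2, min) - 1L, 1L)
  hi <- pmin(apply(co, 2, max) + 1L, dim(grid))
  grid[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
}

# index ranges of voxels whose neighbor at +off stays in the grid;
# NULL when the offset exceeds the grid extent
off_ranges <- function(dims, off) {
  lo <- pmax(1L, 1L - off)
  hi <- pmin(dims, dims - off)
  if (any(lo > hi)) return(NULL)
  list(x = lo[1]:hi[1], y = lo[2]:hi[2], z = lo[3]:hi[3])
}

# paired level values (a at voxel v, b at v + off) for all in-mask pairs
shifted_pairs <- function(grid, off) {
  rg <- off_ranges(dim(grid), off)
  if (is.null(rg)) return(cbind(a = integer(0), b = integer(0)))
  a <- grid[rg$x, rg$y, rg$z, drop = FALSE]
  b <- grid[rg$x + off[1], rg$y + off[2], rg$z + off[3], drop = FALSE]
  ok <- !is.na(a) & !is.na(b)
  cbind(a = a[ok], b = b[ok])
}

#' Gray-level co-occurrence matrix (GLCM)
#'
#' Joint probability of gray-level pairs over all 13 unique 3D directions at
#' Chebyshev distance 1, counting both orderings (so the matrix is
#' symmetric), restricted to pairs with both voxels inside the ROI, and
#' normalized to sum to 1.
#'
#' @param q A `quantized_roi` from [lloyd_max_quantize()] (levels in
#'   `which(mask == 1)` order).
#' @param mask The `roi_mask` the quantization came from.
#' @return `ng` x `ng` matrix of joint probabilities.
#' @export
build_glcm <- function(q, mask) {
  grid <- crop_to_roi(level_grid(q, mask))
  ng <- q$ng
  counts <- numeric(ng * ng)
  for (r in seq_len(13L)) {
    off <- texture_offsets()[r, ]
    pr <- shifted_pairs(grid, off)
    if (nrow(pr) == 0L) next
    k1 <- (pr[, 1] - 1L) * ng + pr[, 2]
    k2 <- (pr[, 2] - 1L) * ng + pr[, 1]
    tab <- tabulate(c(k1, k2), nbins = ng * ng)
    counts <- counts + tab
  }
  total <- sum(counts)
  if (total == 0) {
    abort("no valid voxel pairs in the ROI; GLCM undefined.")
  }
  matrix(counts / total, nrow = ng, ncol = ng, byrow = TRUE)
}

#' Gray-level run-length matrix (GLRLM)
#'
#' Counts maximal runs of equal gray level along each of the 13 directions
#' (runs truncated at the ROI boundary), accumulated over all directions
#' into one level-by-length matrix. Because every direction scans every ROI
#' voxel, the run-length mass `sum(l * r(i, l))` equals 13 times the ROI
#' voxel count.
#'
#' @inheritParams build_glcm
#' @return Matrix of run counts, `ng` rows, `max run length` columns.
#' @export
build_glrlm <- function(q, mask) {
  grid <- crop_to_roi(level_grid(q, mask))
  dims <- dim(grid)
  idx <- which(!is.na(grid))
  if (length(idx) == 0L) abort("empty ROI.")
  co <- arrayInd(idx, dims)
  lv <- grid[idx]
  offs <- texture_offsets()
  lengths_all <- integer(0)
  levels_all <- integer(0)
  for (r in seq_len(nrow(offs))) {
    off <- offs[r, ]
    # steps backward to the grid boundary along -off
    tb <- rep(.Machine$integer.max, length(idx))
    for (a in 1:3) {
      if (off[a] == 1) tb <- pmin(tb, co[, a] - 1L)
      if (off[a] == -1) tb <- pmin(tb, dims[a] - co[, a])
    }
    start <- co - tb * matrix(off, nrow = length(idx), ncol = 3, byrow = TRUE)
    key <- (start[, 1] - 1L) + dims[1] * (start[, 2] - 1L) +
      dims[1] * dims[2] * (start[, 3] - 1L)
    ord <- order(key, tb)
    k <- key[ord]; t <- tb[ord]; l <- lv[ord]
    n <- length(k)
    new_run <- c(TRUE, k[-1] != k[-n] | t[-1] != t[-n] + 1L | l[-1] != l[-n])
    starts <- which(new_run)
    run_len <- diff(c(starts, n + 1L))
    lengths_all <- c(lengths_all, run_len)
    levels_all <- c(levels_all, l[starts])
  }
  lmax <- max(lengths_all)
  tab <- tabulate((levels_all - 1L) * lmax + lengths_all, nbins = q$ng * lmax)
  matrix(tab, nrow = q$ng, ncol = lmax, byrow = TRUE)
}

#' Gray-level size-zone matrix (GLSZM)
#'
#' Zones are 26-connected components of equal gray level within the ROI;
#' `z(i, s)` counts zones of level `i` and size `s` voxels.
#'
#' @inheritParams build_glcm
#' @return Matrix of zone counts, `ng` rows, `max zone size` columns.
#' @export
build_glszm <- function(q, mask) {
  grid <- crop_to_roi(level_grid(q, mask))
  dims <- dim(grid)
  idx <- which(!is.na(grid))
  if (length(idx) == 0L) abort("empty ROI.")
  vid <- match(seq_len(prod(dims)), idx)   # linear voxel -> vertex id
  edges <- list()
  offs <- texture_offsets()
  for (r in seq_len(nrow(offs))) {
    off <- offs[r, ]
    rg <- off_ranges(dims, off)
    if (is.null(rg)) next
    xr <- rg$x; yr <- rg$y; zr <- rg$z
    a <- grid[xr, yr, zr, drop = FALSE]
    b <- grid[xr + off[1], yr + off[2], zr + off[3], drop = FALSE]
    ok <- which(!is.na(a) & !is.na(b) & a == b)
    if (length(ok) == 0L) next
    # linear indices of the two endpoints in the full grid
    sub <- arrayInd(ok, dim(a))
    la <- (xr[sub[, 1]]) + dims[1] * (yr[sub[, 2]] - 1L) +
      dims[1] * dims[2] * (zr[sub[, 3]] - 1L)
    lb <- la + off[1] + dims[1] * off[2] + dims[1] * dims[2] * off[3]
    edges[[length(edges) + 1L]] <- cbind(vid[la], vid[lb])
  }
  nv <- length(idx)
  if (length(edges) > 0L) {
    em <- do.call(rbind, edges)
    g <- igraph::graph_from_edgelist(em, directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, nv - igraph::vcount(g)))
    comp <- igraph::components(g)$membership[seq_len(nv)]
  } else {
    comp <- seq_len(nv)
  }
  lv <- grid[idx]
  zone_level <- tapply(lv, comp, function(v) v[1])
  zone_size <- as.integer(table(comp))
  smax <- max(zone_size)
  tab <- tabulate((as.integer(zone_level) - 1L) * smax + zone_size,
                  nbins = q$ng * smax)
  matrix(tab, nrow = q$ng, ncol = smax, byrow = TRUE)
}

#' Neighborhood gray-tone difference matrix (NGTDM)
#'
#' For each ROI voxel with at least one ROI neighbor in its 26-neighborhood,
#' the absolute difference between its level and the mean level of its
#' in-ROI neighbors is accumulated into `s[i]`; `n[i]` counts contributing
#' voxels at level `i` and `p[i] = n[i] / sum(n)`.
#'
#' @inheritParams build_glcm
#' @return List with vectors `n`, `p`, `s` (length `ng`).
#' @export
build_ngtdm <- function(q, mask) {
  grid <- crop_to_roi(level_grid(q, mask))
  dims <- dim(grid)
  nb_sum <- array(0, dim = dims)
  nb_cnt <- array(0L, dim = dims)
  offs <- texture_offsets()
  add_dir <- function(off) {
    rg <- off_ranges(dims, off)
    if (is.null(rg)) return(invisible(NULL))
    xr <- rg$x; yr <- rg$y; zr <- rg$z
    b <- grid[xr + off[1], yr + off[2], zr + off[3], drop = FALSE]
    bval <- b; bval[is.na(b)] <- 0L
    nb_sum[xr, yr, zr] <<- nb_sum[xr, yr, zr, drop = FALSE] + bval
    nb_cnt[xr, yr, zr] <<- nb_cnt[xr, yr, zr, drop = FALSE] + !is.na(b)
  }
  for (r in seq_len(nrow(offs))) {
    add_dir(offs[r, ])
    add_dir(-offs[r, ])
  }
  ok <- !is.na(grid) & nb_cnt > 0L
  if (!any(ok)) abort("no ROI voxel has an in-ROI neighbor; NGTDM undefined.")
  lv <- grid[ok]
  dev <- abs(lv - nb_sum[ok] / nb_cnt[ok])
  ng <- q$ng
  s <- rowsum_fast(dev, lv, ng)
  n <- tabulate(lv, nbins = ng)
  list(n = n, p = n / sum(n), s = s)
}
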