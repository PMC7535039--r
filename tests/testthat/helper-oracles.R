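# Independent brute-force oracles for the texture matrices, written as
# plain triple loops over voxels and neighbor offsets. They share no code
# with the package implementations.

all_26_offsets <- function() {
  g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  g[rowSums(abs(g)) > 0, , drop = FALSE]
}

half_13_offsets <- function() {
  g <- all_26_offsets()
  g[g[, 1] > 0 | (g[, 1] == 0 & g[, 2] > 0) |
      (g[, 1] == 0 & g[, 2] == 0 & g[, 3] > 0), , drop = FALSE]
}

in_grid <- function(v, dims) all(v >= 1) && all(v <= dims)

# GLCM: ordered-pair counts over all 26 offsets, normalized
oracle_glcm <- function(grid, ng) {
  dims <- dim(grid)
  offs <- all_26_offsets()
  P <- matrix(0, ng, ng)
  for (x in 1:dims[1]) for (y in 1:dims[2]) for (z in 1:dims[3]) {
    a <- grid[x, y, z]
    if (is.na(a)) next
    for (r in seq_len(nrow(offs))) {
      w <- c(x, y, z) + offs[r, ]
      if (!in_grid(w, dims)) next
      b <- grid[w[1], w[2], w[3]]
      if (is.na(b)) next
      P[a, b] <- P[a, b] + 1
    }
  }
  if (sum(P) == 0) stop("no pairs")
  P / sum(P)
}

# GLRLM: maximal equal-level runs along the 13 directions
oracle_glrlm <- function(grid, ng) {
  dims <- dim(grid)
  offs <- half_13_offsets()
  runs_level <- integer(0)
  runs_len <- integer(0)
  for (r in seq_len(nrow(offs))) {
    off <- offs[r, ]
    for (x in 1:dims[1]) for (y in 1:dims[2]) for (z in 1:dims[3]) {
      a <- grid[x, y, z]
      if (is.na(a)) next
      prev <- c(x, y, z) - off
      prev_same <- in_grid(prev, dims) &&
        !is.na(grid[prev[1], prev[2], prev[3]]) &&
        grid[prev[1], prev[2], prev[3]] == a
      if (prev_same) next    # not a run start
      len <- 0L
      w <- c(x, y, z)
      while (in_grid(w, dims) && !is.na(grid[w[1], w[2], w[3]]) &&
             grid[w[1], w[2], w[3]] == a) {
        len <- len + 1L
        w <- w + off
      }
      runs_level <- c(runs_level, a)
      runs_len <- c(runs_len, len)
    }
  }
  lmax <- max(runs_len)
  M <- matrix(0, ng, lmax)
  for (i in seq_along(runs_level)) {
    M[runs_level[i], runs_len[i]] <- M[runs_level[i], runs_len[i]] + 1
  }
  M
}

# GLSZM: flood fill of 26-connected equal-level components
oracle_glszm <- function(grid, ng) {
  dims <- dim(grid)
  offs <- all_26_offsets()
  seen <- array(FALSE, dim = dims)
  zones_level <- integer(0)
  zones_size <- integer(0)
  for (x in 1:dims[1]) for (y in 1:dims[2]) for (z in 1:dims[3]) {
    if (seen[x, y, z] || is.na(grid[x, y, z])) next
    lev <- grid[x, y, z]
    stack <- list(c(x, y, z))
    seen[x, y, z] <- TRUE
    size <- 0L
    while (length(stack) > 0L) {
      v <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      size <- size + 1L
      for (r in seq_len(nrow(offs))) {
        w <- v + offs[r, ]
        if (!in_grid(w, dims)) next
        if (seen[w[1], w[2], w[3]]) next
        lw <- grid[w[1], w[2], w[3]]
        if (is.na(lw) || lw != lev) next
        seen[w[1], w[2], w[3]] <- TRUE
        stack[[length(stack) + 1L]] <- w
      }
    }
    zones_level <- c(zones_level, lev)
    zones_size <- c(zones_size, size)
  }
  smax <- max(zones_size)
  M <- matrix(0, ng, smax)
  for (i in seq_along(zones_level)) {
    M[zones_level[i], zones_size[i]] <- M[zones_level[i], zones_size[i]] + 1
  }
  M
}

# NGTDM: per-voxel deviation from the mean of its in-ROI 26-neighborhood
oracle_ngtdm <- function(grid, ng) {
  dims <- dim(grid)
  offs <- all_26_offsets()
  s <- numeric(ng)
  n <- integer(ng)
  for (x in 1:dims[1]) for (y in 1:dims[2]) for (z in 1:dims[3]) {
    a <- grid[x, y, z]
    if (is.na(a)) next
    nb <- numeric(0)
    for (r in seq_len(nrow(offs))) {
      w <- c(x, y, z) + offs[r, ]
      if (!in_grid(w, dims)) next
      b <- grid[w[1], w[2], w[3]]
      if (!is.na(b)) nb <- c(nb, b)
    }
    if (length(nb) == 0L) next
    s[a] <- s[a] + abs(a - mean(nb))
    n[a] <- n[a] + 1L
  }
  list(n = n, p = n / sum(n), s = s)
}

# Wrap an integer level grid (NA outside ROI) as (quantized_roi, roi_mask)
# inputs for the package builders.
grid_to_inputs <- function(grid, ng = max(grid, na.rm = TRUE)) {
  mask <- roi_mask(array(as.integer(!is.na(grid)), dim = dim(grid)),
                   role = "GTVr")
  q <- structure(
    list(levels = as.integer(grid[!is.na(grid)]), ng = as.integer(ng),
         centroids = seq_len(ng), boundaries = seq_len(ng - 1) + 0.5,
         mse = 0, mse_trace = numeric(0), n_iter = 0L),
    class = "quantized_roi"
  )
  list(q = q, mask = mask)
}

# random level grid: random shape, random mask coverage, levels 1..ng
random_level_grid <- function(max_dims = c(6, 6, 4), ng = 4,
                              p_mask = 0.7) {
  dims <- c(sample(2:max_dims[1], 1), sample(2:max_dims[2], 1),
            sample(1:max_dims[3], 1))
  grid <- array(sample.int(ng, prod(dims), replace = TRUE), dim = dims)
  grid[runif(prod(dims)) > p_mask] <- NA_integer_
  if (all(is.na(grid))) grid[1, 1, 1] <- 1L
  grid
}

row_grid <- function(v) array(as.integer(v), dim = c(length(v), 1, 1))

small_phantom_config <- function(...) {
  phantom_config(shape = c(32, 32, 8), tumor_radius_vox = c(7, 7, 2.5),
                 ...)
}
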