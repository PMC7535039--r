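# Feature formulas for the four texture families. All operate on the raw
# matrices from build_*(); level/length/size indices enter the formulas as
# their integer values.

#' GLCM features
#'
#' Haralick-style features of a joint gray-level co-occurrence probability
#' matrix: energy, contrast, entropy (log2, with 0*log0 = 0), homogeneity,
#' correlation, sum average, variance, dissimilarity and autocorrelation.
#' Correlation is undefined (NaN) for a degenerate matrix with zero
#' marginal SD.
#'
#' @param P GLCM probability matrix from [build_glcm()].
#' @return Named numeric vector of the 9 `GLCM_*` features.
#' @export
glcm_features <- function(P) {
  if (sum(P) <= 0) abort("zero GLCM.")
  ng <- nrow(P)
  occ <- which(P > 0, arr.ind = TRUE)
  p <- P[occ]
  i <- occ[, 1]
  j <- occ[, 2]
  mu_i <- sum(i * p)
  mu_j <- sum(j * p)
  sd_i <- sqrt(sum((i - mu_i)^2 * p))
  sd_j <- sqrt(sum((j - mu_j)^2 * p))
  corr <- if (sd_i * sd_j > 0) {
    sum((i - mu_i) * (j - mu_j) * p) / (sd_i * sd_j)
  } else NaN
  c(
    GLCM_Energy = sum(p^2),
    GLCM_Contrast = sum((i - j)^2 * p),
    GLCM_Entropy = -sum(p * log2(p)),
    GLCM_Homogeneity = sum(p / (1 + abs(i - j))),
    GLCM_Correlation = corr,
    GLCM_SumAverage = sum((i + j) * p),
    GLCM_Variance = sum((i - mu_i)^2 * p),
    GLCM_Dissimilarity = sum(abs(i - j) * p),
    GLCM_AutoCorrelation = sum(i * j * p)
  )
}

#' GLRLM features
#'
#' The 13 run-length features (Galloway / Chu / Dasarathy lineage): short
#' and long run emphasis, gray-level and run-length non-uniformity, run
#' percentage, low/high gray-level run emphasis, the four joint
#' short/long-low/high emphases, and gray-level / run-length variance
#' (weighted by the normalized matrix). Run percentage is the run count
#' divided by the run-length mass `sum(l * r(i, l))`, i.e. the voxel count
#' with direction multiplicity.
#'
#' @param R Run count matrix from [build_glrlm()] (rows = levels,
#'   columns = run lengths).
#' @return Named numeric vector of the 13 `GLRLM_*` features.
#' @export
glrlm_features <- function(R) {
  stats <- run_zone_stats(R)
  setNames(stats, paste0("GLRLM_", c(
    "SRE", "LRE", "GLN", "RLN", "RP", "LGRE", "HGRE",
    "SRLGE", "SRHGE", "LRLGE", "LRHGE", "GLV", "RLV"
  )))
}

#' GLSZM features
#'
#' The 13 size-zone features (Thibault lineage), mirroring the run-length
#' set with run length replaced by zone size: small/large zone emphasis,
#' gray-level non-uniformity, zone-size non-uniformity, zone percentage
#' (zones per ROI voxel), low/high gray-level zone emphasis, the four joint
#' emphases, and gray-level / zone-size variance.
#'
#' @param Z Zone count matrix from [build_glszm()] (rows = levels,
#'   columns = zone sizes).
#' @return Named numeric vector of the 13 `GLSZM_*` features.
#' @export
glszm_features <- function(Z) {
  stats <- run_zone_stats(Z)
  setNames(stats, paste0("GLSZM_", c(
    "SZE", "LZE", "GLN", "ZSN", "ZP", "LGZE", "HGZE",
    "SZLGE", "SZHGE", "LZLGE", "LZHGE", "GLV", "ZSV"
  )))
}

# shared arithmetic for GLRLM/GLSZM: M[i, l] counts of (level i, length l)
run_zone_stats <- function(M) {
  ns <- sum(M)
  if (ns <= 0) abort("zero run/zone matrix.")
  occ <- which(M > 0, arr.ind = TRUE)
  m <- M[occ]
  i <- occ[, 1]
  l <- occ[, 2]
  p <- m / ns
  nvox <- sum(l * m)
  mu_i <- sum(p * i)
  mu_l <- sum(p * l)
  c(
    sum(m / l^2) / ns,                     # short emphasis
    sum(m * l^2) / ns,                     # long emphasis
    sum(rowsum(m, i)[, 1]^2) / ns,         # gray-level non-uniformity
    sum(rowsum(m, l)[, 1]^2) / ns,         # length non-uniformity
    ns / nvox,                             # run/zone percentage
    sum(m / i^2) / ns,                     # low gray-level emphasis
    sum(m * i^2) / ns,                     # high gray-level emphasis
    sum(m / (i^2 * l^2)) / ns,             # short low
    sum(m * i^2 / l^2) / ns,               # short high
    sum(m * l^2 / i^2) / ns,               # long low
    sum(m * i^2 * l^2) / ns,               # long high
    sum(p * (i - mu_i)^2),                 # gray-level variance
    sum(p * (l - mu_l)^2)                  # length variance
  )
}

#' NGTDM features
#'
#' Amadasun-King coarseness, contrast, busyness, complexity and strength.
#' Denominators are guarded with `eps` (default 1e-6): a perfectly uniform
#' ROI has coarseness `1/eps`, and a single occupied level yields contrast
#' and busyness 0.
#'
#' @param t NGTDM list from [build_ngtdm()] (`n`, `p`, `s`).
#' @param eps Denominator guard.
#' @return Named numeric vector of the 5 `NGTDM_*` features.
#' @export
ngtdm_features <- function(t, eps = 1e-6) {
  occ <- which(t$n > 0L)
  if (length(occ) == 0L) abort("empty NGTDM.")
  p <- t$p[occ]
  s <- t$s[occ]
  lev <- occ
  ngr <- length(occ)
  nvox <- sum(t$n)
  coarseness <- 1 / (eps + sum(p * s))
  if (ngr == 1L) {
    contrast <- 0
    busyness <- 0
  } else {
    dl2 <- outer(lev, lev, `-`)^2
    pp <- outer(p, p)
    contrast <- (sum(pp * dl2) / (ngr * (ngr - 1))) * (sum(s) / nvox)
    denom <- sum(abs(outer(lev * p, lev * p, `-`)))
    busyness <- sum(p * s) / (eps + denom)
  }
  ps <- p * s
  comp_num <- outer(ps, ps, `+`)
  comp_w <- abs(outer(lev, lev, `-`)) / (nvox * outer(p, p, `+`))
  complexity <- sum(comp_w * comp_num)
  if (ngr == 1L) {
    strength <- 0
  } else {
    strength <- sum(outer(p, p, `+`) * outer(lev, lev, `-`)^2) /
      (eps + sum(s))
  }
  c(
    NGTDM_Coarseness = coarseness,
    NGTDM_Contrast = contrast,
    NGTDM_Busyness = busyness,
    NGTDM_Complexity = complexity,
    NGTDM_Strength = strength
  )
}

#' Extract the full 47-feature vector for both habitats of one subject
#'
#' First-order features are computed on the raw ROI intensities; texture
#' features on the Lloyd-Max quantized levels (each habitat with its own
#' codebook). A habitat smaller than `min_voxels` flags the subject as
#' unusable: no partial output is produced.
#'
#' @param img An [image_volume()].
#' @param pair A `habitat_pair` from [make_habitats()].
#' @param ng Gray-level count for quantization; default 256.
#' @param min_voxels Minimum habitat size; default 8.
#' @return A tibble with two rows (`roi_role` = "recurrent",
#'   "nonrecurrent"), columns `subject_id`, `roi_role`, then the 47
#'   features in canonical order.
#' @export
extract_all <- function(img, pair, ng = 256L, min_voxels = 8L) {
  stopifnot(inherits(img, "image_volume"), inherits(pair, "habitat_pair"))
  n_rec <- mask_count(pair$recurrent)
  n_non <- mask_count(pair$nonrecurrent)
  if (n_rec < min_voxels || n_non < min_voxels) {
    abort(sprintf(
      "habitat too small (recurrent %d, non-recurrent %d; need >= %d voxels); subject flagged unusable.",
      n_rec, n_non, min_voxels
    ))
  }
  one_roi <- function(mask, role) {
    x <- img$data[mask$data == 1L]
    q <- lloyd_max_quantize(x, ng = ng)
    fo <- first_order_features(x)
    glcm <- glcm_features(build_glcm(q, mask))
    glrlm <- glrlm_features(build_glrlm(q, mask))
    glszm <- glszm_features(build_glszm(q, mask))
    ngtdm <- ngtdm_features(build_ngtdm(q, mask))
    vals <- c(fo, glcm, glrlm, glszm, ngtdm)
    stopifnot(identical(names(vals), hetrad_feature_names()))
    dplyr::bind_cols(
      tibble(subject_id = pair$subject_id, roi_role = role),
      as_tibble(as.list(vals))
    )
  }
  dplyr::bind_rows(
    one_roi(pair$recurrent, "recurrent"),
    one_roi(pair$nonrecurrent, "nonrecurrent")
  )
}
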