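#' Phantom configuration
#'
#' Configuration for the paired-habitat phantom generator, which emulates a
#' contrast-enhanced T1-like MRI volume containing an ellipsoidal tumor
#' (GTV) with an embedded, connected recurrent subregion (GTVr) whose
#' texture statistics differ controllably from the remainder.
#'
#' Each habitat's texture is a Gaussian random field: white noise smoothed
#' with a Gaussian kernel of the habitat's correlation length (voxels),
#' rescaled to `noise_sd` and added to the habitat's mean intensity. The
#' recurrent habitat additionally receives `intensity_shift`. By default the
#' recurrent habitat has the longer correlation length, i.e. a coarser,
#' patchier texture: lower NGTDM busyness and higher coarseness/strength
#' than the non-recurrent habitat, the direction the study question implies.
#' Intensities are clipped to \[0, 4095\] (scanner dynamic range); at the
#' defaults the clipping rate is far below 0.1%.
#'
#' @param shape Grid dimensions (nx, ny, nz); default `c(64, 64, 12)`, a
#'   desk-scale reduction of a 512 x 512 x (44-100) clinical grid.
#' @param spacing Voxel spacing in mm; default `c(0.7, 0.7, 5)`.
#' @param n_subjects Cohort size; default 14.
#' @param seed Base RNG seed; per-subject streams are derived from it.
#' @param tumor_radius_vox Ellipsoid semi-axes in voxels (length 1 or 3).
#' @param recurrent_fraction Target |GTVr| / |GTV|, in (0, 1); default 0.3.
#' @param intensity_shift Additive mean shift of the recurrent habitat.
#' @param correlation_length_rec,correlation_length_nonrec Gaussian-field
#'   correlation lengths (voxels) for the two habitats.
#' @param noise_sd Marginal SD of each habitat's texture field.
#' @param infield_overlap Fraction of GTVr covered by the 95%-isodose mask.
#' @param tumor_mean,background_mean Mean intensities inside/outside GTV.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(shape = c(64, 64, 12),
                           spacing = c(0.7, 0.7, 5),
                           n_subjects = 14,
                           seed = 42,
                           tumor_radius_vox = c(14, 14, 4),
                           recurrent_fraction = 0.3,
                           intensity_shift = 60,
                           correlation_length_rec = 2.5,
                           correlation_length_nonrec = 1.0,
                           noise_sd = 80,
                           infield_overlap = 0.97,
                           tumor_mean = 800,
                           background_mean = 300) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < c(16L, 16L, 4L))) {
    abort("`shape` must be three integers, each >= (16, 16, 4).")
  }
  if (length(tumor_radius_vox) == 1L) {
    tumor_radius_vox <- rep(tumor_radius_vox, 3L)
  }
  if (!(recurrent_fraction > 0 && recurrent_fraction < 1)) {
    abort("`recurrent_fraction` must lie in (0, 1).")
  }
  if (correlation_length_rec <= 0 || correlation_length_nonrec <= 0) {
    abort("correlation lengths must be > 0.")
  }
  if (infield_overlap < 0 || infield_overlap > 1) {
    abort("`infield_overlap` must lie in [0, 1].")
  }
  if (any(tumor_radius_vox * 2 + 2 > shape)) {
    abort("tumor does not fit in `shape`; reduce `tumor_radius_vox`.")
  }
  structure(
    list(shape = shape, spacing = as.numeric(spacing),
         n_subjects = as.integer(n_subjects), seed = as.integer(seed),
         tumor_radius_vox = as.numeric(tumor_radius_vox),
         recurrent_fraction = recurrent_fraction,
         intensity_shift = intensity_shift,
         correlation_length_rec = correlation_length_rec,
         correlation_length_nonrec = correlation_length_nonrec,
         noise_sd = noise_sd, infield_overlap = infield_overlap,
         tumor_mean = tumor_mean, background_mean = background_mean),
    class = "phantom_config"
  )
}

# Stationary Gaussian random field: circular FFT convolution of white noise
# with a (separable) Gaussian kernel, rescaled to unit marginal SD.
gaussian_random_field <- function(shape, corr_length) {
  noise <- array(rnorm(prod(shape)), dim = shape)
  if (corr_length < 1e-8) {
    return(noise)
  }
  k1 <- function(n, sigma) {
    d <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
    k <- exp(-d^2 / (2 * sigma^2))
    k / sum(k)
  }
  kx <- k1(shape[1], corr_length)
  ky <- k1(shape[2], corr_length)
  kz <- k1(shape[3], corr_length)
  kern <- outer(outer(kx, ky), kz)
  sm <- Re(fft(fft(noise) * fft(kern), inverse = TRUE)) / prod(shape)
  s <- sd(sm)
  if (s < 1e-12) sm else sm / s
}

ellipsoid_mask <- function(shape, center, radii) {
  ix <- (seq_len(shape[1]) - center[1]) / radii[1]
  iy <- (seq_len(shape[2]) - center[2]) / radii[2]
  iz <- (seq_len(shape[3]) - center[3]) / radii[3]
  d2 <- outer(outer(ix^2, iy^2, `+`), iz^2, `+`)
  array(as.integer(d2 <= 1), dim = shape)
}

# Grow a connected blob inside `inside` (logical/0-1 array) from `seed_vox`
# until `target` voxels, by repeatedly admitting the frontier voxel with the
# smallest jittered distance to the seed. 6-connected growth; guaranteed
# connected and a subset of `inside`.
grow_blob <- function(inside, seed_vox, target, jitter = 1.5) {
  shape <- dim(inside)
  idx <- function(v) v[1] + (v[2] - 1L) * shape[1] +
    (v[3] - 1L) * shape[1] * shape[2]
  stopifnot(inside[idx(seed_vox)] == 1)
  coords <- which(inside == 1)
  arr <- arrayInd(coords, shape)
  pri_all <- rep(NA_real_, prod(shape))
  d <- sqrt(((arr[, 1] - seed_vox[1]))^2 + ((arr[, 2] - seed_vox[2]))^2 +
              ((arr[, 3] - seed_vox[3]) * 2)^2)
  pri_all[coords] <- d + rnorm(length(d), sd = jitter)
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  in_blob <- logical(prod(shape))
  s0 <- idx(seed_vox)
  in_blob[s0] <- TRUE
  frontier <- integer(0)
  push_neighbors <- function(v_lin, frontier) {
    v <- arrayInd(v_lin, shape)[1, ]
    for (r in seq_len(nrow(offs))) {
      w <- v + offs[r, ]
      if (all(w >= 1L) && all(w <= shape)) {
        wl <- idx(w)
        if (!in_blob[wl] && !is.na(pri_all[wl]) && !(wl %in% frontier)) {
          frontier <- c(frontier, wl)
        }
      }
    }
    frontier
  }
  frontier <- push_neighbors(s0, frontier)
  n <- 1L
  while (n < target && length(frontier) > 0L) {
    j <- which.min(pri_all[frontier])
    v_lin <- frontier[j]
    frontier <- frontier[-j]
    in_blob[v_lin] <- TRUE
    n <- n + 1L
    frontier <- push_neighbors(v_lin, frontier)
  }
  if (n < target) {
    abort("recurrent_fraction incompatible with tumor size: blob cannot grow.")
  }
  array(as.integer(in_blob), dim = shape)
}

#' Generate one phantom subject
#'
#' Deterministic given `(config$seed, subject_index)`: the volume, GTV, GTVr
#' and 95%-isodose masks are reproduced bit-for-bit on re-run.
#'
#' @param config A [phantom_config()].
#' @param subject_index 1-based subject index, `<= config$n_subjects`.
#' @return List with elements `volume` ([image_volume()]), `gtv`, `gtvr`,
#'   `isodose95` ([roi_mask()]s) and `subject_id`.
#' @export
generate_phantom <- function(config, subject_index = 1L) {
  stopifnot(inherits(config, "phantom_config"))
  subject_index <- as.integer(subject_index)
  if (subject_index < 1L || subject_index > config$n_subjects) {
    abort("`subject_index` must be in 1..n_subjects.")
  }
  subject_id <- sprintf("SUB%03d", subject_index)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(as.integer(
    (as.numeric(config$seed) * 1009 + subject_index * 7919) %% 2147483647
  ))

  shape <- config$shape
  center <- (shape + 1) / 2
  gtv_arr <- ellipsoid_mask(shape, center, config$tumor_radius_vox)
  n_gtv <- sum(gtv_arr)
  target <- max(1L, round(config$recurrent_fraction * n_gtv))
  seed_vox <- round(center + c(config$tumor_radius_vox[1] / 3, 0, 0))
  gtvr_arr <- grow_blob(gtv_arr, as.integer(seed_vox), target)

  f_bg <- gaussian_random_field(shape, config$correlation_length_nonrec)
  f_nr <- gaussian_random_field(shape, config$correlation_length_nonrec)
  f_re <- gaussian_random_field(shape, config$correlation_length_rec)
  img <- config$background_mean + 0.5 * config$noise_sd * f_bg
  in_nr <- gtv_arr == 1L & gtvr_arr == 0L
  in_re <- gtvr_arr == 1L
  img[in_nr] <- config$tumor_mean + config$noise_sd * f_nr[in_nr]
  img[in_re] <- config$tumor_mean + config$intensity_shift +
    config$noise_sd * f_re[in_re]
  img <- pmin(pmax(img, 0), 4095)

  iso_arr <- ellipsoid_mask(shape, center, pmin(
    config$tumor_radius_vox + 2, (shape - 1) / 2
  ))
  iso_arr[gtv_arr == 1L] <- 1L
  k_out <- round((1 - config$infield_overlap) * sum(gtvr_arr))
  if (k_out > 0L) {
    rec_idx <- which(gtvr_arr == 1L)
    rc <- arrayInd(rec_idx, shape)
    d2 <- ((rc[, 1] - center[1]) / config$tumor_radius_vox[1])^2 +
      ((rc[, 2] - center[2]) / config$tumor_radius_vox[2])^2 +
      ((rc[, 3] - center[3]) / config$tumor_radius_vox[3])^2
    drop_idx <- rec_idx[order(-d2)[seq_len(k_out)]]
    iso_arr[drop_idx] <- 0L
  }

  list(
    volume = image_volume(img, spacing = config$spacing, id = subject_id),
    gtv = roi_mask(gtv_arr, role = "GTV", spacing = config$spacing),
    gtvr = roi_mask(gtvr_arr, role = "GTVr", spacing = config$spacing),
    isodose95 = roi_mask(iso_arr, role = "isodose95",
                         spacing = config$spacing),
    subject_id = subject_id
  )
}

#' Generate and write a phantom cohort
#'
#' Writes `n_subjects` quadruples of NIfTI files (volume, GTV, GTVr,
#' 95%-isodose) plus a `manifest.csv` recording per-subject file paths,
#' voxel counts and the generating parameters.
#'
#' @param config A [phantom_config()].
#' @param out_dir Output directory (created if needed).
#' @return The manifest tibble, invisibly.
#' @export
generate_cohort <- function(config, out_dir) {
  stopifnot(inherits(config, "phantom_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- vector("list", config$n_subjects)
  for (i in seq_len(config$n_subjects)) {
    ph <- generate_phantom(config, i)
    base <- file.path(out_dir, ph$subject_id)
    paths <- c(volume = paste0(base, "_volume.nii.gz"),
               gtv = paste0(base, "_gtv.nii.gz"),
               gtvr = paste0(base, "_gtvr.nii.gz"),
               isodose95 = paste0(base, "_isodose95.nii.gz"))
    write_volume(ph$volume, paths[["volume"]])
    write_volume(ph$gtv, paths[["gtv"]])
    write_volume(ph$gtvr, paths[["gtvr"]])
    write_volume(ph$isodose95, paths[["isodose95"]])
    rows[[i]] <- tibble(
      subject_id = ph$subject_id,
      volume = paths[["volume"]], gtv = paths[["gtv"]],
      gtvr = paths[["gtvr"]], isodose95 = paths[["isodose95"]],
      n_gtv = mask_count(ph$gtv), n_gtvr = mask_count(ph$gtvr),
      overlap_isodose = overlap_fraction(ph$gtvr, ph$isodose95),
      recurrent_fraction = config$recurrent_fraction,
      intensity_shift = config$intensity_shift,
      correlation_length_rec = config$correlation_length_rec,
      correlation_length_nonrec = config$correlation_length_nonrec,
      noise_sd = config$noise_sd, seed = config$seed
    )
  }
  manifest <- if (config$n_subjects == 0L) {
    tibble(subject_id = character(0), volume = character(0),
           gtv = character(0), gtvr = character(0),
           isodose95 = character(0), n_gtv = integer(0),
           n_gtvr = integer(0), overlap_isodose = numeric(0),
           recurrent_fraction = numeric(0), intensity_shift = numeric(0),
           correlation_length_rec = numeric(0),
           correlation_length_nonrec = numeric(0), noise_sd = numeric(0),
           seed = integer(0))
  } else {
    dplyr::bind_rows(rows)
  }
  readr::write_csv(manifest, file.path(out_dir, "manifest.csv"))
  invisible(manifest)
}
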