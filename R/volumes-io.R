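#' Image volumes and ROI masks
#'
#' `image_volume()` wraps a 3D scalar array with its voxel spacing and a
#' subject label; `roi_mask()` wraps a binary array of the same shape with a
#' role label. Masks and volumes are index-aligned: voxel (i, j, k) in a mask
#' refers to voxel (i, j, k) in its companion volume, and no resampling is
#' ever performed.
#'
#' @param data 3D numeric array. For masks, values must be 0/1 (within 1e-6).
#' @param spacing Numeric length-3 voxel spacing (dx, dy, dz) in mm.
#' @param id Subject label.
#' @param role Mask role: one of `"GTV"`, `"GTVr"`, `"GTVnr"`, `"isodose95"`.
#' @return An object of class `image_volume` or `roi_mask`.
#' @export
image_volume <- function(data, spacing = c(1, 1, 1), id = "subject") {
  data <- as.array(data)
  if (length(dim(data)) != 3L) {
    abort("`data` must be a 3D array.")
  }
  if (any(dim(data) < 1L)) {
    abort("all three dimensions must be >= 1.")
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    abort("`spacing` must be three positive finite numbers (mm).")
  }
  n_bad <- sum(!is.finite(data))
  if (n_bad > 0L) {
    abort(sprintf("volume contains %d non-finite voxel(s) (NaN/Inf).", n_bad))
  }
  structure(
    list(data = data, spacing = spacing, id = as.character(id)),
    class = "image_volume"
  )
}

#' @rdname image_volume
#' @export
roi_mask <- function(data, role = c("GTV", "GTVr", "GTVnr", "isodose95"),
                     spacing = c(1, 1, 1)) {
  role <- match.arg(role)
  data <- as.array(data)
  if (length(dim(data)) != 3L) {
    abort("mask `data` must be a 3D array.")
  }
  off <- abs(data - round(data)) > 1e-6 | (round(data) != 0 & round(data) != 1)
  if (any(off)) {
    abort(sprintf(
      "mask is not binary: %d voxel(s) differ from 0/1 by more than 1e-6.",
      sum(off)
    ))
  }
  spacing <- as.numeric(spacing)
  storage.mode(data) <- "integer"
  structure(
    list(data = data, role = role, spacing = spacing),
    class = "roi_mask"
  )
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf(
    "<image_volume '%s'> %s voxels, spacing %s mm, range [%.4g, %.4g]\n",
    x$id, paste(dim(x$data), collapse = "x"),
    paste(format(x$spacing), collapse = "x"),
    min(x$data), max(x$data)
  ))
  invisible(x)
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf(
    "<roi_mask %s> %s grid, %d voxels in mask\n",
    x$role, paste(dim(x$data), collapse = "x"), mask_count(x)
  ))
  invisible(x)
}

#' Number of voxels in a mask
#' @param mask A `roi_mask`.
#' @return Integer voxel count.
#' @export
mask_count <- function(mask) {
  stopifnot(inherits(mask, "roi_mask"))
  sum(mask$data)
}

#' Read a NIfTI-1 scalar volume
#'
#' Reads a 3D NIfTI-1 volume from disk; voxel spacing is taken from the
#' header (`pixdim`). 4D/vector images and non-finite voxels are errors.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param id Subject label; defaults to the file name without extension.
#' @return An [image_volume()].
#' @export
read_volume <- function(path, id = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path))
  }
  img <- tryCatch(
    suppressWarnings(RNifti::readNifti(path)),
    error = function(e) abort(sprintf("not a readable NIfTI volume: %s (%s)",
                                      path, conditionMessage(e)))
  )
  d <- dim(img)
  if (length(d) != 3L) {
    abort(sprintf("expected a 3D scalar volume, got %d dimensions.", length(d)))
  }
  if (is.null(id)) {
    id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  }
  image_volume(array(as.numeric(img), dim = d),
               spacing = RNifti::pixdim(img)[1:3], id = id)
}

#' Read a binary ROI mask on the grid of a reference volume
#'
#' @param path Path to a NIfTI mask.
#' @param reference The [image_volume()] whose grid the mask must match.
#' @inheritParams roi_mask
#' @return An [roi_mask()].
#' @export
read_mask <- function(path, reference,
                      role = c("GTV", "GTVr", "GTVnr", "isodose95")) {
  role <- match.arg(role)
  stopifnot(inherits(reference, "image_volume"))
  vol <- read_volume(path, id = "mask")
  if (!identical(dim(vol$data), dim(reference$data))) {
    abort(sprintf(
      "mask grid %s does not match reference grid %s.",
      paste(dim(vol$data), collapse = "x"),
      paste(dim(reference$data), collapse = "x")
    ))
  }
  roi_mask(vol$data, role = role, spacing = reference$spacing)
}

#' Write a volume or mask to NIfTI-1
#'
#' @param x An [image_volume()] or [roi_mask()].
#' @param path Destination `.nii` or `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  if (inherits(x, "roi_mask")) {
    dat <- x$data
    spacing <- x$spacing
  } else {
    stopifnot(inherits(x, "image_volume"))
    dat <- x$data
    spacing <- x$spacing
  }
  img <- RNifti::asNifti(dat)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write and read the per-ROI feature table
#'
#' The feature table is the pipeline's central tabular artifact: one row per
#' (subject, ROI role) with the 47 features in their canonical order
#' (7 intensity-histogram, 9 GLCM, 13 GLRLM, 13 GLSZM, 5 NGTDM), so that
#' outputs are diffable across runs.
#'
#' @param rows A tibble/data frame with columns `subject_id`, `roi_role` and
#'   the 47 feature columns (any order; they are reordered canonically).
#' @param path Destination CSV path.
#' @return `write_feature_table()` returns `path` invisibly;
#'   `read_feature_table()` returns a tibble.
#' @export
write_feature_table <- function(rows, path) {
  nm <- hetrad_feature_names()
  if (nrow(as.data.frame(rows)) == 0L) {
    out <- as_tibble(setNames(
      rep(list(numeric(0)), length(nm) + 2L),
      c("subject_id", "roi_role", nm)
    ))
    out$subject_id <- character(0)
    out$roi_role <- character(0)
    readr::write_csv(out, path)
    return(invisible(path))
  }
  rows <- as_tibble(rows)
  missing <- setdiff(c("subject_id", "roi_role", nm), names(rows))
  if (length(missing) > 0L) {
    abort(paste0("feature table is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  out <- rows[, c("subject_id", "roi_role", nm)]
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  # base read.csv: strtod parsing reproduces the written doubles exactly,
  # so write -> read -> write is byte-identical
  as_tibble(utils::read.csv(path, check.names = FALSE,
                            colClasses = c(subject_id = "character",
                                           roi_role = "character")))
}
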