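#' ROI algebra for habitat construction
#'
#' The recurrent habitat is the recurrence volume (GTVr) clipped to the
#' pre-treatment tumor volume (GTV); the non-recurrent habitat is the set
#' difference GTV minus GTVr. `subtract_mask()` implements the voxelwise
#' difference, `overlap_fraction()` the containment fraction used by the
#' in-field rule, and `make_habitats()` assembles the pair.
#'
#' @param a,b,inner,outer `roi_mask` objects on the same grid.
#' @return `subtract_mask()` returns an `roi_mask`; `overlap_fraction()` a
#'   number in \[0, 1\].
#' @export
subtract_mask <- function(a, b) {
  check_same_grid(a, b)
  roi_mask(ifelse(a$data == 1L & b$data == 0L, 1L, 0L),
           role = a$role, spacing = a$spacing)
}

#' @rdname subtract_mask
#' @export
overlap_fraction <- function(inner, outer) {
  check_same_grid(inner, outer)
  n_in <- mask_count(inner)
  if (n_in == 0L) {
    abort("`inner` mask is empty; overlap fraction is undefined.")
  }
  sum(inner$data == 1L & outer$data == 1L) / n_in
}

#' Classify a recurrence as in-field
#'
#' A recurrence is in-field when at least 95% of the recurrence volume lies
#' within the 95% isodose region of the delivered plan. The threshold
#' comparison is inclusive (>= 0.95).
#'
#' @param gtvr Recurrence mask.
#' @param isodose95 95%-isodose region mask.
#' @param threshold Containment threshold; default 0.95.
#' @return Logical scalar.
#' @export
classify_infield <- function(gtvr, isodose95, threshold = 0.95) {
  overlap_fraction(gtvr, isodose95) >= threshold
}

#' Build the recurrent / non-recurrent habitat pair
#'
#' The recurrent habitat is `gtvr` intersected with `gtv` (recurrence voxels
#' contoured slightly outside the tumor are clipped in, with a warning, not
#' rejected: the recurrence contour originates on a different scan, so small
#' excursions are expected). The non-recurrent habitat is `gtv` minus
#' `gtvr`. A subject whose non-recurrent habitat is empty (recurrence covers
#' the whole tumor) is unusable and raises an error.
#'
#' @param gtv Tumor mask at diagnosis.
#' @param gtvr Recurrence mask.
#' @param subject_id Subject label carried through to the feature table.
#' @return A `habitat_pair`: list with `recurrent`, `nonrecurrent`
#'   (`roi_mask`, roles GTVr / GTVnr) and `subject_id`.
#' @export
make_habitats <- function(gtv, gtvr, subject_id = "subject") {
  check_same_grid(gtv, gtvr)
  inter <- gtv$data == 1L & gtvr$data == 1L
  if (!any(inter)) {
    abort("gtvr does not intersect gtv; no recurrent habitat.")
  }
  n_outside <- sum(gtvr$data == 1L & gtv$data == 0L)
  if (n_outside > 0L) {
    warn(sprintf(
      "%d GTVr voxel(s) lie outside GTV; clipped to the recurrent habitat.",
      n_outside
    ))
  }
  rec <- roi_mask(array(as.integer(inter), dim = dim(gtv$data)),
                  role = "GTVr", spacing = gtv$spacing)
  nonrec <- roi_mask(
    array(as.integer(gtv$data == 1L & gtvr$data == 0L), dim = dim(gtv$data)),
    role = "GTVnr", spacing = gtv$spacing
  )
  if (mask_count(nonrec) == 0L) {
    abort("non-recurrent habitat is empty (GTVr covers GTV); subject unusable.")
  }
  structure(
    list(recurrent = rec, nonrecurrent = nonrec,
         subject_id = as.character(subject_id)),
    class = "habitat_pair"
  )
}

#' @export
print.habitat_pair <- function(x, ...) {
  cat(sprintf(
    "<habitat_pair '%s'> recurrent %d voxels, non-recurrent %d voxels\n",
    x$subject_id, mask_count(x$recurrent), mask_count(x$nonrecurrent)
  ))
  invisible(x)
}

check_same_grid <- function(a, b) {
  da <- if (inherits(a, "image_volume")) dim(a$data) else dim(a$data)
  db <- dim(b$data)
  if (!identical(da, db)) {
    abort(sprintf("grid mismatch: %s vs %s.",
                  paste(da, collapse = "x"), paste(db, collapse = "x")))
  }
  invisible(TRUE)
}
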