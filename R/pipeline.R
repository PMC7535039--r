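#' Validate one subject's inputs
#'
#' Checks grid agreement of all masks with the volume, nonemptiness of both
#' habitats, minimum habitat voxel counts, and (when an isodose mask is
#' present) the in-field status. Returns a verdict object instead of
#' erroring so the pipeline can exclude and report.
#'
#' @param volume An [image_volume()].
#' @param gtv,gtvr `roi_mask`s; `isodose95` optional (`NULL` to skip the
#'   in-field check).
#' @param min_voxels Minimum habitat size; default 8.
#' @return List with `valid` (logical), `reasons` (character),
#'   `warnings` (character), `infield` (logical or NA), `overlap` (numeric
#'   or NA).
#' @export
validate_subject <- function(volume, gtv, gtvr, isodose95 = NULL,
                             min_voxels = 8L) {
  reasons <- character(0)
  warnings <- character(0)
  infield <- NA
  overlap <- NA_real_
  for (m in list(gtv = gtv, gtvr = gtvr)) {
    if (!identical(dim(m$data), dim(volume$data))) {
      reasons <- c(reasons, "grid mismatch between mask and volume")
    }
  }
  if (length(reasons) == 0L) {
    n_rec <- sum(gtv$data == 1L & gtvr$data == 1L)
    n_non <- sum(gtv$data == 1L & gtvr$data == 0L)
    if (n_rec == 0L) reasons <- c(reasons, "empty recurrent habitat")
    if (n_non == 0L) {
      reasons <- c(reasons, "empty non-recurrent habitat (GTVr covers GTV)")
    }
    if (n_rec > 0L && n_rec < min_voxels) {
      reasons <- c(reasons, sprintf("recurrent habitat below %d voxels",
                                    min_voxels))
    }
    if (n_non > 0L && n_non < min_voxels) {
      reasons <- c(reasons, sprintf("non-recurrent habitat below %d voxels",
                                    min_voxels))
    }
    if (!is.null(isodose95)) {
      if (!identical(dim(isodose95$data), dim(volume$data))) {
        reasons <- c(reasons, "grid mismatch between isodose mask and volume")
      } else if (mask_count(gtvr) > 0L) {
        overlap <- overlap_fraction(gtvr, isodose95)
        infield <- overlap >= 0.95
        if (!infield) {
          warnings <- c(warnings, sprintf(
            "out-of-field recurrence (overlap %.3f < 0.95); still analyzable",
            overlap
          ))
        }
      }
    }
  }
  list(valid = length(reasons) == 0L, reasons = reasons,
       warnings = warnings, infield = infield, overlap = overlap)
}

#' Run the full habitat-radiomics pipeline
#'
#' End-to-end orchestration: load or generate a cohort, validate each
#' subject, partition the tumor into habitats, extract the 47 features per
#' habitat, and run the paired statistical stage. All outputs are written
#' as CSV (features, tests, correlations, PCA scores and variance) plus a
#' plain-text report; subjects failing validation are excluded and listed,
#' never silently dropped. Deterministic given the seed.
#'
#' @param config Either a path to a YAML file or a list, with entries:
#'   `phantom` (a list of [phantom_config()] arguments) or `manifest`
#'   (path to a cohort manifest CSV with columns `subject_id`, `volume`,
#'   `gtv`, `gtvr` and optionally `isodose95`); optional
#'   `quantization_levels` (default 256), `alpha` (default 0.05), `seed`
#'   (default 1), `require_infield` (default FALSE), `plots` (default
#'   FALSE).
#' @param out_dir Output directory.
#' @return Invisibly, a `hetrad_run`: list with `features`, `study`,
#'   `subjects` (per-subject verdict tibble), `excluded`, `paths`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort("`config` must be a list or a YAML path.")
  levels <- config$quantization_levels %||% 256L
  alpha <- config$alpha %||% 0.05
  seed <- as.integer(config$seed %||% 1L)
  require_infield <- isTRUE(config$require_infield)
  if (!(alpha > 0 && alpha < 1)) abort("`alpha` must lie in (0, 1).")
  if (levels < 2L) abort("`quantization_levels` must be >= 2.")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  subjects <- load_cohort(config, seed)
  if (length(subjects) == 0L) abort("no subjects in input.")

  verdicts <- vector("list", length(subjects))
  feat_rows <- list()
  for (i in seq_along(subjects)) {
    s <- subjects[[i]]
    v <- validate_subject(s$volume, s$gtv, s$gtvr, s$isodose95)
    if (v$valid && require_infield && identical(v$infield, FALSE)) {
      v$valid <- FALSE
      v$reasons <- c(v$reasons, "out-of-field recurrence (strict mode)")
    }
    if (v$valid) {
      pair <- suppressWarnings(
        make_habitats(s$gtv, s$gtvr, subject_id = s$subject_id)
      )
      feat_rows[[length(feat_rows) + 1L]] <-
        extract_all(s$volume, pair, ng = levels)
    }
    verdicts[[i]] <- tibble(
      subject_id = s$subject_id, valid = v$valid,
      reasons = paste(v$reasons, collapse = "; "),
      warnings = paste(v$warnings, collapse = "; "),
      infield = v$infield, isodose_overlap = v$overlap,
      n_gtv = mask_count(s$gtv), n_gtvr = mask_count(s$gtvr)
    )
  }
  subject_table <- dplyr::bind_rows(verdicts)
  excluded <- subject_table$subject_id[!subject_table$valid]
  if (length(feat_rows) == 0L) abort("no valid subjects after validation.")
  features <- dplyr::bind_rows(feat_rows)

  n_valid <- length(unique(features$subject_id))
  study <- if (n_valid >= 3L) run_statistics(features, alpha = alpha) else NULL

  paths <- list(
    features = file.path(out_dir, "features.csv"),
    subjects = file.path(out_dir, "subjects.csv"),
    tests = file.path(out_dir, "tests.csv"),
    corr = file.path(out_dir, "corr.csv"),
    corr_mask = file.path(out_dir, "corr_mask.csv"),
    pca_scores = file.path(out_dir, "pca_scores.csv"),
    pca_variance = file.path(out_dir, "pca_variance.csv"),
    report = file.path(out_dir, "report.txt")
  )
  write_feature_table(features, paths$features)
  readr::write_csv(subject_table, paths$subjects)
  if (!is.null(study)) {
    readr::write_csv(study$tests, paths$tests)
    if (!is.null(study$corr)) {
      readr::write_csv(as_tibble(as.data.frame(study$corr$r),
                                 rownames = "feature"), paths$corr)
      readr::write_csv(as_tibble(as.data.frame(study$corr$significant),
                                 rownames = "feature"), paths$corr_mask)
    }
    if (!is.null(study$pca)) {
      readr::write_csv(study$pca$scores, paths$pca_scores)
      readr::write_csv(
        tibble(component = paste0("PC", seq_along(
          study$pca$explained_variance_fraction)),
          explained_variance_fraction = study$pca$explained_variance_fraction),
        paths$pca_variance
      )
    }
  }
  writeLines(run_report(config, subject_table, study, levels, alpha, seed),
             paths$report)
  if (isTRUE(config$plots) && !is.null(study) && !is.null(study$pca)) {
    ggplot2::ggsave(file.path(out_dir, "pca.png"), autoplot(study$pca),
                    width = 6, height = 5, dpi = 120)
    if (!is.null(study$corr)) {
      ggplot2::ggsave(file.path(out_dir, "corr.png"), autoplot(study$corr),
                      width = 6, height = 5, dpi = 120)
    }
  }
  invisible(structure(
    list(features = features, study = study, subjects = subject_table,
         excluded = excluded, paths = paths),
    class = "hetrad_run"
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

load_cohort <- function(config, seed) {
  if (!is.null(config$phantom)) {
    args <- config$phantom
    if (is.null(args$seed)) args$seed <- seed
    pc <- do.call(phantom_config, args)
    lapply(seq_len(pc$n_subjects), function(i) generate_phantom(pc, i))
  } else if (!is.null(config$manifest)) {
    man <- readr::read_csv(config$manifest, show_col_types = FALSE,
                           progress = FALSE)
    lapply(seq_len(nrow(man)), function(i) {
      vol <- read_volume(man$volume[i], id = man$subject_id[i])
      iso <- if ("isodose95" %in% names(man) && !is.na(man$isodose95[i])) {
        read_mask(man$isodose95[i], vol, role = "isodose95")
      } else NULL
      list(
        subject_id = man$subject_id[i], volume = vol,
        gtv = read_mask(man$gtv[i], vol, role = "GTV"),
        gtvr = read_mask(man$gtvr[i], vol, role = "GTVr"),
        isodose95 = iso
      )
    })
  } else {
    abort("config must contain either `phantom` or `manifest`.")
  }
}

run_report <- function(config, subject_table, study, levels, alpha, seed) {
  lines <- c(
    "habitat radiomics run report",
    sprintf("quantization levels: %d (Lloyd-Max, quantile init, tol 1e-8)",
            levels),
    sprintf("alpha: %g; Bonferroni threshold: %.6g (displayed %.3f)",
            alpha, alpha / 47, round(alpha / 47, 3)),
    sprintf("seed: %d", seed),
    "NGTDM epsilon guard: 1e-6; Shapiro branch threshold: 0.05",
    sprintf("subjects: %d total, %d valid, %d excluded",
            nrow(subject_table), sum(subject_table$valid),
            sum(!subject_table$valid))
  )
  bad <- subject_table[!subject_table$valid, ]
  if (nrow(bad) > 0L) {
    lines <- c(lines, "excluded subjects:",
               sprintf("  %s: %s", bad$subject_id, bad$reasons))
  }
  if (!is.null(study)) {
    lines <- c(
      lines,
      sprintf("features tested: %d; significant: %d", nrow(study$tests),
              length(study$significant)),
      if (length(study$significant) > 0L) {
        paste0("significant features: ",
               paste(study$significant, collapse = ", "))
      },
      if (!is.null(study$pca)) {
        sprintf("PC1/PC2 explained variance: %.1f%% / %.1f%%",
                100 * study$pca$explained_variance_fraction[1],
                100 * study$pca$explained_variance_fraction[2])
      },
      study$warnings
    )
  }
  lines[!vapply(lines, is.null, logical(1))]
}

#' @export
print.hetrad_run <- function(x, ...) {
  cat(sprintf("<hetrad_run> %d subjects (%d excluded), %d feature rows\n",
              nrow(x$subjects), length(x$excluded), nrow(x$features)))
  if (!is.null(x$study)) print(x$study)
  invisible(x)
}
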