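#' Paired recurrent-minus-nonrecurrent feature differences
#'
#' Builds the per-subject difference table d_f(k) = value(recurrent, k) -
#' value(nonrecurrent, k) for every feature, from a wide feature table with
#' one row per (subject, ROI role).
#'
#' @param features Tibble with columns `subject_id`, `roi_role` (values
#'   `"recurrent"` / `"nonrecurrent"`) and the 47 feature columns, as
#'   produced by [extract_all()] / [write_feature_table()].
#' @return Tibble with `subject_id` plus one difference column per feature.
#' @export
paired_differences <- function(features) {
  features <- as_tibble(features)
  nm <- intersect(hetrad_feature_names(), names(features))
  if (length(nm) == 0L) abort("no recognized feature columns.")
  rec <- dplyr::filter(features, .data$roi_role == "recurrent")
  non <- dplyr::filter(features, .data$roi_role == "nonrecurrent")
  if (nrow(rec) != nrow(non)) {
    abort("unequal numbers of recurrent and nonrecurrent rows.")
  }
  rec <- dplyr::arrange(rec, .data$subject_id)
  non <- dplyr::arrange(non, .data$subject_id)
  if (!identical(rec$subject_id, non$subject_id)) {
    abort("subject_id sets do not match between the two ROI roles.")
  }
  out <- as_tibble(as.data.frame(
    as.matrix(rec[, nm]) - as.matrix(non[, nm])
  ))
  dplyr::bind_cols(tibble(subject_id = rec$subject_id), out)
}

#' Bonferroni-corrected significance threshold
#'
#' `alpha / m`. Selection always uses the unrounded value; `display`
#' rounds to 3 decimals for reporting only (0.05 / 47 displays as 0.001).
#'
#' @param alpha Family-wise error rate.
#' @param m Number of tests, >= 1.
#' @return The unrounded threshold, with attribute `display`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m = 47L) {
  if (m < 1L) abort("`m` must be >= 1.")
  thr <- alpha / m
  attr(thr, "display") <- round(thr, 3)
  thr
}

#' Normality-branched paired test of one feature's differences
#'
#' Shapiro-Wilk is run on the differences; if its p-value is below
#' `shapiro_alpha` (0.05) the Wilcoxon signed-rank test is used (zeros
#' dropped; exact distribution for n <= 25 without ties, otherwise normal
#' approximation with continuity correction), else the paired t-test.
#' Significance is judged against the unrounded `alpha / m`.
#'
#' @param d Numeric vector of paired differences, n >= 3.
#' @param alpha Family-wise error rate; default 0.05.
#' @param m Number of tests in the family; default 47.
#' @param feature Feature name carried into the result.
#' @param shapiro_alpha Normality branch threshold; default 0.05.
#' @return One-row tibble: `feature`, `n`, `shapiro_p`, `test_used`,
#'   `mean_diff`, `sd_diff`, `p_value`, `significant`, `degenerate`.
#' @export
test_feature <- function(d, alpha = 0.05, m = 47L, feature = "feature",
                         shapiro_alpha = 0.05) {
  d <- as.numeric(d)
  n <- length(d)
  if (n < 3L) abort("need n >= 3 paired differences.")
  mean_diff <- mean(d)
  sd_diff <- sd(d)
  if (sd_diff == 0) {
    return(tibble(
      feature = feature, n = n, shapiro_p = NA_real_,
      test_used = NA_character_, mean_diff = mean_diff, sd_diff = sd_diff,
      p_value = NA_real_, significant = FALSE, degenerate = TRUE
    ))
  }
  shapiro_p <- shapiro.test(d)$p.value
  if (shapiro_p < shapiro_alpha) {
    dz <- d[d != 0]
    has_ties <- anyDuplicated(abs(dz)) > 0L
    use_exact <- length(dz) <= 25L && !has_ties
    p <- if (length(dz) == 0L) {
      1
    } else {
      suppressWarnings(
        wilcox.test(dz, exact = use_exact, correct = TRUE)$p.value
      )
    }
    test_used <- "wilcoxon_signed_rank"
  } else {
    p <- t.test(d)$p.value
    test_used <- "paired_t"
  }
  thr <- bonferroni_threshold(alpha, m)
  tibble(
    feature = feature, n = n, shapiro_p = shapiro_p, test_used = test_used,
    mean_diff = mean_diff, sd_diff = sd_diff, p_value = p,
    significant = p < as.numeric(thr), degenerate = FALSE
  )
}

#' Test every feature column of a difference table
#'
#' @param diffs Difference table from [paired_differences()].
#' @inheritParams test_feature
#' @return Tibble with one [test_feature()] row per feature.
#' @export
test_features <- function(diffs, alpha = 0.05, m = NULL,
                          shapiro_alpha = 0.05) {
  nm <- setdiff(names(diffs), "subject_id")
  if (is.null(m)) m <- length(nm)
  purrr::map_dfr(nm, function(f) {
    test_feature(diffs[[f]], alpha = alpha, m = m, feature = f,
                 shapiro_alpha = shapiro_alpha)
  })
}

#' Pearson correlation matrix of paired differences
#'
#' Pairwise Pearson correlations (with p-values) between the difference
#' columns of the selected features; the significance mask marks p < 0.05
#' (unadjusted).
#'
#' @param diffs Difference table from [paired_differences()].
#' @param features Character vector of >= 2 feature columns to correlate.
#' @param sig_level Mask threshold; default 0.05.
#' @return A `habitat_corr`: list of matrices `r`, `p`, `significant`.
#' @export
correlation_matrix <- function(diffs, features, sig_level = 0.05) {
  if (length(features) < 2L) abort("need >= 2 features to correlate.")
  X <- as.matrix(diffs[, features])
  if (nrow(X) < 3L) abort("need n >= 3 subjects.")
  zero_var <- apply(X, 2, sd) == 0
  if (any(zero_var)) {
    abort(paste0("zero-variance difference column(s): ",
                 paste(features[zero_var], collapse = ", ")))
  }
  k <- length(features)
  r <- diag(1, k)
  p <- matrix(0, k, k)
  for (a in seq_len(k - 1)) {
    for (b in (a + 1):k) {
      ct <- cor.test(X[, a], X[, b], method = "pearson")
      r[a, b] <- r[b, a] <- unname(ct$estimate)
      p[a, b] <- p[b, a] <- ct$p.value
    }
  }
  dimnames(r) <- dimnames(p) <- list(features, features)
  structure(
    list(r = r, p = p, significant = p < sig_level & !diag(k),
         sig_level = sig_level),
    class = "habitat_corr"
  )
}

#' @export
print.habitat_corr <- function(x, ...) {
  cat(sprintf("<habitat_corr> %d features, %d significant off-diagonal pairs (p < %g)\n",
              nrow(x$r), sum(x$significant[upper.tri(x$significant)]),
              x$sig_level))
  invisible(x)
}

#' @method tidy habitat_corr
#' @export
tidy.habitat_corr <- function(x, ...) {
  nm <- rownames(x$r)
  ut <- which(upper.tri(x$r), arr.ind = TRUE)
  tibble(
    feature_a = nm[ut[, 1]], feature_b = nm[ut[, 2]],
    r = x$r[ut], p_value = x$p[ut], significant = x$significant[ut]
  )
}

#' PCA of region feature vectors
#'
#' Pools the recurrent and non-recurrent rows (2n region vectors) restricted
#' to the selected features, z-scores each column, and runs PCA. Components
#' are ordered by decreasing explained variance; each component's sign is
#' fixed so its largest-magnitude loading is positive.
#'
#' @param features Wide feature table (as for [paired_differences()]).
#' @param which_features Character vector of >= 2 feature columns.
#' @return A `habitat_pca`: list with `loadings`, `scores` (tibble with
#'   `subject_id`, `roi_role`, `PC1`, ...), `explained_variance_fraction`.
#' @export
pca_regions <- function(features, which_features) {
  if (length(which_features) < 2L) abort("need >= 2 features for PCA.")
  features <- as_tibble(features)
  X <- as.matrix(features[, which_features])
  if (nrow(X) < 3L) abort("need >= 3 region rows for PCA.")
  if (any(apply(X, 2, sd) == 0)) {
    abort("constant feature column after pooling; PCA undefined.")
  }
  pc <- prcomp(X, center = TRUE, scale. = TRUE)
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  rot <- sweep(pc$rotation, 2, flip, `*`)
  scores <- sweep(pc$x, 2, flip, `*`)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  structure(
    list(
      loadings = rot,
      scores = dplyr::bind_cols(
        features[, c("subject_id", "roi_role")],
        as_tibble(as.data.frame(scores))
      ),
      explained_variance_fraction = ev
    ),
    class = "habitat_pca"
  )
}

#' @export
print.habitat_pca <- function(x, ...) {
  ev <- x$explained_variance_fraction
  cat(sprintf("<habitat_pca> %d components; PC1 %.0f%%, PC2 %.0f%% of variance\n",
              length(ev), 100 * ev[1], 100 * ev[min(2, length(ev))]))
  invisible(x)
}

# mean silhouette of the two ROI-role groups using PC1 scores only
silhouette_pc1 <- function(pca) {
  sc <- pca$scores
  x <- sc$PC1
  g <- sc$roi_role
  s <- vapply(seq_along(x), function(i) {
    own <- x[g == g[i] & seq_along(x) != i]
    oth <- x[g != g[i]]
    a <- mean(abs(x[i] - own))
    b <- mean(abs(x[i] - oth))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

#' Run the full paired statistical stage
#'
#' Differences, normality-branched tests with Bonferroni selection, Pearson
#' correlation of the significant features' differences, and PCA of the
#' pooled region vectors on the significant features. If no feature reaches
#' the Bonferroni threshold, correlation and PCA fall back to the `top_k`
#' features by p-value, with a warning recorded in the result.
#'
#' @param features Wide feature table: one row per (subject, ROI role).
#' @param alpha Family-wise error rate; default 0.05.
#' @param top_k Fallback feature count when nothing is significant.
#' @return A `habitat_study`: list with `tests` (tibble), `significant`
#'   (character), `corr` (`habitat_corr`), `pca` (`habitat_pca`),
#'   `threshold`, `alpha`, `n`, `warnings`.
#' @export
run_statistics <- function(features, alpha = 0.05, top_k = 7L) {
  diffs <- paired_differences(features)
  n <- nrow(diffs)
  if (n < 3L) abort("need at least 3 subjects.")
  nm <- setdiff(names(diffs), "subject_id")
  tests <- test_features(diffs, alpha = alpha, m = length(nm))
  sig <- tests$feature[tests$significant %in% TRUE]
  warnings <- character(0)
  sel <- sig
  if (length(sig) == 0L) {
    ok <- tests[!tests$degenerate & !is.na(tests$p_value), ]
    sel <- head(ok$feature[order(ok$p_value)], top_k)
    warnings <- c(warnings, sprintf(
      "no feature significant at alpha/m; correlation/PCA use top %d by p-value.",
      length(sel)
    ))
  }
  corr <- if (length(sel) >= 2L) {
    correlation_matrix(diffs, sel)
  } else NULL
  pca <- if (length(sel) >= 2L) {
    pca_regions(features, sel)
  } else NULL
  structure(
    list(tests = tests, significant = sig, selected = sel, corr = corr,
         pca = pca, threshold = bonferroni_threshold(alpha, length(nm)),
         alpha = alpha, n = n, diffs = diffs, warnings = warnings),
    class = "habitat_study"
  )
}

#' @export
print.habitat_study <- function(x, ...) {
  cat(sprintf(
    "<habitat_study> n = %d subjects, %d features tested, %d significant at p < %.3g\n",
    x$n, nrow(x$tests), length(x$significant), as.numeric(x$threshold)
  ))
  if (length(x$significant) > 0L) {
    cat("  significant:", paste(x$significant, collapse = ", "), "\n")
  }
  for (w in x$warnings) cat("  note:", w, "\n")
  invisible(x)
}

#' Tidy and summarize a habitat study
#'
#' `tidy()` returns the per-feature test table (feature, n, shapiro_p,
#' test_used, mean and SD of the differences, p-value, significance);
#' `glance()` a one-row summary (n, features tested, significant count,
#' threshold, PC1/PC2 explained variance).
#'
#' @param x A `habitat_study` from [run_statistics()].
#' @param ... Unused.
#' @method tidy habitat_study
#' @export
tidy.habitat_study <- function(x, ...) {
  x$tests
}

#' @rdname tidy.habitat_study
#' @method glance habitat_study
#' @export
glance.habitat_study <- function(x, ...) {
  ev <- if (!is.null(x$pca)) x$pca$explained_variance_fraction else c(NA, NA)
  tibble(
    n_subjects = x$n,
    n_features = nrow(x$tests),
    n_significant = length(x$significant),
    threshold = as.numeric(x$threshold),
    threshold_display = attr(x$threshold, "display"),
    pc1_variance_fraction = ev[1],
    pc2_variance_fraction = if (length(ev) >= 2) ev[2] else NA_real_
  )
}
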