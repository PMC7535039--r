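mk_feature_table <- function(n, values_rec, values_non) {
  nm <- hetrad_feature_names()
  mk <- function(ids, role, vals) {
    dplyr::bind_cols(
      tibble::tibble(subject_id = ids, roi_role = role),
      tibble::as_tibble(as.data.frame(vals) |> setNames(nm))
    )
  }
  ids <- sprintf("S%02d", seq_len(n))
  dplyr::bind_rows(mk(ids, "recurrent", values_rec),
                   mk(ids, "nonrecurrent", values_non))
}

test_that("paired differences are recurrent minus non-recurrent", {
  set.seed(90)
  n <- 6
  base <- matrix(rnorm(n * 47), n, 47)
  ft_same <- mk_feature_table(n, base, base)
  d0 <- paired_differences(ft_same)
  expect_true(all(as.matrix(d0[, -1]) == 0))

  shift <- matrix(rep(seq_len(47), each = n), n, 47)
  ft_c <- mk_feature_table(n, base + shift, base)
  dc <- paired_differences(ft_c)
  for (j in c(1, 20, 47)) {
    expect_equal(unname(as.matrix(dc[, -1])[, j]), rep(j, n))
  }
  # brute-force recomputation of column means
  ft_r <- mk_feature_table(n, base + shift, base * 2)
  dr <- paired_differences(ft_r)
  manual <- colMeans((base + shift) - base * 2)
  expect_equal(unname(colMeans(as.matrix(dr[, -1]))), unname(manual))
})

test_that("Bonferroni threshold selects unrounded, displays rounded", {
  thr <- bonferroni_threshold(0.05, 47)
  expect_equal(as.numeric(thr), 0.05 / 47)
  expect_gt(as.numeric(thr), 0.001)   # unrounded value is 0.0010638...
  expect_equal(attr(thr, "display"), 0.001)
  expect_equal(as.numeric(bonferroni_threshold(0.05, 1)), 0.05)
  expect_equal(as.numeric(bonferroni_threshold(0.05, 50)), 0.001)
  expect_error(bonferroni_threshold(0.05, 0), ">= 1")
})

test_that("normal differences choose the paired t branch", {
  set.seed(91)
  picks <- replicate(100, {
    test_feature(rnorm(14, mean = 2, sd = 1))$test_used
  })
  expect_gte(sum(picks == "paired_t"), 90)
})

test_that("heavily skewed differences fall to the Wilcoxon branch", {
  set.seed(92)
  picks <- replicate(100, {
    test_feature(rexp(14) - 0.1)$test_used
  })
  expect_gte(mean(picks == "wilcoxon_signed_rank"), 0.5)
})

test_that("branching follows the Shapiro p-value exactly", {
  set.seed(93)
  for (i in 1:50) {
    d <- if (i %% 2) rnorm(14) else rexp(14)^2
    r <- test_feature(d)
    expected <- if (r$shapiro_p < 0.05) "wilcoxon_signed_rank" else "paired_t"
    expect_identical(r$test_used, expected)
  }
})

test_that("paired t p-values match the closed form", {
  set.seed(94)
  for (i in 1:20) {
    d <- rnorm(14, mean = 0.3)
    r <- test_feature(d)
    if (r$test_used != "paired_t") next
    tstat <- r$mean_diff / (r$sd_diff / sqrt(r$n))
    p_closed <- 2 * pt(-abs(tstat), df = r$n - 1)
    expect_equal(r$p_value, p_closed, tolerance = 1e-12)
  }
})

test_that("Wilcoxon exact p-values reproduce the 2^5 sign enumeration", {
  set.seed(95)
  for (i in 1:10) {
    d <- round(rexp(5, rate = 0.2) + 0.5, 3) * sample(c(-1, 1), 5, TRUE)
    if (anyDuplicated(abs(d))) next
    got <- suppressWarnings(wilcox.test(d, exact = TRUE)$p.value)
    # enumerate all 2^5 sign assignments of the ranked magnitudes
    rk <- rank(abs(d))
    W_obs <- sum(rk[d > 0])
    Ws <- sapply(0:31, function(m) {
      signs <- as.integer(intToBits(m))[1:5]
      sum(rk[signs == 1])
    })
    n <- length(Ws)
    EW <- sum(rk) / 2
    p_enum <- min(1, 2 * min(mean(Ws <= W_obs), mean(Ws >= W_obs)))
    # two-sided exact p: standard doubling of the smaller tail
    expect_equal(got, p_enum, tolerance = 1e-12)
  }
})

test_that("zero-variance differences are flagged degenerate", {
  r <- test_feature(rep(2, 14))
  expect_true(r$degenerate)
  expect_false(r$significant)
})

test_that("null Wilcoxon type-I error is near nominal", {
  set.seed(96)
  rej <- replicate(2000, {
    d <- rexp(14) * sample(c(-1, 1), 14, replace = TRUE)   # symmetric Laplace
    r <- test_feature(d, alpha = 0.05, m = 1)
    !is.na(r$p_value) && r$p_value < 0.05
  })
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})

test_that("correlation matrix is symmetric with unit diagonal", {
  set.seed(97)
  n <- 14
  base <- matrix(rnorm(n * 47), n, 47)
  rec <- base
  rec[, 2] <- rec[, 1]            # duplicated feature
  rec[, 3] <- -rec[, 1]           # anti-correlated feature
  ft <- mk_feature_table(n, rec, matrix(0, n, 47))
  d <- paired_differences(ft)
  nm <- hetrad_feature_names()
  cm <- correlation_matrix(d, nm[1:3])
  expect_equal(cm$r, t(cm$r))
  expect_equal(unname(diag(cm$r)), rep(1, 3))
  expect_equal(cm$r[1, 2], 1)
  expect_true(cm$significant[1, 2])
  expect_equal(cm$r[1, 3], -1)
  td <- tidy(cm)
  expect_equal(nrow(td), 3)

  # independent noise: ~5% of pairs significant under the null
  set.seed(98)
  hits <- replicate(1000, {
    dd <- tibble::tibble(subject_id = 1:14, A = rnorm(14), B = rnorm(14))
    correlation_matrix(dd, c("A", "B"))$significant[1, 2]
  })
  expect_gt(mean(hits), 0.02)
  expect_lt(mean(hits), 0.09)
})

test_that("PCA normalizes, orders components, and fixes signs", {
  set.seed(99)
  n <- 28
  X <- matrix(rnorm(n * 7), n, 7)
  nm <- hetrad_feature_names()[1:7]
  ft <- tibble::as_tibble(as.data.frame(X) |> setNames(nm))
  ft <- dplyr::bind_cols(
    tibble::tibble(subject_id = rep(sprintf("S%02d", 1:14), 2),
                   roi_role = rep(c("recurrent", "nonrecurrent"), each = 14)),
    ft
  )
  pca <- pca_regions(ft, nm)
  ev <- pca$explained_variance_fraction
  expect_equal(sum(ev), 1, tolerance = 1e-9)
  expect_true(all(diff(ev) <= 1e-12))
  expect_true(all(ev >= 0 & ev <= 1))
  # scores have zero column means and reproduce loadings^T z-scored data
  sc <- as.matrix(pca$scores[, paste0("PC", 1:7)])
  expect_equal(unname(colMeans(sc)), rep(0, 7), tolerance = 1e-9)
  Z <- scale(X)
  expect_equal(unname(sc), unname(Z %*% pca$loadings), tolerance = 1e-9)
  # sign convention: largest-magnitude loading of each PC is positive
  for (j in 1:7) {
    v <- pca$loadings[, j]
    expect_gte(v[which.max(abs(v))], 0)
  }

  # two perfectly correlated features: PC1 explains everything
  ft2 <- ft[, 1:2]
  ft2$F1 <- rnorm(n)
  ft2$F2 <- 2 * ft2$F1
  p2 <- pca_regions(ft2, c("F1", "F2"))
  expect_equal(p2$explained_variance_fraction[1], 1, tolerance = 1e-9)
})

test_that("the full statistical stage ties the pieces together", {
  set.seed(101)
  n <- 14
  base <- matrix(rnorm(n * 47), n, 47)
  # inject a strong paired effect in three feature columns
  eff <- matrix(0, n, 47); eff[, c(5, 20, 40)] <- 3
  other <- matrix(rnorm(n * 47), n, 47)
  ft_non <- mk_feature_table(n, base + eff, other)
  study <- run_statistics(ft_non)
  expect_s3_class(study, "habitat_study")
  expect_equal(nrow(study$tests), 47)
  nm <- hetrad_feature_names()
  expect_true(all(nm[c(5, 20, 40)] %in% study$significant))
  g <- glance(study)
  expect_equal(g$n_subjects, 14)
  expect_equal(g$threshold_display, 0.001)
  td <- tidy(study)
  expect_identical(td, study$tests)

  # doubled alpha: significant set is a superset
  study2 <- run_statistics(ft_non, alpha = 0.1)
  expect_true(all(study$significant %in% study2$significant))

  # identical pairs: nothing significant, all degenerate
  ft_id <- mk_feature_table(n, base, base)
  study0 <- run_statistics(ft_id)
  expect_length(study0$significant, 0)
  expect_true(all(study0$tests$degenerate))
})

test_that("autoplot methods return ggplot objects", {
  set.seed(102)
  cfg <- small_phantom_config(seed = 15)
  ph <- generate_phantom(cfg, 1)
  pair <- make_habitats(ph$gtv, ph$gtvr, ph$subject_id)
  h <- paired_histograms(ph$volume, pair)
  expect_s3_class(autoplot(h), "ggplot")
  n <- 14
  base <- matrix(rnorm(n * 47), n, 47)
  eff <- matrix(0, n, 47); eff[, 1:5] <- 2
  ft <- mk_feature_table(n, base + eff, base)
  study <- run_statistics(ft)
  if (!is.null(study$pca)) {
    expect_s3_class(autoplot(study, "pca"), "ggplot")
  }
  if (!is.null(study$corr)) {
    expect_s3_class(autoplot(study, "correlation"), "ggplot")
  }
})
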