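# ggplot2 methods for the result objects.

#' Plot a paired habitat histogram
#'
#' Shared-scale intensity histograms of the recurrent and non-recurrent
#' habitats as step outlines.
#'
#' @param object A `habitat_histogram` from [paired_histograms()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot habitat_histogram
#' @export
autoplot.habitat_histogram <- function(object, ...) {
  mids <- (object$bin_edges[-1] + object$bin_edges[-length(object$bin_edges)]) / 2
  df <- tibble(
    intensity = rep(mids, 2),
    density = c(object$density_rec, object$density_nonrec),
    habitat = rep(c("recurrent", "non-recurrent"), each = length(mids))
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$intensity, .data$density,
                                   colour = .data$habitat)) +
    ggplot2::geom_step() +
    ggplot2::labs(
      title = paste0("Habitat intensity histograms — ", object$subject_id),
      x = "intensity", y = "relative frequency"
    )
}

#' Plot a correlation matrix of paired differences
#'
#' Heatmap of Pearson correlations; cells with p above the significance
#' level are left uncoloured.
#'
#' @param object A `habitat_corr` from [correlation_matrix()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot habitat_corr
#' @export
autoplot.habitat_corr <- function(object, ...) {
  nm <- rownames(object$r)
  df <- expand.grid(feature_a = nm, feature_b = nm, stringsAsFactors = FALSE)
  df$r <- as.vector(object$r)
  df$shown <- as.vector(object$p < object$sig_level)
  df$r[!df$shown] <- NA_real_
  ggplot2::ggplot(df, ggplot2::aes(.data$feature_a, .data$feature_b,
                                   fill = .data$r)) +
    ggplot2::geom_tile(colour = "grey70") +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), na.value = "white") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Pearson r")
}

#' Plot PCA scores of region vectors
#'
#' PC1/PC2 scatter of the pooled recurrent and non-recurrent region
#' vectors, with axis labels reporting explained variance.
#'
#' @param object A `habitat_pca` from [pca_regions()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot habitat_pca
#' @export
autoplot.habitat_pca <- function(object, ...) {
  ev <- object$explained_variance_fraction
  sc <- object$scores
  ggplot2::ggplot(sc, ggplot2::aes(.data$PC1, .data$PC2,
                                   colour = .data$roi_role)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = sprintf("PC1 (%.0f%%)", 100 * ev[1]),
      y = sprintf("PC2 (%.0f%%)", 100 * ev[min(2, length(ev))]),
      colour = "region"
    )
}

#' @rdname autoplot.habitat_pca
#' @param type Which panel to draw for a `habitat_study`: `"pca"` or
#'   `"correlation"`.
#' @method autoplot habitat_study
#' @export
autoplot.habitat_study <- function(object, type = c("pca", "correlation"),
                                   ...) {
  type <- match.arg(type)
  if (type == "pca") {
    if (is.null(object$pca)) abort("study has no PCA result.")
    autoplot(object$pca)
  } else {
    if (is.null(object$corr)) abort("study has no correlation result.")
    autoplot(object$corr)
  }
}
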