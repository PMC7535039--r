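#' Canonical radiomics feature names
#'
#' The 47 features computed per ROI, in fixed output order: 7 intensity
#' histogram features (computed on raw intensities), then 9 GLCM, 13 GLRLM,
#' 13 GLSZM and 5 NGTDM texture features (computed on Lloyd-Max quantized
#' gray levels).
#'
#' @param family Optional family filter: one of `"Intensity"`, `"GLCM"`,
#'   `"GLRLM"`, `"GLSZM"`, `"NGTDM"`.
#' @return Character vector of feature names.
#' @export
hetrad_feature_names <- function(family = NULL) {
  nms <- c(
    paste0("Intensity_", c("Mean", "Variance", "Skewness", "Kurtosis",
                           "MAD", "Hyperskewness", "Hyperflatness")),
    paste0("GLCM_", c("Energy", "Contrast", "Entropy", "Homogeneity",
                      "Correlation", "SumAverage", "Variance",
                      "Dissimilarity", "AutoCorrelation")),
    paste0("GLRLM_", c("SRE", "LRE", "GLN", "RLN", "RP", "LGRE", "HGRE",
                       "SRLGE", "SRHGE", "LRLGE", "LRHGE", "GLV", "RLV")),
    paste0("GLSZM_", c("SZE", "LZE", "GLN", "ZSN", "ZP", "LGZE", "HGZE",
                       "SZLGE", "SZHGE", "LZLGE", "LZHGE", "GLV", "ZSV")),
    paste0("NGTDM_", c("Coarseness", "Contrast", "Busyness", "Complexity",
                       "Strength"))
  )
  if (!is.null(family)) {
    family <- match.arg(family, c("Intensity", "GLCM", "GLRLM", "GLSZM",
                                  "NGTDM"))
    nms <- nms[startsWith(nms, paste0(family, "_"))]
  }
  nms
}
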