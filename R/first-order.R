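#' First-order intensity histogram features
#'
#' Seven features of the raw (unquantized) ROI intensity distribution,
#' using population (divide-by-N) moments: mean, variance, skewness,
#' kurtosis (raw 4th standardized moment; Gaussian -> 3), mean absolute
#' deviation, hyperskewness and hyperflatness (5th and 6th standardized
#' central moments). For a constant ROI the variance is 0 and the
#' standardized moments are undefined (`NaN`, with attribute
#' `undefined_reason`).
#'
#' @param x Numeric vector of ROI intensities, length >= 2.
#' @return Named numeric vector with names
#'   `Intensity_{Mean,Variance,Skewness,Kurtosis,MAD,Hyperskewness,Hyperflatness}`.
#' @export
first_order_features <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 2L) abort("first-order features need at least 2 voxels.")
  m <- mean(x)
  cm <- function(p) mean((x - m)^p)
  v <- cm(2)
  out <- c(
    Intensity_Mean = m,
    Intensity_Variance = v,
    Intensity_Skewness = NaN,
    Intensity_Kurtosis = NaN,
    Intensity_MAD = mean(abs(x - m)),
    Intensity_Hyperskewness = NaN,
    Intensity_Hyperflatness = NaN
  )
  if (v > 0) {
    s <- sqrt(v)
    out["Intensity_Skewness"] <- cm(3) / s^3
    out["Intensity_Kurtosis"] <- cm(4) / s^4
    out["Intensity_Hyperskewness"] <- cm(5) / s^5
    out["Intensity_Hyperflatness"] <- cm(6) / s^6
  } else {
    attr(out, "undefined_reason") <-
      "constant intensities: standardized moments undefined"
  }
  out
}
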