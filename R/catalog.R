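#' The 125-feature catalog
#'
#' Returns the fixed, ordered catalog of the 125 texture and geometry
#' features the extraction battery emits: 45 texture features across seven
#' models (co-occurrence statistics F1-F14, gray-level difference statistics
#' F15-F19, first-order statistics F20-F23, statistical feature matrix
#' F24-F27, Laws texture energy F28-F41, fractal Hurst coefficients F42-F43,
#' Fourier power spectrum F44-F45) and 80 geometry features (shape
#' descriptors F46-F58, Zernike moment magnitudes F59-F73, generic Fourier
#' descriptors F74-F125).
#'
#' Column identifiers combine index and name (e.g. \code{"F99_FD26"})
#' because bare names such as \code{Contrast} repeat across models.
#'
#' @return A data frame with columns \code{index} (integer 1..125),
#'   \code{feature} (e.g. \code{"F99"}), \code{name}, \code{model}, and
#'   \code{column} (the unique table header).
#' @examples
#' cat125 <- feature_catalog()
#' subset(cat125, feature == "F99")
#' table(cat125$model)
#' @export
feature_catalog <- function() {
  zern <- zernike_spec()
  zm_names <- sprintf("ZM%d%s", zern$n,
                      ifelse(zern$m < 0, paste0("-", -zern$m), zern$m))
  entries <- rbind(
    data.frame(model = "SGLCM", name = c(
      "ASM", "Contrast", "Correlation", "Sum_Squares", "Inverse_Diff_Moment",
      "Sum_Average", "Sum_Variance", "Sum_Entropy", "Entropy",
      "Diff_Variance", "Diff_Entropy", "Info_Measure1", "Info_Measure2",
      "Max_Corr_Coff")),
    data.frame(model = "GLDS", name = c(
      "Homogeneity", "Contrast", "Mean", "Energy", "Entropy")),
    data.frame(model = "FOS", name = c(
      "Mean", "Variance", "Skewness", "Kurtosis")),
    data.frame(model = "SFM", name = c(
      "Coarseness", "Contrast", "Periodicity", "Roughness")),
    data.frame(model = "LTEM", name = c(
      "EE", "SS", "WW", "RR", "EL", "SL", "WL", "RL", "SE", "WE", "RE",
      "WS", "RS", "RW")),
    data.frame(model = "Fractal", name = c("H1", "H2")),
    data.frame(model = "FPS", name = c("Sr", "Stheta")),
    data.frame(model = "Shape", name = c(
      "Area", "Major_Axis_Length", "Minor_Axis_Length", "Eccentricity",
      "Orientation", "Convex_Area", "Filled_Area", "Euler_Number",
      "Equiv_Diameter", "Solidity", "Extent", "Perimeter",
      "Perimeter_Cirratio")),
    data.frame(model = "Zernike", name = zm_names),
    data.frame(model = "GFD", name = sprintf("FD%d", 1:52))
  )
  entries$index <- seq_len(nrow(entries))
  entries$feature <- sprintf("F%d", entries$index)
  entries$column <- paste0(entries$feature, "_", entries$name)
  entries[, c("index", "feature", "name", "model", "column")]
}

# Cached catalog column names, used by table validation on every read/write.
catalog_columns <- local({
  cols <- NULL
  function() {
    if (is.null(cols)) cols <<- feature_catalog()$column
    cols
  }
})
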