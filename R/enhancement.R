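#' @title ROI contrast enhancement
#' @description Screen-film mammograms (CBIS-DDSM-like data) have low soft-
#'   tissue contrast. ROIs are enhanced by global histogram equalization,
#'   unsharp masking with strength 0.8, and a 3 x 3 median filter, in that
#'   order. Full-field digital images (INbreast-like data) are already
#'   well-contrasted and are passed through unchanged by disabling the step.
#' @name enhancement
NULL

#' Enhancement configuration
#'
#' @param enabled logical; `FALSE` makes [enhanceROI()] the identity.
#' @param strength unsharp-masking amount (default 0.8).
#' @param medianKernel odd side length of the median filter (default 3).
#' @param gaussianSigma sigma of the Gaussian blur used to form the unsharp
#'   high-pass residual (default 1).
#' @return A list of class `"EnhancementConfig"`.
#' @export
enhancementConfig <- function(enabled = TRUE, strength = 0.8,
                              medianKernel = 3L, gaussianSigma = 1) {
  stopifnot(strength >= 0, medianKernel %% 2 == 1, gaussianSigma > 0)
  structure(list(enabled = enabled, strength = strength,
                 medianKernel = as.integer(medianKernel),
                 gaussianSigma = gaussianSigma),
            class = "EnhancementConfig")
}

#' Enhance an ROI
#'
#' Applies, in order: global histogram equalization (256 bins over the ROI's
#' own intensity range), unsharp masking
#' `out = in + strength * (in - gaussian(in, sigma))` clipped to the input
#' range, and a median filter. Deterministic; output has the input's shape
#' and intensity range. A disabled config returns the input bit-identically.
#'
#' @param pixels numeric intensity matrix.
#' @param config an [enhancementConfig()].
#' @return Enhanced matrix of the same dimensions.
#' @export
enhanceROI <- function(pixels, config = enhancementConfig()) {
  stopifnot(is.matrix(pixels), length(pixels) > 0L)
  if (!config$enabled) return(pixels)
  lo <- min(pixels); hi <- max(pixels)
  if (hi <= lo) return(pixels)  # constant image: equalization/median no-ops
  # work in [0,1] on the ROI's own range
  x <- (pixels - lo) / (hi - lo)
  x <- as.matrix(EBImage::equalize(x, range = c(0, 1), levels = 256))
  blur <- as.matrix(EBImage::gblur(x, sigma = config$gaussianSigma))
  x <- clampRange(x + config$strength * (x - blur), 0, 1)
  r <- (config$medianKernel - 1L) %/% 2L
  x <- as.matrix(EBImage::medianFilter(x, size = r))
  x * (hi - lo) + lo
}

#' Median-filter a matrix (noise-reduction stage used by [enhanceROI()])
#'
#' Exposed separately so the denoising stage can be audited in isolation.
#'
#' @param pixels numeric intensity matrix.
#' @param kernel odd side length (default 3).
#' @return Filtered matrix.
#' @export
medianFilterROI <- function(pixels, kernel = 3L) {
  stopifnot(kernel %% 2 == 1)
  lo <- min(pixels); hi <- max(pixels)
  if (hi <= lo) return(pixels)
  x <- (pixels - lo) / (hi - lo)
  x <- as.matrix(EBImage::medianFilter(x, size = (kernel - 1L) %/% 2L))
  x * (hi - lo) + lo
}
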