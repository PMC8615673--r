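#' @title Multi-context ROI extraction
#' @description Two schemes extract ROIs with diverse contextual information
#'   around a segmented mass: scale-based (expanding the bounding box by a
#'   fixed percentage per edge) and translation-based (isotropic rescaling to
#'   a 256-pixel base followed by four-corner/center crops and their
#'   horizontal flips). Every emitted ROI is 224 x 224.
#' @name roi-context
NULL

.ROI_SIZE <- 224L
.BASE_SCALE <- 256L

# Crop a 0-based half-open bbox out of an intensity matrix.
cropBBox <- function(image, bbox) {
  image[(bbox[1L] + 1L):bbox[3L], (bbox[2L] + 1L):bbox[4L], drop = FALSE]
}

#' Expand a bounding box by a percentage of its own side lengths
#'
#' Each side grows by `percent`% of the corresponding bbox dimension on each
#' of its two edges (so `percent = 50` adds half the height above and below,
#' and half the width left and right), then the result is clamped to the
#' image bounds. The input box is always contained in the output.
#'
#' @param bbox integer vector `c(rowMin, colMin, rowMax, colMax)`, 0-based
#'   half-open.
#' @param percent non-negative expansion percentage per edge.
#' @param imageShape integer vector `c(rows, cols)` of the host image.
#' @return Expanded, clamped bbox in the same encoding.
#' @examples
#' expandBBox(c(100, 100, 200, 200), 50, c(1000, 1000)) # c(50, 50, 250, 250)
#' @export
expandBBox <- function(bbox, percent, imageShape) {
  bbox <- as.integer(round(bbox))
  if (percent < 0) stop("percent must be non-negative")
  if (bbox[3L] <= bbox[1L] || bbox[4L] <= bbox[2L] || any(bbox < 0L))
    stop("invalid bbox")
  if (bbox[3L] > imageShape[1L] || bbox[4L] > imageShape[2L])
    stop("bbox outside image bounds")
  h <- bbox[3L] - bbox[1L]
  w <- bbox[4L] - bbox[2L]
  dr <- as.integer(roundHalfUp(percent / 100 * h))
  dc <- as.integer(roundHalfUp(percent / 100 * w))
  out <- c(max(0L, bbox[1L] - dr), max(0L, bbox[2L] - dc),
           min(as.integer(imageShape[1L]), bbox[3L] + dr),
           min(as.integer(imageShape[2L]), bbox[4L] + dc))
  as.integer(out)
}

#' Scale-based multi-context ROI extraction
#'
#' For each expansion percentage, the mass bounding box is expanded with
#' [expandBBox()], cropped, and anisotropically resized to 224 x 224. ROIs
#' are ordered by ascending scale.
#'
#' @param region a [MassRegion-class].
#' @param scales non-empty numeric vector of expansion percentages (0 means
#'   the tight bounding box). The scheme families used at test time are
#'   `c(5,10,15,20,25)` (MS1), `c(10,20,30,40,50)` (MS2) and
#'   `c(50,60,70,80,100)` (MS3).
#' @return An [ROISet-class] with one ROI per scale.
#' @export
extractMultiscaleROIs <- function(region, scales) {
  if (length(scales) == 0L) stop("scales must be non-empty")
  scales <- sort(unique(as.numeric(scales)))
  img <- region@image
  shp <- dim(img)
  rois <- vector("list", length(scales))
  for (i in seq_along(scales)) {
    eb <- expandBBox(region@bbox, scales[i], shp)
    rois[[i]] <- resizeBilinear(cropBBox(img, eb), .ROI_SIZE, .ROI_SIZE)
  }
  prov <- data.frame(scheme = "scale", index = seq_along(scales),
                     scale_percent = scales, crop_position = NA_character_,
                     flipped = FALSE, stringsAsFactors = FALSE)
  ROISet(rois, prov, regionRef = region@id)
}

#' Isotropically rescale a crop so its smaller side equals a base scale
#'
#' Aspect ratio is preserved; the output's smaller side is exactly `base`
#' pixels and the larger side is scaled by the same factor (rounded half-up).
#'
#' @param crop numeric intensity matrix.
#' @param base target size of the smaller side (default 256).
#' @return Rescaled matrix.
#' @examples
#' dim(isotropicRescaleToBase(matrix(0, 128, 160))) # 256 320
#' @export
isotropicRescaleToBase <- function(crop, base = .BASE_SCALE) {
  stopifnot(nrow(crop) >= 1L, ncol(crop) >= 1L)
  if (min(dim(crop)) == base) return(crop)
  f <- base / min(dim(crop))
  outR <- if (nrow(crop) <= ncol(crop)) base else as.integer(roundHalfUp(nrow(crop) * f))
  outC <- if (ncol(crop) < nrow(crop)) base else as.integer(roundHalfUp(ncol(crop) * f))
  resizeBilinear(crop, outR, outC)
}

# Deterministic 224x224 window offsets (0-based) on a rescaled crop.
.contextOffsets <- function(rows, cols, size = .ROI_SIZE) {
  list(TL = c(0L, 0L),
       TR = c(0L, cols - size),
       BL = c(rows - size, 0L),
       BR = c(rows - size, cols - size),
       C  = c((rows - size) %/% 2L, (cols - size) %/% 2L))
}

#' Translation-based multi-context ROI extraction
#'
#' The bounding-box crop is isotropically rescaled so its smaller side is 256
#' pixels, then 224 x 224 windows are cut from the four corners and the
#' center and each is horizontally flipped. Together with the whole rescaled
#' crop anisotropically resized to 224 x 224 this yields 11 ROIs in the fixed
#' order `full, TL, TR, BL, BR, C, TLf, TRf, BLf, BRf, Cf` (scheme
#' `"MC2"`). Scheme `"MC1"` is the 3-context subset `full, C, Cf`.
#'
#' @param region a [MassRegion-class].
#' @param scheme `"MC2"` (11 ROIs, default) or `"MC1"` (3 ROIs).
#' @return An [ROISet-class].
#' @export
extractMulticontextROIs <- function(region, scheme = c("MC2", "MC1")) {
  scheme <- match.arg(scheme)
  crop <- cropBBox(region@image, region@bbox)
  res <- isotropicRescaleToBase(crop)
  rows <- nrow(res); cols <- ncol(res)
  off <- .contextOffsets(rows, cols)
  win <- function(o) res[(o[1L] + 1L):(o[1L] + .ROI_SIZE),
                         (o[2L] + 1L):(o[2L] + .ROI_SIZE), drop = FALSE]
  full <- resizeBilinear(res, .ROI_SIZE, .ROI_SIZE)
  positions <- if (scheme == "MC2") c("TL", "TR", "BL", "BR", "C") else "C"
  crops <- lapply(off[positions], win)
  rois <- c(list(full), crops, lapply(crops, flipHorizontal))
  prov <- data.frame(
    scheme = "context",
    index = seq_along(rois),
    scale_percent = NA_real_,
    crop_position = c("full", positions, positions),
    flipped = c(FALSE, rep(FALSE, length(positions)), rep(TRUE, length(positions))),
    stringsAsFactors = FALSE)
  ROISet(rois, prov, regionRef = region@id)
}
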