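#' @title Training-set augmentation
#' @description Simulates a large training set from few annotated masses by
#'   three families of transforms: multi-context sliding windows (fixed-size
#'   window sliding with a 10-pixel stride while the whole mass stays
#'   inscribed), multi-orientation variants (clockwise rotations by 0/90/180/
#'   270 degrees, each optionally flipped), and multi-scale bounding-box
#'   expansions (5% and 10% per edge). Orientations are applied to the
#'   sliding-window crops; scale expansions are added as a separate family.
#' @name augmentation
NULL

#' Augmentation plan
#'
#' @param stride sliding-window stride in pixels (default 10).
#' @param angles clockwise rotation angles, multiples of 90 degrees.
#' @param flip logical; also emit horizontally flipped variants.
#' @param scalePercents per-edge bounding-box expansions for the multi-scale
#'   family (default `c(5, 10)`).
#' @param windowMargin extra pixels added to the mass's longer side when
#'   choosing the fixed sliding-window size (default 20).
#' @return A list of class `"AugmentationPlan"`.
#' @export
augmentationPlan <- function(stride = 10L, angles = c(0L, 90L, 180L, 270L),
                             flip = TRUE, scalePercents = c(5, 10),
                             windowMargin = 20L) {
  stopifnot(stride >= 1, all(angles %% 90 == 0))
  structure(list(stride = as.integer(stride), angles = as.integer(angles),
                 flip = flip, scalePercents = scalePercents,
                 windowMargin = as.integer(windowMargin)),
            class = "AugmentationPlan")
}

# Valid 0-based offsets along one axis: window within the image and the bbox
# within the window; multiples of `stride` counted from the interval start.
.slideOffsets <- function(lo, hi, extent, window, imageExtent, stride) {
  rmin <- max(0L, hi - window)
  rmax <- min(lo, imageExtent - window)
  if (rmax < rmin) stop("window cannot simultaneously contain the bbox and fit the image")
  rmin + stride * (0L:((rmax - rmin) %/% stride))
}

#' Multi-context sliding-window crops
#'
#' Slides a fixed-size window in `stride`-pixel steps over all offsets where
#' the window both lies inside the image and fully contains the mass
#' bounding box, and resizes each crop to 224 x 224. The number of crops is
#' `(floor(dr/stride)+1) * (floor(dc/stride)+1)` where `dr`, `dc` are the
#' valid offset ranges per axis.
#'
#' @param region a [MassRegion-class].
#' @param window window side length in pixels, or `NULL` to use the bbox's
#'   longer side plus `plan$windowMargin`.
#' @param plan an [augmentationPlan()].
#' @return An [ROISet-class] of crops (scheme `"window"`).
#' @export
slidingWindowCrops <- function(region, window = NULL, plan = augmentationPlan()) {
  b <- region@bbox
  bh <- b[3L] - b[1L]; bw <- b[4L] - b[2L]
  if (is.null(window)) window <- max(bh, bw) + plan$windowMargin
  window <- as.integer(window)
  img <- region@image
  if (window < bh || window < bw) stop("window smaller than the mass bounding box")
  if (window > nrow(img) || window > ncol(img)) stop("window larger than the image")
  rOff <- .slideOffsets(b[1L], b[3L], bh, window, nrow(img), plan$stride)
  cOff <- .slideOffsets(b[2L], b[4L], bw, window, ncol(img), plan$stride)
  grid <- expand.grid(r = rOff, c = cOff)
  rois <- lapply(seq_len(nrow(grid)), function(i) {
    r <- grid$r[i]; c <- grid$c[i]
    resizeBilinear(img[(r + 1L):(r + window), (c + 1L):(c + window), drop = FALSE],
                   .ROI_SIZE, .ROI_SIZE)
  })
  prov <- data.frame(scheme = "window", index = seq_along(rois),
                     scale_percent = NA_real_,
                     crop_position = sprintf("r%d_c%d", grid$r, grid$c),
                     flipped = FALSE, stringsAsFactors = FALSE)
  ROISet(rois, prov, regionRef = region@id)
}

#' Multi-orientation variants of one ROI
#'
#' Rotates a square ROI clockwise through each angle and optionally pairs
#' each rotation with its horizontal flip. Rotations by multiples of 90
#' degrees are lossless array permutations. Order: all unflipped rotations
#' (ascending angle), then the flipped ones.
#'
#' @param roi square numeric matrix.
#' @param angles clockwise angles in degrees, multiples of 90.
#' @param flip logical; include flipped variants.
#' @return Named list of matrices (e.g. `rot90`, `rot90_flip`).
#' @export
orientationVariants <- function(roi, angles = c(0L, 90L, 180L, 270L), flip = TRUE) {
  stopifnot(nrow(roi) == ncol(roi), all(angles %% 90 == 0))
  rot <- lapply(angles, function(a) rot90cw(roi, a %/% 90L))
  names(rot) <- sprintf("rot%d", angles)
  if (flip) {
    fl <- lapply(rot, flipHorizontal)
    names(fl) <- sprintf("%s_flip", names(rot))
    rot <- c(rot, fl)
  }
  rot
}

#' Build an augmented training set
#'
#' Union of the three augmentation families for every labeled region:
#' orientation variants of each sliding-window crop, plus the multi-scale
#' expanded-bbox ROIs. Output order and count are deterministic for a given
#' plan.
#'
#' @param regions list of labeled [MassRegion-class] objects.
#' @param plan an [augmentationPlan()].
#' @param outDir optional directory; when given, ROIs are written as PNG
#'   files and the manifest's `path` column points at them. Otherwise pixel
#'   data are returned in memory.
#' @return A list with `manifest` (data.frame: `roi_id`, `source_region`,
#'   `label`, `family`, `transform`) and, when `outDir` is `NULL`, `rois`
#'   (list of 224 x 224 matrices aligned with the manifest rows).
#' @export
buildTrainingSet <- function(regions, plan = augmentationPlan(), outDir = NULL) {
  rows <- list(); rois <- list(); k <- 0L
  for (region in regions) {
    if (!region@label %in% .LABELS)
      stop(sprintf("region '%s' has no pathology label", region@id))
    win <- slidingWindowCrops(region, plan = plan)
    wp <- roiProvenance(win)
    for (i in seq_len(nROIs(win))) {
      ov <- orientationVariants(roiList(win)[[i]], plan$angles, plan$flip)
      for (j in seq_along(ov)) {
        k <- k + 1L
        rois[[k]] <- ov[[j]]
        rows[[k]] <- data.frame(
          roi_id = sprintf("%s_w%03d_%s", region@id, i, names(ov)[j]),
          source_region = region@id, label = region@label,
          family = "context-orientation",
          transform = sprintf("%s|%s", wp$crop_position[i], names(ov)[j]),
          stringsAsFactors = FALSE)
      }
    }
    if (length(plan$scalePercents)) {
      ms <- extractMultiscaleROIs(region, plan$scalePercents)
      mp <- roiProvenance(ms)
      for (i in seq_len(nROIs(ms))) {
        k <- k + 1L
        rois[[k]] <- roiList(ms)[[i]]
        rows[[k]] <- data.frame(
          roi_id = sprintf("%s_s%03d", region@id, i),
          source_region = region@id, label = region@label,
          family = "scale",
          transform = sprintf("scale%.0f", mp$scale_percent[i]),
          stringsAsFactors = FALSE)
      }
    }
  }
  manifest <- if (k) do.call(rbind, rows) else
    data.frame(roi_id = character(), source_region = character(),
               label = character(), family = character(),
               transform = character(), stringsAsFactors = FALSE)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    paths <- file.path(outDir, sprintf("%s.png", manifest$roi_id))
    for (i in seq_len(k)) {
      mx <- max(rois[[i]], 1e-9)
      png::writePNG(clampRange(rois[[i]] / max(255, mx), 0, 1), paths[i])
    }
    manifest$path <- paths
    write.csv(manifest, file.path(outDir, "manifest.csv"), row.names = FALSE)
    return(list(manifest = manifest))
  }
  list(manifest = manifest, rois = rois)
}
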