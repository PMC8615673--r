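#' @title Synthetic mammogram-like fixtures
#' @description Generates labeled mass regions on textured grayscale
#'   backgrounds so the whole pipeline (extraction, enhancement, backbone,
#'   fusion, metrics) runs without clinical data. The two classes are made
#'   separable along the visual axes radiologists use: benign masses are
#'   smooth bright ellipses with sharp margins; malignant masses are
#'   star-convex spiculated blobs with blurred margins. Background texture
#'   energy scales with the BI-RADS density tag. No claim of physical
#'   realism is made.
#' @name synthetic-fixtures
NULL

#' Synthetic dataset configuration
#'
#' @param imageSize `c(rows, cols)` of each phantom (default 512 x 512).
#' @param nPerClass regions per class (default 50).
#' @param densityMix proportions over BI-RADS I-IV; must sum to 1.
#' @param noiseSd additive Gaussian noise SD on the `[0, 1]` scale.
#' @param benignAxes range of ellipse semi-axes in pixels.
#' @param malignantRadius range of mean spicule-star radii in pixels.
#' @param spiculeCount range of spicule counts for malignant lesions.
#' @param marginBlurSigma Gaussian sigma blurring malignant margins.
#' @param lesionAmplitude peak lesion brightness above background.
#' @param bitDepth 8 (default) or 16.
#' @param trainFraction stratified train share of [generateDataset()]
#'   (default 0.7).
#' @param seed RNG seed.
#' @return A list of class `"SyntheticConfig"`.
#' @export
syntheticConfig <- function(imageSize = c(512L, 512L), nPerClass = 50L,
                            densityMix = c(0.25, 0.25, 0.25, 0.25),
                            noiseSd = 0.02,
                            benignAxes = c(35, 65),
                            malignantRadius = c(35, 55),
                            spiculeCount = c(8L, 14L),
                            marginBlurSigma = 3,
                            lesionAmplitude = 0.35,
                            bitDepth = 8L, trainFraction = 0.7, seed = 1L) {
  stopifnot(nPerClass >= 1, length(densityMix) == 4,
            abs(sum(densityMix) - 1) < 1e-8, trainFraction > 0,
            trainFraction < 1)
  structure(list(imageSize = as.integer(imageSize),
                 nPerClass = as.integer(nPerClass), densityMix = densityMix,
                 noiseSd = noiseSd, benignAxes = benignAxes,
                 malignantRadius = malignantRadius,
                 spiculeCount = as.integer(spiculeCount),
                 marginBlurSigma = marginBlurSigma,
                 lesionAmplitude = lesionAmplitude,
                 bitDepth = as.integer(bitDepth),
                 trainFraction = trainFraction, seed = as.integer(seed)),
            class = "SyntheticConfig")
}

# Smooth textured background; texture amplitude grows with density I..IV.
.background <- function(rows, cols, densityIdx) {
  tex <- matrix(rnorm(rows * cols), rows, cols)
  tex <- as.matrix(EBImage::gblur(tex, sigma = 6))
  tex <- tex / max(sd(tex), 1e-9)
  base <- 0.28 + 0.04 * densityIdx
  amp <- 0.03 + 0.03 * densityIdx
  base + amp * tex
}

#' Generate one synthetic mass region
#'
#' Uses the current RNG state (seed via `set.seed()` or through
#' [generateDataset()]). The bounding box is the tight box of the lesion's
#' support mask.
#'
#' @param cls `"benign"` or `"malignant"`.
#' @param density BI-RADS density `"I".."IV"`.
#' @param config a [syntheticConfig()].
#' @param id identifier for the region.
#' @return A [MassRegion-class].
#' @export
generateRegion <- function(cls = c("benign", "malignant"),
                           density = c("I", "II", "III", "IV"),
                           config = syntheticConfig(), id = "synthetic") {
  cls <- match.arg(cls)
  density <- match.arg(density)
  d <- match(density, .DENSITIES)
  rows <- config$imageSize[1L]; cols <- config$imageSize[2L]
  bg <- .background(rows, cols, d)

  cy <- runif(1, 0.35, 0.65) * rows
  cx <- runif(1, 0.35, 0.65) * cols
  yy <- matrix(seq_len(rows) - cy, rows, cols)
  xx <- matrix(seq_len(cols) - cx, rows, cols, byrow = TRUE)

  if (cls == "benign") {
    ax <- runif(1, config$benignAxes[1L], config$benignAxes[2L])
    bxs <- runif(1, config$benignAxes[1L], config$benignAxes[2L])
    phi <- runif(1, 0, pi)
    u <- cos(phi) * xx + sin(phi) * yy
    v <- -sin(phi) * xx + cos(phi) * yy
    dist <- sqrt((u / ax)^2 + (v / bxs)^2)  # 1 at the margin
    edge <- 2 / min(ax, bxs)                # ~2 px sharp margin
    profile <- clampRange((1 - dist) / edge, 0, 1)
    support <- dist <= 1
  } else {
    r0 <- runif(1, config$malignantRadius[1L], config$malignantRadius[2L])
    k <- sample(config$spiculeCount[1L]:config$spiculeCount[2L], 1L)
    phase <- runif(1, 0, 2 * pi)
    irr <- runif(3, -0.06, 0.06)
    theta <- atan2(yy, xx)
    radius <- r0 * (1 + 0.35 * abs(cos(k * theta / 2 + phase))^3 +
                    irr[1] * cos(theta) + irr[2] * sin(2 * theta) +
                    irr[3] * cos(3 * theta))
    rr <- sqrt(xx^2 + yy^2)
    core <- (rr <= radius) * clampRange((radius - rr) / (0.35 * r0), 0, 1)
    profile <- as.matrix(EBImage::gblur(core, sigma = config$marginBlurSigma))
    support <- profile > 0.02
  }

  img <- bg + config$lesionAmplitude * profile +
    config$noiseSd * matrix(rnorm(rows * cols), rows, cols)
  img <- clampRange(img, 0, 1)
  mx <- 2^config$bitDepth - 1
  img <- roundHalfUp(img * mx)

  ri <- range(which(rowSums(support) > 0L))
  ci <- range(which(colSums(support) > 0L))
  bbox <- c(ri[1L] - 1L, ci[1L] - 1L, ri[2L], ci[2L])
  MassRegion(img, bbox, label = cls, density = density,
             bitDepth = config$bitDepth, id = id)
}

#' Generate a labeled synthetic dataset with a stratified split
#'
#' @param config a [syntheticConfig()]; `config$seed` fixes the RNG, so the
#'   same config reproduces the same dataset bit for bit.
#' @return A list with `regions` (list of [MassRegion-class]) and `manifest`
#'   (data.frame: `id`, `label`, `density`, `split`), rows aligned.
#' @export
generateDataset <- function(config = syntheticConfig()) {
  set.seed(config$seed)
  n <- config$nPerClass
  labels <- rep(.LABELS, each = n)
  densities <- sample(.DENSITIES, 2L * n, replace = TRUE,
                      prob = config$densityMix)
  ids <- sprintf("syn_%s_%03d", labels, rep(seq_len(n), 2L))
  regions <- vector("list", 2L * n)
  for (i in seq_along(regions))
    regions[[i]] <- generateRegion(labels[i], densities[i], config, ids[i])
  split <- rep("test", 2L * n)
  for (lb in .LABELS) {
    ix <- which(labels == lb)
    ntr <- round(length(ix) * config$trainFraction)
    split[ix[seq_len(ntr)]] <- "train"
  }
  manifest <- data.frame(id = ids, label = labels, density = densities,
                         split = split, stringsAsFactors = FALSE)
  list(regions = regions, manifest = manifest)
}

#' Write a synthetic dataset as image files plus a CSV manifest
#'
#' Produces the same manifest schema the pipeline reader consumes
#' (`image_path`, bbox columns, `label`, `density`, `id`, `split`). PNG
#' output is 8-bit; TIFF output preserves 16-bit intensities.
#'
#' @param dataset result of [generateDataset()].
#' @param dir output directory.
#' @param format `"png"` (default) or `"tiff"`.
#' @return Path of the written manifest CSV, invisibly.
#' @export
writeDataset <- function(dataset, dir, format = c("png", "tiff")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_along(dataset$regions), function(i) {
    rg <- dataset$regions[[i]]
    mx <- 2^rg@bitDepth - 1
    path <- file.path(dir, sprintf("%s.%s", rg@id, format))
    if (format == "png") {
      png::writePNG(rg@image / mx, path)
    } else {
      tiff::writeTIFF(rg@image / mx, path, bits.per.sample = 16L)
    }
    data.frame(image_path = path,
               row_min = rg@bbox[1L], col_min = rg@bbox[2L],
               row_max = rg@bbox[3L], col_max = rg@bbox[4L],
               label = rg@label, density = rg@density, id = rg@id,
               split = dataset$manifest$split[i], stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  out <- file.path(dir, "manifest.csv")
  write.csv(manifest, out, row.names = FALSE)
  invisible(out)
}

# Three-feature lesion summary used to audit class separability:
# margin sharpness (mean gradient magnitude on the lesion boundary),
# eccentricity of the thresholded support, and boundary complexity
# (perimeter^2 / (4*pi*area), a spiculation surrogate).
.regionFeatures <- function(region) {
  crop <- cropBBox(region@image, region@bbox) / (2^region@bitDepth - 1)
  sm <- as.matrix(EBImage::gblur(crop, sigma = 2))
  mask <- sm > EBImage::otsu(sm, range = range(sm))
  lb <- EBImage::bwlabel(mask)
  mask <- lb == which.max(tabulate(lb[lb > 0]))     # largest component
  mask <- as.matrix(EBImage::fillHull(mask)) > 0
  er <- as.matrix(EBImage::erode(mask, EBImage::makeBrush(3, "box"))) > 0
  boundary <- mask & !er
  gy <- rbind(diff(sm), 0)
  gx <- cbind(t(apply(sm, 1L, diff)), 0)
  grad <- sqrt(gx^2 + gy^2)
  f1 <- mean(grad[boundary])
  ij <- which(mask, arr.ind = TRUE)
  ij <- sweep(ij, 2L, colMeans(ij))
  ev <- eigen(crossprod(ij) / nrow(ij), symmetric = TRUE)$values
  f2 <- sqrt(max(0, 1 - ev[2L] / max(ev[1L], 1e-9)))
  f3 <- sum(boundary)^2 / (4 * pi * sum(mask))
  c(marginGradient = f1, eccentricity = f2, spiculeEnergy = f3)
}
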