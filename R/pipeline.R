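#' @title End-to-end pipeline
#' @description Orchestrates the full flow: read a manifest of annotated
#'   mass regions, extract context-diverse ROIs per the configured scheme,
#'   optionally enhance them, fine-tune the backbone on the training
#'   regions (90:10 train/validation split), fit the stacking
#'   meta-classifier on backbone predictions over training and validation
#'   regions, and evaluate fused decisions on held-out regions.
#' @name pipeline
NULL

.SCHEMES <- c("single", "MS1", "MS2", "MS3", "MC1", "MC2")
.FUSIONS <- c("none", "majority", "soft", "max",
              "stack-rbf", "stack-linear", "stack-poly", "stack-rf")
.MS_SETS <- list(MS1 = c(5, 10, 15, 20, 25),
                 MS2 = c(10, 20, 30, 40, 50),
                 MS3 = c(50, 60, 70, 80, 100))

#' Run configuration
#'
#' @param scheme ROI extraction scheme: `"single"` (tight bbox), `"MS1"`,
#'   `"MS2"`, `"MS3"` (multi-scale expansions), `"MC1"`, `"MC2"`
#'   (translation-based multi-context).
#' @param variant backbone variant (see [buildBackbone()]).
#' @param fusion fusion rule; `"none"` uses the single ROI's argmax and is
#'   the only rule valid with `scheme = "single"`.
#' @param enhancement an [enhancementConfig()] (disabled by default, the
#'   digital-mammogram setting).
#' @param train a [trainConfig()].
#' @param densityFilter optional BI-RADS classes to keep (e.g. `"I"`).
#' @param seed seed for region-level splits.
#' @return A list of class `"RunConfig"`.
#' @export
runConfig <- function(scheme = "MC2", variant = "tiny", fusion = "stack-rbf",
                      enhancement = enhancementConfig(enabled = FALSE),
                      train = trainConfig(), densityFilter = NULL,
                      seed = 1L) {
  scheme <- match.arg(scheme, .SCHEMES)
  fusion <- match.arg(fusion, .FUSIONS)
  if (scheme == "single" && fusion != "none")
    stop("fusion requires more than one ROI; use fusion = 'none' with scheme 'single'")
  if (scheme != "single" && fusion == "none")
    stop("multi-ROI schemes need a fusion rule")
  structure(list(scheme = scheme, variant = variant, fusion = fusion,
                 enhancement = enhancement, train = train,
                 densityFilter = densityFilter, seed = as.integer(seed)),
            class = "RunConfig")
}

# Backbone prediction with stub support: evaluation accepts a plain
# function(roiset, pixelMax) in place of a BackboneModel, so plumbing can be
# audited with oracle predictors.
.backbonePredict <- function(backbone, rs, pixelMax) {
  if (is.function(backbone)) backbone(rs, pixelMax)
  else predictProba(backbone, rs, pixelMax)
}

# Scheme-dispatch ROI extraction (+ optional enhancement).
extractSchemeROIs <- function(region, scheme, enhancement = NULL) {
  rs <- switch(scheme,
    single = extractMultiscaleROIs(region, 0),
    MS1 = , MS2 = , MS3 = extractMultiscaleROIs(region, .MS_SETS[[scheme]]),
    MC1 = extractMulticontextROIs(region, "MC1"),
    MC2 = extractMulticontextROIs(region, "MC2"),
    stop(sprintf("unknown scheme '%s'", scheme)))
  if (!is.null(enhancement) && enhancement$enabled)
    rs@rois <- lapply(rs@rois, enhanceROI, config = enhancement)
  rs
}

#' Read a CSV manifest of annotated mass regions
#'
#' Required columns: `image_path`, `row_min`, `col_min`, `row_max`,
#' `col_max`, `label`; optional: `density`, `id`, `split`. Bounding boxes
#' are 0-based half-open. PNG and TIFF images are supported; each failure
#' mode (missing column, unreadable image, invalid box) raises a distinct
#' error naming the offending row.
#'
#' @param path CSV file path.
#' @return List of [MassRegion-class] objects; the manifest's `split`
#'   column, when present, is carried in an attribute `"split"`.
#' @export
readManifest <- function(path) {
  if (!file.exists(path)) stop(sprintf("manifest not found: %s", path))
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("image_path", "row_min", "col_min", "row_max", "col_max", "label")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("manifest missing required columns: %s",
                 paste(miss, collapse = ", ")))
  regions <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    p <- df$image_path[i]
    ext <- tolower(tools::file_ext(p))
    if (!file.exists(p))
      stop(sprintf("row %d: image not readable: %s", i, p))
    img <- switch(ext,
      png = {
        a <- png::readPNG(p)
        if (length(dim(a)) == 3L) a <- a[, , 1L]
        list(pix = roundHalfUp(a * 255), depth = 8L)
      },
      tif = , tiff = {
        a <- tiff::readTIFF(p)
        if (length(dim(a)) == 3L) a <- a[, , 1L]
        list(pix = roundHalfUp(a * 65535), depth = 16L)
      },
      dcm = stop(sprintf("row %d: DICOM input is not supported; convert to PNG or 16-bit TIFF", i)),
      stop(sprintf("row %d: unsupported image format '%s'", i, ext)))
    bbox <- c(df$row_min[i], df$col_min[i], df$row_max[i], df$col_max[i])
    if (bbox[3L] <= bbox[1L] || bbox[4L] <= bbox[2L] || any(bbox < 0) ||
        bbox[3L] > nrow(img$pix) || bbox[4L] > ncol(img$pix))
      stop(sprintf("row %d: invalid bounding box [%s]", i,
                   paste(bbox, collapse = ", ")))
    regions[[i]] <- MassRegion(
      img$pix, bbox, label = df$label[i],
      density = if ("density" %in% names(df)) df$density[i] else "unknown",
      bitDepth = img$depth,
      id = if ("id" %in% names(df)) df$id[i] else sprintf("region_%04d", i))
  }
  if ("split" %in% names(df)) attr(regions, "split") <- df$split
  regions
}

.filterDensity <- function(regions, filter) {
  if (is.null(filter)) return(regions)
  keep <- vapply(regions, function(r) r@density %in% filter, logical(1))
  if (!any(keep)) stop("density filter removed every region")
  regions[keep]
}

#' Train the full system on labeled regions
#'
#' Splits regions 90:10 (stratified by label), extracts scheme ROIs,
#' fine-tunes the backbone on the training regions' ROIs, and -- for
#' stacking rules -- fits the meta-classifier on backbone predictions over
#' the training plus validation regions (the held-out test set is never
#' touched).
#'
#' @param regions list of labeled [MassRegion-class] objects (e.g. from
#'   [readManifest()] or [generateDataset()]).
#' @param config a [runConfig()].
#' @return A model bundle (list of class `"massContextBundle"`): `backbone`,
#'   `stacker` (or `NULL`), `config`, and the per-ROI probability matrices
#'   used to fit the stacker.
#' @export
runTrain <- function(regions, config = runConfig()) {
  regions <- .filterDensity(regions, config$densityFilter)
  labels <- vapply(regions, regionLabel, character(1))
  if (any(!labels %in% .LABELS)) stop("all training regions must be labeled")
  roisets <- lapply(regions, extractSchemeROIs, scheme = config$scheme,
                    enhancement = config$enhancement)
  set.seed(config$seed)
  y <- .labelIndex(labels)
  val <- unlist(lapply(split(seq_along(y), y), function(ix)
    sample(ix, max(1L, round(length(ix) * config$train$validationFraction)))),
    use.names = FALSE)
  tr <- setdiff(seq_along(y), val)

  pool <- unlist(lapply(roisets[tr], roiList), recursive = FALSE)
  poolLab <- rep(labels[tr], vapply(roisets[tr], nROIs, integer(1)))
  pixelMax <- 2^regions[[1L]]@bitDepth - 1
  cfgTrain <- config$train
  cfgTrain$pixelMax <- pixelMax
  backbone <- buildBackbone(config$variant)
  backbone <- fineTune(backbone, pool, poolLab, cfgTrain)

  probs <- lapply(roisets, function(rs) predictProba(backbone, rs, pixelMax))
  stacker <- NULL
  if (startsWith(config$fusion, "stack")) {
    kind <- c(`stack-rbf` = "svm_rbf", `stack-linear` = "svm_linear",
              `stack-poly` = "svm_poly", `stack-rf` = "random_forest")[[config$fusion]]
    vecs <- do.call(rbind, lapply(probs, stackVector))
    stacker <- fitStacker(vecs, labels, kind, seed = config$seed)
  }
  structure(list(backbone = backbone, stacker = stacker, config = config,
                 pixelMax = pixelMax, trainIndex = tr, valIndex = val,
                 trainProbs = probs, trainIds = vapply(regions, regionId,
                                                       character(1))),
            class = "massContextBundle")
}

#' Evaluate a trained bundle on held-out regions
#'
#' Extracts the bundle's scheme ROIs for every region, computes per-ROI
#' probabilities, fuses them with the configured rule, and reports the
#' screening metrics. The region-level malignancy score used for the ROC is
#' the mean per-ROI malignant probability.
#'
#' @param bundle result of [runTrain()].
#' @param regions list of labeled [MassRegion-class] objects.
#' @return List with `report` (a [MetricsReport-class]), `predictions`
#'   (data.frame: `id`, `truth`, `predicted`, `score`), and `roiProbs`
#'   (per-region probability matrices, for offline fusion audits).
#' @export
runEval <- function(bundle, regions) {
  config <- bundle$config
  regions <- .filterDensity(regions, config$densityFilter)
  truth <- vapply(regions, regionLabel, character(1))
  if (any(!truth %in% .LABELS)) stop("all evaluation regions must be labeled")
  roisets <- lapply(regions, extractSchemeROIs, scheme = config$scheme,
                    enhancement = config$enhancement)
  probs <- lapply(roisets, function(rs)
    .backbonePredict(bundle$backbone, rs, bundle$pixelMax))
  predicted <- vapply(probs, function(p) {
    if (config$fusion == "none") .LABELS[which.max(p[1L, ])]
    else fuseDecision(p, config$fusion, bundle$stacker)
  }, character(1))
  score <- vapply(probs, function(p) mean(p[, 2L]), numeric(1))
  cm <- confusionFromLabels(predicted, truth)
  auc <- if (length(unique(truth)) == 2L) rocAuc(score, truth) else NA_real_
  report <- computeMetrics(cm, auc = auc)
  list(report = report,
       predictions = data.frame(id = vapply(regions, regionId, character(1)),
                                truth = truth, predicted = predicted,
                                score = score, stringsAsFactors = FALSE),
       roiProbs = probs)
}
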