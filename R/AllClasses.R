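#' @title Core S4 classes
#' @name massContext-classes
#' @description S4 containers used throughout the package: annotated mass
#'   regions, extracted ROI sets, backbone architecture specifications,
#'   trained models, and evaluation containers.
NULL

.LABELS <- c("benign", "malignant")
.DENSITIES <- c("I", "II", "III", "IV")

#' MassRegion: a grayscale mammogram region with mass annotation
#'
#' Carries the image pixels, the mass bounding box (0-based, half-open
#' `[rowMin, rowMax) x [colMin, colMax)`), the pathology label and the
#' BI-RADS density class. Label and density may be `"unknown"` at inference.
#'
#' @slot image numeric matrix of intensities in `[0, 2^bitDepth - 1]`.
#' @slot bitDepth integer, 8 or 16.
#' @slot bbox integer vector `c(rowMin, colMin, rowMax, colMax)`.
#' @slot label character, one of `"benign"`, `"malignant"`, `"unknown"`.
#' @slot density character, one of `"I".."IV"`, `"unknown"`.
#' @slot id character identifier.
#' @exportClass MassRegion
setClass("MassRegion",
  representation(image = "matrix", bitDepth = "integer", bbox = "integer",
                 label = "character", density = "character", id = "character"))

setValidity("MassRegion", function(object) {
  msg <- character()
  img <- object@image
  if (nrow(img) < 1L || ncol(img) < 1L) msg <- c(msg, "image must be non-empty")
  if (!object@bitDepth %in% c(8L, 16L)) msg <- c(msg, "bitDepth must be 8 or 16")
  mx <- 2^object@bitDepth - 1
  if (any(img < 0 | img > mx)) msg <- c(msg, "intensities outside bit-depth range")
  b <- object@bbox
  if (length(b) != 4L) msg <- c(msg, "bbox must have 4 entries")
  else {
    if (b[3L] <= b[1L] || b[4L] <= b[2L]) msg <- c(msg, "bbox must have positive extent")
    if (any(b < 0L)) msg <- c(msg, "bbox indices must be >= 0")
    if (b[3L] > nrow(img) || b[4L] > ncol(img)) msg <- c(msg, "bbox outside image bounds")
  }
  if (!object@label %in% c(.LABELS, "unknown")) msg <- c(msg, "invalid label")
  if (!object@density %in% c(.DENSITIES, "unknown")) msg <- c(msg, "invalid density")
  if (length(msg)) msg else TRUE
})

#' Construct a MassRegion
#'
#' @param image numeric matrix of pixel intensities (rows x cols).
#' @param bbox numeric/integer vector `c(rowMin, colMin, rowMax, colMax)`,
#'   0-based half-open.
#' @param label `"benign"`, `"malignant"` or `"unknown"`.
#' @param density BI-RADS density `"I".."IV"` or `"unknown"`.
#' @param bitDepth 8 (default) or 16.
#' @param id identifier string.
#' @return A [MassRegion-class] object.
#' @examples
#' img <- matrix(runif(64 * 64, 0, 255), 64, 64)
#' MassRegion(img, c(10, 10, 40, 40), label = "benign")
#' @export
MassRegion <- function(image, bbox, label = "unknown", density = "unknown",
                       bitDepth = 8L, id = "region") {
  new("MassRegion", image = image, bitDepth = as.integer(bitDepth),
      bbox = as.integer(round(bbox)), label = label, density = density,
      id = as.character(id))
}

#' ROISet: an ordered set of fixed-size ROIs extracted from one mass region
#'
#' Ordering is deterministic and part of the contract: stacked-generalization
#' feature vectors index ROIs by position.
#'
#' @slot rois list of square numeric matrices, all `roiSize x roiSize`.
#' @slot provenance data.frame with columns `scheme`, `index`,
#'   `scale_percent`, `crop_position`, `flipped`.
#' @slot regionRef character id of the source [MassRegion-class].
#' @slot roiSize integer side length (224).
#' @exportClass ROISet
setClass("ROISet",
  representation(rois = "list", provenance = "data.frame",
                 regionRef = "character", roiSize = "integer"))

setValidity("ROISet", function(object) {
  msg <- character()
  if (length(object@rois) == 0L) msg <- c(msg, "ROISet must be non-empty")
  ok <- vapply(object@rois, function(r)
    is.matrix(r) && all(dim(r) == object@roiSize), logical(1))
  if (!all(ok)) msg <- c(msg, sprintf("all ROIs must be %dx%d", object@roiSize, object@roiSize))
  if (nrow(object@provenance) != length(object@rois))
    msg <- c(msg, "provenance rows must match number of ROIs")
  need <- c("scheme", "index", "scale_percent", "crop_position", "flipped")
  if (!all(need %in% names(object@provenance)))
    msg <- c(msg, "provenance missing required columns")
  if (length(msg)) msg else TRUE
})

ROISet <- function(rois, provenance, regionRef = "region", roiSize = 224L) {
  new("ROISet", rois = rois, provenance = provenance,
      regionRef = regionRef, roiSize = as.integer(roiSize))
}

#' ArchSpec: declarative description of a backbone computational graph
#'
#' @slot variant character, one of `"base"`, `"DI"`, `"DII"`, `"DIII"`,
#'   `"DIV"`, `"tiny"`.
#' @slot nodes list of layer descriptors (id, op, inputs, geometry).
#' @slot featureWidth integer channels entering the final classifier.
#' @slot numClasses integer, 2.
#' @exportClass ArchSpec
setClass("ArchSpec",
  representation(variant = "character", nodes = "list",
                 featureWidth = "integer", numClasses = "integer"))

#' BackboneModel: an ArchSpec plus concrete weights
#'
#' @slot spec [ArchSpec-class].
#' @slot weights named list of per-node parameter arrays.
#' @slot inputChannels integer (3 for ImageNet-shaped variants, 1 for tiny).
#' @slot trained logical.
#' @slot log data.frame of per-epoch training/validation losses.
#' @exportClass BackboneModel
setClass("BackboneModel",
  representation(spec = "ArchSpec", weights = "list",
                 inputChannels = "integer", trained = "logical",
                 log = "data.frame"))

#' StackerModel: meta-classifier over per-ROI malignancy probabilities
#'
#' @slot kind `"svm_rbf"`, `"svm_linear"`, `"svm_poly"` or `"random_forest"`.
#' @slot model fitted e1071/randomForest object.
#' @slot center,scale numeric standardization parameters (length = nFeatures).
#' @slot nFeatures integer stack-vector length.
#' @exportClass StackerModel
setClass("StackerModel",
  representation(kind = "character", model = "ANY", center = "numeric",
                 scale = "numeric", nFeatures = "integer"))

#' ConfusionMatrix: binary confusion counts (positive class = malignant)
#'
#' @slot TP,FN,TN,FP non-negative integer counts.
#' @exportClass ConfusionMatrix
setClass("ConfusionMatrix",
  representation(TP = "integer", FN = "integer", TN = "integer", FP = "integer"))

setValidity("ConfusionMatrix", function(object) {
  v <- c(object@TP, object@FN, object@TN, object@FP)
  if (any(v < 0L)) "counts must be non-negative" else TRUE
})

#' Construct a ConfusionMatrix
#'
#' @param TP,FN,TN,FP counts; positive class is malignant.
#' @return A [ConfusionMatrix-class].
#' @examples
#' confusionCounts(131, 1, 159, 23)
#' @export
confusionCounts <- function(TP, FN, TN, FP) {
  new("ConfusionMatrix", TP = as.integer(TP), FN = as.integer(FN),
      TN = as.integer(TN), FP = as.integer(FP))
}

#' MetricsReport: screening metrics derived from a confusion matrix
#'
#' Percentages are on the 0-100 scale; `auc`, `po`, `pe` are fractions.
#' Metrics with zero denominators are `NA` (undefined, not 0).
#'
#' @slot sensitivity,specificity,accuracy,kappa,f1 numeric percentages.
#' @slot auc numeric fraction in `[0, 1]` (or `NA`).
#' @slot po,pe numeric observed/expected agreement fractions.
#' @slot cm [ConfusionMatrix-class] the report derives from.
#' @exportClass MetricsReport
setClass("MetricsReport",
  representation(sensitivity = "numeric", specificity = "numeric",
                 accuracy = "numeric", kappa = "numeric", f1 = "numeric",
                 auc = "numeric", po = "numeric", pe = "numeric",
                 cm = "ConfusionMatrix"))

setMethod("show", "MassRegion", function(object) {
  cat(sprintf("MassRegion '%s': %d x %d (%d-bit), bbox [%d,%d) x [%d,%d), label=%s, density=%s\n",
              object@id, nrow(object@image), ncol(object@image), object@bitDepth,
              object@bbox[1], object@bbox[3], object@bbox[2], object@bbox[4],
              object@label, object@density))
})

setMethod("show", "ROISet", function(object) {
  cat(sprintf("ROISet of %d ROIs (%dx%d) from '%s' [%s]\n",
              length(object@rois), object@roiSize, object@roiSize,
              object@regionRef, paste(unique(object@provenance$scheme), collapse = ",")))
})

setMethod("show", "ArchSpec", function(object) {
  cat(sprintf("ArchSpec '%s': %d nodes, feature width %d, %d-way classifier\n",
              object@variant, length(object@nodes), object@featureWidth,
              object@numClasses))
})

setMethod("show", "BackboneModel", function(object) {
  cat(sprintf("BackboneModel '%s' (%s, %d input channel%s), %s parameters\n",
              object@spec@variant, if (object@trained) "trained" else "untrained",
              object@inputChannels, if (object@inputChannels > 1) "s" else "",
              format(paramCount(object), big.mark = ",")))
})

setMethod("show", "StackerModel", function(object) {
  cat(sprintf("StackerModel '%s' on %d-length stack vectors\n",
              object@kind, object@nFeatures))
})

setMethod("show", "ConfusionMatrix", function(object) {
  cat(sprintf("ConfusionMatrix (positive = malignant): TP=%d FN=%d TN=%d FP=%d\n",
              object@TP, object@FN, object@TN, object@FP))
})

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf(
    "MetricsReport: Sen %.2f%%  Spe %.2f%%  Acc %.2f%%  Kappa %.2f  F1 %.2f%s\n",
    object@sensitivity, object@specificity, object@accuracy, object@kappa,
    object@f1, if (is.na(object@auc)) "" else sprintf("  AUC %.4f", object@auc)))
})

# ---- accessors -------------------------------------------------------------

#' Accessors for core classes
#'
#' @param object a package S4 object.
#' @return The requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
regionImage <- function(object) object@image

#' @rdname accessors
#' @export
regionBBox <- function(object) object@bbox

#' @rdname accessors
#' @export
regionLabel <- function(object) object@label

#' @rdname accessors
#' @export
regionDensity <- function(object) object@density

#' @rdname accessors
#' @export
regionId <- function(object) object@id

#' @rdname accessors
#' @export
roiList <- function(object) object@rois

#' @rdname accessors
#' @export
roiProvenance <- function(object) object@provenance

#' @rdname accessors
#' @export
nROIs <- function(object) length(object@rois)

#' @rdname accessors
#' @export
archSpec <- function(object) object@spec

#' @rdname accessors
#' @export
trainingLog <- function(object) object@log

#' @rdname accessors
#' @export
featureWidth <- function(object) {
  if (is(object, "BackboneModel")) object <- object@spec
  object@featureWidth
}
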