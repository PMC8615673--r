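#' @title Backbone architectures
#' @description Builds the ResNet-50 backbone and its four breast-density-
#'   specific modifications as declarative graph specifications with channel
#'   contracts. Every density variant alters the last bottleneck block of the
#'   final (7 x 7) stage and fuses global average pooling (GAP), global max
#'   pooling (GMP) and/or a 1 x 1-convolution projection shortcut so that the
#'   concatenated feature entering the 2-way classifier is exactly 2048
#'   channels wide -- the width of the unmodified network. A `"tiny"`
#'   reduced-depth backbone with a GAP||GMP head is provided for desk-scale
#'   experiments and tests.
#' @name backbone-zoo
NULL

.VARIANTS <- c("base", "DI", "DII", "DIII", "DIV", "tiny")

# -- tiny node-list builder --------------------------------------------------
.gr <- function() new.env(parent = emptyenv())
.addNode <- function(g, id, op, inputs = character(), ...) {
  nd <- c(list(id = id, op = op, inputs = inputs), list(...))
  g$nodes <- c(g$nodes %||% list(), list(nd))
  id
}
.conv <- function(g, id, from, f, k, stride = 1L, pad = (k - 1L) %/% 2L)
  .addNode(g, id, "conv", from, kh = as.integer(k), kw = as.integer(k),
           stride = as.integer(stride), pad = as.integer(pad),
           filters = as.integer(f))

# conv + frozen batch-norm (+ optional relu); returns id of last node
.convBN <- function(g, id, from, f, k, stride = 1L, relu = TRUE) {
  c1 <- .conv(g, paste0(id, "_conv"), from, f, k, stride)
  b1 <- .addNode(g, paste0(id, "_bn"), "bn", c1)
  if (relu) .addNode(g, paste0(id, "_relu"), "relu", b1) else b1
}

# Standard bottleneck residual block: 1x1 (stride) -> 3x3 -> 1x1, with
# identity or 1x1-projection shortcut and a block-level ReLU after the add.
# `surgery` controls the density-specific modifications of the final block:
#   NULL         : standard block
#   list(drop3)  : third conv block, its ReLU and the shortcut removed
#   list(f3)     : third conv replaced by f3 filters, shortcut removed
.bottleneck <- function(g, id, from, mid, out, stride = 1L, project = FALSE,
                        surgery = NULL) {
  a <- .convBN(g, paste0(id, "_1"), from, mid, 1L, stride)
  b <- .convBN(g, paste0(id, "_2"), a, mid, 3L)
  if (!is.null(surgery) && isTRUE(surgery$drop3)) return(b)
  f3 <- if (is.null(surgery)) out else surgery$f3
  if (!is.null(surgery)) {
    cB <- .convBN(g, paste0(id, "_3"), b, f3, 1L, relu = isTRUE(surgery$relu))
    return(cB)
  }
  cB <- .convBN(g, paste0(id, "_3"), b, out, 1L, relu = FALSE)
  sc <- if (project)
    .convBN(g, paste0(id, "_proj"), from, out, 1L, stride, relu = FALSE)
  else from
  ad <- .addNode(g, paste0(id, "_add"), "add", c(cB, sc))
  .addNode(g, paste0(id, "_relu"), "relu", ad)
}

# Stem + stages G2..G5 of ResNet-50; `lastSurgery` applies to the final block
# of G5. Returns list(g, out, g4out, g5b1out) for variant heads.
.resnetTrunk <- function(lastSurgery = NULL) {
  g <- .gr()
  inp <- .addNode(g, "input", "input")
  x <- .convBN(g, "G1", inp, 64L, 7L, 2L)
  x <- .addNode(g, "G1_pool", "maxpool", x, kh = 3L, kw = 3L,
                stride = 2L, pad = 1L)
  blocks <- c(3L, 4L, 6L, 3L)
  mids <- c(64L, 128L, 256L, 512L)
  g4out <- g5b1out <- NULL
  for (s in 1:4) {
    out <- mids[s] * 4L
    for (r in seq_len(blocks[s])) {
      stride <- if (s > 1L && r == 1L) 2L else 1L
      surgery <- if (s == 4L && r == blocks[s]) lastSurgery else NULL
      x <- .bottleneck(g, sprintf("G%d_%d", s + 1L, r), x, mids[s], out,
                       stride, project = (r == 1L), surgery = surgery)
      if (s == 3L && r == blocks[s]) g4out <- x
      if (s == 4L && r == 1L) g5b1out <- x
    }
  }
  list(g = g, out = x, g4out = g4out, g5b1out = g5b1out)
}

.finishSpec <- function(g, feature, variant, fcIn) {
  .addNode(g, "fc", "fc", feature, units = 2L)
  .addNode(g, "softmax", "softmax", "fc")
  spec <- new("ArchSpec", variant = variant, nodes = g$nodes,
              featureWidth = as.integer(fcIn), numClasses = 2L)
  spec
}

# Projection shortcut used by the density variants: 1x1 conv block followed
# by a max-pool over the whole stated spatial grid (output one value per
# channel, i.e. a global max pool of the projected map).
.projShortcut <- function(g, id, from, filters) {
  p <- .convBN(g, id, from, filters, 1L, relu = FALSE)
  .addNode(g, paste0(id, "_pool"), "gmp", p)
}

.buildArchSpec <- function(variant) {
  switch(variant,
    base = {
      tr <- .resnetTrunk()
      feat <- .addNode(tr$g, "gap", "gap", tr$out)
      .finishSpec(tr$g, feat, "base", 2048L)
    },
    DI = {
      # Final bottleneck loses its 2048-filter 1x1 conv, block ReLU and
      # shortcut (512-channel output); GAP || GMP over that map, plus a
      # projection shortcut (1x1 conv, 1024 filters, 7x7 max-pool) from the
      # first G5 block's ReLU: 512 + 512 + 1024 = 2048.
      tr <- .resnetTrunk(lastSurgery = list(drop3 = TRUE))
      gapN <- .addNode(tr$g, "gap", "gap", tr$out)
      gmpN <- .addNode(tr$g, "gmp", "gmp", tr$out)
      prj <- .projShortcut(tr$g, "projsc", tr$g5b1out, 1024L)
      feat <- .addNode(tr$g, "concat", "concat", c(gapN, gmpN, prj))
      .finishSpec(tr$g, feat, "DI", 2048L)
    },
    DII = {
      # Final 1x1 conv replaced by 1024 filters, shortcut removed; GAP in
      # parallel with a projection block (1x1 conv 1024 + 7x7 max-pool):
      # 1024 + 1024 = 2048.
      tr <- .resnetTrunk(lastSurgery = list(f3 = 1024L, relu = TRUE))
      gapN <- .addNode(tr$g, "gap", "gap", tr$out)
      prj <- .projShortcut(tr$g, "projsc", tr$out, 1024L)
      feat <- .addNode(tr$g, "concat", "concat", c(gapN, prj))
      .finishSpec(tr$g, feat, "DII", 2048L)
    },
    DIII = {
      # Final 1x1 conv replaced by 512 filters, shortcut removed; GAP || GMP
      # (512 + 512) plus a projection shortcut from the last G4 block's ReLU
      # (14 x 14 map) through 1x1 conv 1024 + 14x14 max-pool: total 2048.
      tr <- .resnetTrunk(lastSurgery = list(f3 = 512L, relu = TRUE))
      gapN <- .addNode(tr$g, "gap", "gap", tr$out)
      gmpN <- .addNode(tr$g, "gmp", "gmp", tr$out)
      prj <- .projShortcut(tr$g, "projsc", tr$g4out, 1024L)
      feat <- .addNode(tr$g, "concat", "concat", c(gapN, gmpN, prj))
      .finishSpec(tr$g, feat, "DIII", 2048L)
    },
    DIV = {
      # Final 1x1 conv replaced by 1024 filters, shortcut removed; GAP || GMP
      # after the block ReLU: 1024 + 1024 = 2048.
      tr <- .resnetTrunk(lastSurgery = list(f3 = 1024L, relu = TRUE))
      gapN <- .addNode(tr$g, "gap", "gap", tr$out)
      gmpN <- .addNode(tr$g, "gmp", "gmp", tr$out)
      feat <- .addNode(tr$g, "concat", "concat", c(gapN, gmpN))
      .finishSpec(tr$g, feat, "DIV", 2048L)
    },
    tiny = {
      # Reduced-depth backbone for desk-scale runs: three conv stages with
      # the same GAP || GMP head idea, 128-wide feature.
      g <- .gr()
      inp <- .addNode(g, "input", "input")
      x <- .conv(g, "c1", inp, 16L, 7L, 4L)
      x <- .addNode(g, "r1", "relu", x)
      x <- .addNode(g, "p1", "maxpool", x, kh = 3L, kw = 3L, stride = 2L, pad = 1L)
      x <- .conv(g, "c2", x, 32L, 3L, 2L)
      x <- .addNode(g, "r2", "relu", x)
      x <- .conv(g, "c3", x, 64L, 3L, 2L)
      x <- .addNode(g, "r3", "relu", x)
      gapN <- .addNode(g, "gap", "gap", x)
      gmpN <- .addNode(g, "gmp", "gmp", x)
      feat <- .addNode(g, "concat", "concat", c(gapN, gmpN))
      .finishSpec(g, feat, "tiny", 128L)
    },
    stop(sprintf("unknown variant '%s'", variant)))
}

#' Build a backbone model
#'
#' Constructs the declarative graph for the requested variant and
#' initializes He-normal random weights (from-scratch mode; no pretrained
#' weights are bundled). The five ImageNet-shaped variants (`"base"`,
#' `"DI"`..`"DIV"`) expect 224 x 224 inputs with grayscale replicated to 3
#' channels; `"tiny"` is single-channel and size-agnostic.
#'
#' @param variant one of `"base"`, `"DI"`, `"DII"`, `"DIII"`, `"DIV"`,
#'   `"tiny"`.
#' @param inputChannels input channel count; defaults to 3 (1 for tiny).
#' @return A [BackboneModel-class].
#' @examples
#' m <- buildBackbone("tiny")
#' featureWidth(m)
#' @export
buildBackbone <- function(variant = .VARIANTS,
                          inputChannels = if (identical(variant, "tiny")) 1L else 3L) {
  variant <- match.arg(variant)
  if (variant == "tiny" && missing(inputChannels)) inputChannels <- 1L
  spec <- .buildArchSpec(variant)
  new("BackboneModel", spec = spec,
      weights = nnInitWeights(spec, as.integer(inputChannels)),
      inputChannels = as.integer(inputChannels), trained = FALSE,
      log = data.frame())
}

#' Total trainable parameter count
#'
#' @param model a [BackboneModel-class] or [ArchSpec-class] (specs are
#'   counted for 3 input channels).
#' @return Integer-valued numeric count of weights (conv/fc weights and
#'   biases, batch-norm scale and shift).
#' @export
paramCount <- function(model) {
  W <- if (is(model, "BackboneModel")) model@weights
       else nnInitWeights(model, 3L)
  tot <- 0
  for (p in W)
    for (nm in intersect(names(p), c("W", "b", "gamma", "beta")))
      tot <- tot + length(p[[nm]])
  tot
}

#' Training configuration
#'
#' Defaults follow the fine-tuning setup: stochastic gradient descent with
#' momentum 0.9, learning rate 1e-4, mini-batch 64, and a 90:10 stratified
#' train/validation split. The default learning rate suits fine-tuning of
#' pretrained weights; from-scratch desk-scale runs use a larger rate.
#'
#' @param epochs training epochs (default 30).
#' @param batchSize mini-batch size (default 64).
#' @param learningRate SGD learning rate (default 1e-4).
#' @param momentum SGD momentum (default 0.9).
#' @param validationFraction held-out fraction, in (0,1) (default 0.10).
#' @param patience early-stopping patience on validation loss (default 5).
#' @param seed RNG seed for the split and shuffling.
#' @param pixelMax intensity ceiling used to scale inputs to `[0, 1]`.
#' @return A list of class `"TrainConfig"`.
#' @export
trainConfig <- function(epochs = 30L, batchSize = 64L, learningRate = 1e-4,
                        momentum = 0.9, validationFraction = 0.10,
                        patience = 5L, seed = 1L, pixelMax = 255) {
  stopifnot(epochs >= 0, batchSize >= 1, learningRate > 0,
            momentum >= 0, momentum < 1,
            validationFraction > 0, validationFraction < 1)
  structure(list(epochs = as.integer(epochs), batchSize = as.integer(batchSize),
                 learningRate = learningRate, momentum = momentum,
                 validationFraction = validationFraction,
                 patience = as.integer(patience), seed = as.integer(seed),
                 pixelMax = pixelMax),
            class = "TrainConfig")
}

.labelIndex <- function(labels) {
  idx <- match(labels, .LABELS)
  if (anyNA(idx)) stop("labels must be 'benign' or 'malignant'")
  idx
}

#' Fine-tune a backbone on labeled ROIs
#'
#' Trains with SGD (momentum, fixed learning rate) on a stratified 90:10
#' train/validation split, tracking per-epoch mean cross-entropy and
#' accuracy, and returns the weights of the best-validation epoch. With
#' `epochs = 0` the initial weights are returned unchanged.
#'
#' @param model a [BackboneModel-class].
#' @param rois list of grayscale ROI matrices (sized for the model).
#' @param labels character vector (`"benign"`/`"malignant"`), one per ROI.
#' @param config a [trainConfig()].
#' @return The trained [BackboneModel-class] with `trainingLog()` populated.
#' @export
fineTune <- function(model, rois, labels, config = trainConfig()) {
  stopifnot(length(rois) == length(labels), length(rois) > 0L)
  y <- .labelIndex(labels)
  if (length(unique(y)) < 2L)
    stop("training data must contain both classes")
  set.seed(config$seed)
  # stratified 90:10 split
  val <- unlist(lapply(split(seq_along(y), y), function(ix) {
    nv <- max(1L, round(length(ix) * config$validationFraction))
    sample(ix, nv)
  }), use.names = FALSE)
  tr <- setdiff(seq_along(y), val)
  if (config$epochs == 0L) {
    model@log <- data.frame(epoch = integer(), train_loss = numeric(),
                            val_loss = numeric(), train_acc = numeric(),
                            val_acc = numeric())
    return(model)
  }
  xs <- lapply(rois, .prepInput, channels = model@inputChannels,
               pixelMax = config$pixelMax)
  weights <- model@weights
  velocity <- list()
  bestW <- weights; bestVal <- Inf; bad <- 0L
  logRows <- vector("list", config$epochs)
  evalSet <- function(ixs) {
    loss <- 0; acc <- 0
    for (i in ixs) {
      p <- nnForward(model, xs[[i]])$probs
      loss <- loss - log(max(p[y[i]], 1e-12))
      acc <- acc + (which.max(p) == y[i])
    }
    c(loss / length(ixs), acc / length(ixs))
  }
  for (ep in seq_len(config$epochs)) {
    ord <- sample(tr)
    epLoss <- 0; epAcc <- 0
    batches <- split(ord, ceiling(seq_along(ord) / config$batchSize))
    for (bt in batches) {
      acc <- list()
      for (i in bt) {
        fw <- nnForward(model, xs[[i]], keepCache = TRUE)
        bw <- nnBackward(model, fw, y[[i]])
        epLoss <- epLoss + bw$loss
        epAcc <- epAcc + (which.max(fw$probs) == y[i])
        for (id in names(bw$grads)) {
          if (is.null(acc[[id]])) acc[[id]] <- bw$grads[[id]]
          else for (nm in names(bw$grads[[id]]))
            acc[[id]][[nm]] <- acc[[id]][[nm]] + bw$grads[[id]][[nm]]
        }
      }
      for (id in names(acc))
        for (nm in names(acc[[id]]))
          acc[[id]][[nm]] <- acc[[id]][[nm]] / length(bt)
      st <- nnSGDStep(weights, velocity, acc, config$learningRate,
                      config$momentum)
      weights <- st$weights; velocity <- st$velocity
      model@weights <- weights
    }
    vl <- evalSet(val)
    logRows[[ep]] <- data.frame(epoch = ep, train_loss = epLoss / length(tr),
                                val_loss = vl[1L],
                                train_acc = epAcc / length(tr),
                                val_acc = vl[2L])
    if (vl[1L] < bestVal) { bestVal <- vl[1L]; bestW <- weights; bad <- 0L }
    else bad <- bad + 1L
    if (bad >= config$patience) { logRows <- logRows[seq_len(ep)]; break }
  }
  model@weights <- bestW
  model@trained <- TRUE
  model@log <- do.call(rbind, logRows[!vapply(logRows, is.null, logical(1))])
  model
}

#' Per-ROI class probabilities
#'
#' Runs the backbone over every ROI of a set, preserving order. Grayscale
#' pixels are scaled to `[0, 1]` and replicated across the model's input
#' channels.
#'
#' @param model a [BackboneModel-class].
#' @param rois an [ROISet-class] or a list of grayscale matrices.
#' @param pixelMax intensity ceiling for scaling (default 255).
#' @return Numeric matrix with one row per ROI and columns
#'   `c("benign", "malignant")`; rows sum to 1.
#' @export
predictProba <- function(model, rois, pixelMax = 255) {
  roiL <- if (is(rois, "ROISet")) roiList(rois) else rois
  if (length(roiL) == 0L) stop("no ROIs to predict")
  out <- matrix(NA_real_, length(roiL), 2L,
                dimnames = list(NULL, .LABELS))
  for (i in seq_along(roiL)) {
    x <- .prepInput(roiL[[i]], model@inputChannels, pixelMax)
    out[i, ] <- nnForward(model, x)$probs
  }
  out
}
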