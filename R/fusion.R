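#' @title Fusing per-ROI predictions
#' @description Combines the backbone's per-ROI predictions for one mass
#'   into a single benign/malignant decision. Three voting rules (majority,
#'   soft, max) treat all ROIs equally; stacked generalization trains a
#'   meta-classifier (SVM with RBF/linear/polynomial kernel, or a random
#'   forest) on the ordered vector of per-ROI malignancy probabilities, so
#'   ROIs are weighted by their learned usefulness. Ties are resolved to
#'   malignant: a screening decision favors sensitivity, and the benign
#'   branch requires a strictly larger benign probability.
#' @name fusion
NULL

.STACKER_KINDS <- c("svm_rbf", "svm_linear", "svm_poly", "random_forest")

.asLabel <- function(x) factor(x, levels = .LABELS)

#' Majority vote over per-ROI labels
#'
#' @param labels character/factor vector of `"benign"`/`"malignant"` votes.
#' @return The label with strictly more votes; ties go to `"malignant"`.
#' @examples
#' majorityVote(c("benign", "benign", "malignant"))
#' @export
majorityVote <- function(labels) {
  if (length(labels) == 0L) stop("no labels to fuse")
  v <- table(.asLabel(labels))
  if (v[["benign"]] > v[["malignant"]]) "benign" else "malignant"
}

#' Soft vote: average the per-ROI probabilities
#'
#' @param probs numeric matrix, one row per ROI, columns
#'   `(benign, malignant)`.
#' @return List with `label` and the averaged `probs` pair.
#' @examples
#' softVote(rbind(c(0.6, 0.4), c(0.2, 0.8)))
#' @export
softVote <- function(probs) {
  probs <- rbind(probs)
  if (nrow(probs) == 0L) stop("no probabilities to fuse")
  p <- colMeans(probs)
  names(p) <- .LABELS
  list(label = if (p[1L] > p[2L]) "benign" else "malignant", probs = p)
}

#' Max vote: take the per-class maximum over ROIs
#'
#' @param probs numeric matrix, one row per ROI, columns
#'   `(benign, malignant)`.
#' @return List with `label` and the per-class maxima `probs`.
#' @examples
#' maxVote(rbind(c(0.6, 0.4), c(0.2, 0.8)))
#' @export
maxVote <- function(probs) {
  probs <- rbind(probs)
  if (nrow(probs) == 0L) stop("no probabilities to fuse")
  p <- apply(probs, 2L, max)
  names(p) <- .LABELS
  list(label = if (p[1L] > p[2L]) "benign" else "malignant", probs = p)
}

#' Build the stack vector for one mass
#'
#' The meta-classifier's feature vector is the ordered sequence of
#' malignant-class probabilities, one per ROI in ROISet order (the benign
#' probability is redundant since the pair sums to one). Order carries
#' meaning -- position identifies the context -- so permuting it is invalid.
#'
#' @param probs matrix of per-ROI `(benign, malignant)` probabilities in
#'   ROISet order.
#' @return Numeric vector of malignant probabilities.
#' @export
stackVector <- function(probs) {
  probs <- rbind(probs)
  as.numeric(probs[, 2L])
}

#' Fit a stacking meta-classifier
#'
#' Standardizes the stack vectors and fits the requested model. The stacker
#' is trained on backbone predictions over the training and validation
#' regions.
#'
#' @param vectors numeric matrix, one row per mass (stack vectors of equal
#'   length), or list of equal-length vectors.
#' @param labels `"benign"`/`"malignant"` per row.
#' @param kind `"svm_rbf"` (default), `"svm_linear"`, `"svm_poly"` or
#'   `"random_forest"`.
#' @param cost,gamma,degree SVM hyperparameters (defaults: `cost = 1`,
#'   e1071's `gamma = 1/ncol`, polynomial `degree = 3`).
#' @param seed RNG seed (random forest).
#' @return A [StackerModel-class].
#' @export
fitStacker <- function(vectors, labels, kind = .STACKER_KINDS,
                       cost = 1, gamma = NULL, degree = 3, seed = 1L) {
  kind <- match.arg(kind)
  X <- if (is.list(vectors)) do.call(rbind, vectors) else rbind(vectors)
  if (nrow(X) != length(labels)) stop("one label per stack vector required")
  y <- .asLabel(labels)
  if (any(table(y) < 2L)) stop("need at least two samples per class")
  ctr <- colMeans(X)
  scl <- apply(X, 2L, sd); scl[scl < 1e-12] <- 1
  Xs <- scale(X, center = ctr, scale = scl)
  colnames(Xs) <- sprintf("roi%02d", seq_len(ncol(Xs)))
  set.seed(seed)
  model <- if (kind == "random_forest") {
    randomForest::randomForest(Xs, y)
  } else {
    kernel <- c(svm_rbf = "radial", svm_linear = "linear",
                svm_poly = "polynomial")[[kind]]
    args <- list(x = Xs, y = y, kernel = kernel, cost = cost, scale = FALSE)
    if (!is.null(gamma)) args$gamma <- gamma
    if (kernel == "polynomial") args$degree <- degree
    do.call(e1071::svm, args)
  }
  new("StackerModel", kind = kind, model = model, center = ctr,
      scale = as.numeric(scl), nFeatures = ncol(X))
}

#' Predict a mass label from its stack vector
#'
#' @param stacker a fitted [StackerModel-class].
#' @param vector numeric stack vector (or matrix of them, one per row) of
#'   the length the stacker was trained on.
#' @return Character label(s).
#' @export
predictStacked <- function(stacker, vector) {
  X <- rbind(vector)
  if (ncol(X) != stacker@nFeatures)
    stop(sprintf("stack vector length %d does not match training length %d",
                 ncol(X), stacker@nFeatures))
  Xs <- scale(X, center = stacker@center, scale = stacker@scale)
  colnames(Xs) <- sprintf("roi%02d", seq_len(ncol(Xs)))
  as.character(predict(stacker@model, Xs))
}

#' Fuse per-ROI probabilities with a named rule
#'
#' Convenience dispatcher used by the pipeline: `"majority"`, `"soft"`,
#' `"max"` apply the voting rules; `"stack-rbf"`, `"stack-linear"`,
#' `"stack-poly"`, `"stack-rf"` require a fitted `stacker`.
#'
#' @param probs per-ROI probability matrix in ROISet order.
#' @param rule fusion rule name.
#' @param stacker optional [StackerModel-class] for the stacking rules.
#' @return Character label.
#' @export
fuseDecision <- function(probs, rule, stacker = NULL) {
  switch(rule,
    majority = majorityVote(.LABELS[ifelse(probs[, 1L] > probs[, 2L], 1L, 2L)]),
    soft = softVote(probs)$label,
    max = maxVote(probs)$label,
    `stack-rbf` = , `stack-linear` = , `stack-poly` = , `stack-rf` = {
      if (is.null(stacker)) stop("stacking rules need a fitted stacker")
      predictStacked(stacker, stackVector(probs))
    },
    stop(sprintf("unknown fusion rule '%s'", rule)))
}
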