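# Shared fixtures, built in code.

# Deterministic asymmetric matrix (no rotational/reflective symmetry).
asymMatrix <- function(n = 6L) matrix(seq_len(n * n), n, n)

# A small MassRegion with a gradient image and a given geometry.
gradientRegion <- function(rows, cols, bbox, label = "benign",
                           density = "II", id = "fixture") {
  img <- outer(seq_len(rows), seq_len(cols), function(i, j) (i * 7 + j * 3) %% 256)
  MassRegion(img, bbox, label = label, density = density, id = id)
}

# Tiny labeled patch set that is separable by construction: malignant
# patches carry a large bright square, benign a small dim one.
separablePatches <- function(nPerClass = 40L, size = 56L, seed = 42L) {
  set.seed(seed)
  mk <- function(cls) {
    x <- matrix(runif(size * size, 0, 80), size, size)
    c0 <- size %/% 2L
    if (cls == "malignant") {
      w <- size %/% 3L
      x[(c0 - w):(c0 + w), (c0 - w):(c0 + w)] <-
        x[(c0 - w):(c0 + w), (c0 - w):(c0 + w)] + 120
    } else {
      w <- size %/% 7L
      x[(c0 - w):(c0 + w), (c0 - w):(c0 + w)] <-
        x[(c0 - w):(c0 + w), (c0 - w):(c0 + w)] + 60
    }
    pmin(x, 255)
  }
  labels <- rep(c("benign", "malignant"), each = nPerClass)
  list(rois = lapply(labels, mk), labels = labels)
}

# Separable stack-vector toy set: class means 0.2 vs 0.8 per feature.
toyStackSet <- function(nPerClass = 50L, len = 11L, seed = 7L) {
  set.seed(seed)
  X <- rbind(
    matrix(pmin(pmax(rnorm(nPerClass * len, 0.2, 0.05), 0), 1), nPerClass),
    matrix(pmin(pmax(rnorm(nPerClass * len, 0.8, 0.05), 0), 1), nPerClass))
  list(X = X, labels = rep(c("benign", "malignant"), each = nPerClass))
}
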