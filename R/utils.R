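# Internal numeric and image helpers shared across modules.

# Round half away from zero (base round() is banker's rounding).
roundHalfUp <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Bilinear resize of a rows x cols intensity matrix to explicit output
# dimensions. EBImage's first array dimension maps onto our row dimension,
# so w/h are passed as rows/cols.
resizeBilinear <- function(x, outRows, outCols) {
  stopifnot(is.matrix(x), outRows >= 1, outCols >= 1)
  y <- EBImage::resize(x, w = outRows, h = outCols, filter = "bilinear")
  as.matrix(y)
}

# Lossless clockwise rotation by a multiple of 90 degrees.
rot90cw <- function(x, times = 1L) {
  times <- as.integer(times) %% 4L
  for (i in seq_len(times)) x <- t(x[rev(seq_len(nrow(x))), , drop = FALSE])
  x
}

# Horizontal flip: mirror columns (left-right in image terms).
flipHorizontal <- function(x) {
  x[, rev(seq_len(ncol(x))), drop = FALSE]
}

# Clamp a scalar/vector into [lo, hi].
clampRange <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a
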