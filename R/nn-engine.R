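#' @title CNN graph engine
#' @description A compact computational-graph engine for the backbone
#'   networks: convolution (via im2col lowering to BLAS matrix products),
#'   batch normalization (frozen statistics), ReLU, max pooling, global
#'   average/max pooling, concatenation, residual addition, fully connected
#'   layers and softmax, with reverse-mode gradients for SGD training.
#'   Activations are `H x W x C` arrays; pooled features are plain vectors.
#' @name nn-engine
NULL

.BN_EPS <- 1e-5

# ---- shape inference -------------------------------------------------------

# Returns a named list: per node either c(H, W, C) or an integer width.
nnInferShapes <- function(spec, inputShape) {
  shapes <- list()
  for (nd in spec@nodes) {
    ins <- lapply(nd$inputs, function(i) shapes[[i]])
    shapes[[nd$id]] <- switch(nd$op,
      input = inputShape,
      conv = {
        s <- ins[[1L]]
        c((s[1L] + 2L * nd$pad - nd$kh) %/% nd$stride + 1L,
          (s[2L] + 2L * nd$pad - nd$kw) %/% nd$stride + 1L, nd$filters)
      },
      maxpool = {
        s <- ins[[1L]]
        c((s[1L] + 2L * nd$pad - nd$kh) %/% nd$stride + 1L,
          (s[2L] + 2L * nd$pad - nd$kw) %/% nd$stride + 1L, s[3L])
      },
      bn = , relu = , add = ins[[1L]],
      gap = , gmp = ins[[1L]][3L],
      concat = sum(vapply(ins, function(s) s[length(s)], numeric(1))),
      fc = nd$units,
      softmax = ins[[1L]],
      stop(sprintf("unknown op '%s'", nd$op)))
  }
  shapes
}

# ---- initialization --------------------------------------------------------

# He-normal initialization given inferred input shapes.
nnInitWeights <- function(spec, inputChannels) {
  shapes <- nnInferShapes(spec, c(NA, NA, inputChannels))
  W <- list()
  for (nd in spec@nodes) {
    if (nd$op == "conv") {
      cin <- shapes[[nd$inputs[1L]]][3L]
      k <- nd$kh * nd$kw * cin
      W[[nd$id]] <- list(
        W = matrix(rnorm(k * nd$filters, sd = sqrt(2 / k)), k, nd$filters),
        b = numeric(nd$filters))
    } else if (nd$op == "bn") {
      ch <- shapes[[nd$inputs[1L]]][3L]
      W[[nd$id]] <- list(gamma = rep(1, ch), beta = numeric(ch),
                         mean = numeric(ch), var = rep(1, ch))
    } else if (nd$op == "fc") {
      cin <- shapes[[nd$inputs[1L]]]
      cin <- cin[length(cin)]
      W[[nd$id]] <- list(
        W = matrix(rnorm(cin * nd$units, sd = sqrt(2 / cin)), cin, nd$units),
        b = numeric(nd$units))
    }
  }
  W
}

# ---- forward ---------------------------------------------------------------

.asCube <- function(x) if (length(dim(x)) == 3L) x else array(x, c(dim(x), 1L))

# Forward pass for one input array (H x W x C). Returns the softmax output
# and, when keepCache, every node activation plus pooling bookkeeping.
nnForward <- function(model, x, keepCache = FALSE) {
  acts <- list(); aux <- list()
  W <- model@weights
  for (nd in model@spec@nodes) {
    ins <- lapply(nd$inputs, function(i) acts[[i]])
    val <- switch(nd$op,
      input = .asCube(x),
      conv = {
        a <- ins[[1L]]
        cols <- .im2col_cpp(a, nd$kh, nd$kw, nd$stride, nd$pad)
        oH <- (dim(a)[1L] + 2L * nd$pad - nd$kh) %/% nd$stride + 1L
        oW <- (dim(a)[2L] + 2L * nd$pad - nd$kw) %/% nd$stride + 1L
        out <- crossprod(cols, W[[nd$id]]$W)
        out <- sweep(out, 2L, W[[nd$id]]$b, "+")
        if (keepCache) aux[[nd$id]] <- cols
        array(out, c(oH, oW, nd$filters))
      },
      bn = {
        p <- W[[nd$id]]
        s <- sqrt(p$var + .BN_EPS)
        a <- ins[[1L]]
        sweep(sweep(a, 3L, p$mean, "-"), 3L, p$gamma / s, "*") +
          array(rep(p$beta, each = prod(dim(a)[1:2])), dim(a))
      },
      relu = pmax(ins[[1L]], 0),
      add = ins[[1L]] + ins[[2L]],
      maxpool = {
        r <- .maxpool_fwd_cpp(ins[[1L]], nd$kh, nd$kw, nd$stride, nd$pad)
        if (keepCache) aux[[nd$id]] <- r$argmax
        r$out
      },
      gap = apply(ins[[1L]], 3L, mean),
      gmp = {
        a <- ins[[1L]]
        m <- apply(a, 3L, max)
        if (keepCache)
          aux[[nd$id]] <- vapply(seq_len(dim(a)[3L]),
                                 function(c) which.max(a[, , c]), integer(1))
        m
      },
      concat = unlist(ins, use.names = FALSE),
      fc = {
        v <- as.numeric(ins[[1L]])
        drop(crossprod(W[[nd$id]]$W, v)) + W[[nd$id]]$b
      },
      softmax = {
        z <- ins[[1L]] - max(ins[[1L]])
        exp(z) / sum(exp(z))
      })
    acts[[nd$id]] <- val
  }
  out <- acts[[model@spec@nodes[[length(model@spec@nodes)]]$id]]
  if (keepCache) list(probs = out, acts = acts, aux = aux) else list(probs = out)
}

# ---- backward --------------------------------------------------------------

# Reverse-mode pass from softmax cross-entropy at target class (1-based).
# Returns gradients keyed like the weights and the scalar loss.
nnBackward <- function(model, fw, target) {
  spec <- model@spec; W <- model@weights
  acts <- fw$acts; aux <- fw$aux
  nodes <- spec@nodes
  grads <- list()
  dacts <- list()
  nOut <- nodes[[length(nodes)]]$id
  p <- acts[[nOut]]
  loss <- -log(max(p[target], 1e-12))
  dacts[[nOut]] <- { d <- p; d[target] <- d[target] - 1; d }  # softmax+CE
  for (k in rev(seq_along(nodes))) {
    nd <- nodes[[k]]
    dy <- dacts[[nd$id]]
    if (is.null(dy)) next
    addGrad <- function(id, g) {
      dacts[[id]] <<- if (is.null(dacts[[id]])) g else dacts[[id]] + g
    }
    switch(nd$op,
      input = NULL,
      softmax = addGrad(nd$inputs[1L], dy),  # dy already holds dLoss/dlogits
      fc = {
        v <- as.numeric(acts[[nd$inputs[1L]]])
        grads[[nd$id]] <- list(W = outer(v, dy), b = dy)
        g <- drop(W[[nd$id]]$W %*% dy)
        up <- acts[[nd$inputs[1L]]]
        addGrad(nd$inputs[1L], if (is.null(dim(up))) g else array(g, dim(up)))
      },
      concat = {
        pos <- 0L
        for (i in nd$inputs) {
          w <- length(acts[[i]])
          addGrad(i, dy[(pos + 1L):(pos + w)])
          pos <- pos + w
        }
      },
      gap = {
        a <- acts[[nd$inputs[1L]]]
        n <- prod(dim(a)[1:2])
        addGrad(nd$inputs[1L], array(rep(dy / n, each = n), dim(a)))
      },
      gmp = {
        a <- acts[[nd$inputs[1L]]]
        g <- array(0, dim(a))
        idx <- aux[[nd$id]]
        n <- prod(dim(a)[1:2])
        g[idx + (seq_along(idx) - 1L) * n] <- dy
        addGrad(nd$inputs[1L], g)
      },
      maxpool = {
        a <- acts[[nd$inputs[1L]]]
        addGrad(nd$inputs[1L],
                .maxpool_bwd_cpp(.asCube(dy), aux[[nd$id]],
                                 dim(a)[1L], dim(a)[2L]))
      },
      add = { addGrad(nd$inputs[1L], dy); addGrad(nd$inputs[2L], dy) },
      relu = addGrad(nd$inputs[1L], dy * (acts[[nd$id]] > 0)),
      bn = {
        p2 <- W[[nd$id]]
        s <- sqrt(p2$var + .BN_EPS)
        a <- acts[[nd$inputs[1L]]]
        xhat <- sweep(sweep(a, 3L, p2$mean, "-"), 3L, s, "/")
        grads[[nd$id]] <- list(
          gamma = apply(dy * xhat, 3L, sum),
          beta = apply(dy, 3L, sum))
        addGrad(nd$inputs[1L], sweep(dy, 3L, p2$gamma / s, "*"))
      },
      conv = {
        a <- acts[[nd$inputs[1L]]]
        dyMat <- matrix(dy, ncol = nd$filters)
        cols <- aux[[nd$id]]
        grads[[nd$id]] <- list(W = cols %*% dyMat, b = colSums(dyMat))
        dcols <- W[[nd$id]]$W %*% t(dyMat)
        addGrad(nd$inputs[1L],
                .col2im_cpp(dcols, dim(a)[1L], dim(a)[2L], dim(a)[3L],
                            nd$kh, nd$kw, nd$stride, nd$pad))
      })
  }
  list(grads = grads, loss = loss)
}

# ---- SGD with momentum -----------------------------------------------------

# In-place-style update: returns list(weights, velocity).
nnSGDStep <- function(weights, velocity, grads, lr, momentum) {
  for (id in names(grads)) {
    for (nm in names(grads[[id]])) {
      g <- grads[[id]][[nm]]
      v <- velocity[[id]][[nm]]
      if (is.null(v)) v <- g * 0
      v <- momentum * v - lr * g
      velocity[[id]][[nm]] <- v
      weights[[id]][[nm]] <- weights[[id]][[nm]] + v
    }
  }
  list(weights = weights, velocity = velocity)
}

# Replicate a grayscale matrix across the model's input channels and scale
# intensities to [0, 1].
.prepInput <- function(roi, channels, pixelMax) {
  x <- roi / pixelMax
  array(rep(x, channels), c(dim(roi), channels))
}
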