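# Minimal neural-network engine: layers as environments with forward /
# backward closures over BLAS matrix products. Activations for
# convolutional stacks are arrays (H, W, C, N); token stacks for the
# transformer are arrays (D, T, N). All randomness is drawn from the
# caller's RNG state so model construction and training are seeded as a
# whole.

newLayer <- function(type) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  e$params <- list()
  e$grads <- list()
  e$children <- list()
  e
}

# Recursively collect layers that own parameters.
collectParams <- function(layer) {
  out <- list()
  if (length(layer$params)) out <- list(layer)
  for (ch in layer$children) out <- c(out, collectParams(ch))
  out
}

countLayerParams <- function(layer) {
  sum(vapply(collectParams(layer), function(l)
    sum(vapply(l$params, length, numeric(1))), numeric(1)))
}

# He-uniform init for conv/dense weights.
heInit <- function(fanIn, n) {
  lim <- sqrt(6 / fanIn)
  stats::runif(n, -lim, lim)
}

# Precompute im2col linear indices for input (H, W, C, N) -> columns of
# kh*kw*C rows by OH*OW*N cols; returns list(idx matrix for n=1, dims).
im2colIndex <- function(H, W, C, kh, kw, stride, pad) {
  Hp <- H + 2 * pad; Wp <- W + 2 * pad
  OH <- (Hp - kh) %/% stride + 1L
  OW <- (Wp - kw) %/% stride + 1L
  oy <- rep(seq_len(OH), times = OW)
  ox <- rep(seq_len(OW), each = OH)
  ky <- rep(seq_len(kh), times = kw * C)
  kx <- rep(rep(seq_len(kw), each = kh), times = C)
  kc <- rep(seq_len(C), each = kh * kw)
  y <- outer(ky, (oy - 1L) * stride, `+`)            # (khkwC, OHOW)
  x <- outer(kx, (ox - 1L) * stride, `+`)
  idx <- y + Hp * (x - 1L) + Hp * Wp * rep(kc - 1L, times = OH * OW)
  dim(idx) <- c(kh * kw * C, OH * OW)
  list(idx = idx, Hp = Hp, Wp = Wp, OH = OH, OW = OW, planeSize = Hp * Wp * C)
}

padInput <- function(x, pad) {
  if (pad == 0) return(x)
  d <- dim(x)
  xp <- array(0, c(d[1] + 2 * pad, d[2] + 2 * pad, d[3], d[4]))
  xp[pad + seq_len(d[1]), pad + seq_len(d[2]), , ] <- x
  xp
}

newConv2d <- function(inC, outC, k = 3L, stride = 1L, pad = (k - 1L) %/% 2L) {
  e <- newLayer("conv2d")
  R <- k * k * inC
  e$params <- list(W = matrix(heInit(R, R * outC), R, outC),
                   b = numeric(outC))
  e$meta <- list(inC = inC, outC = outC, k = k, stride = stride, pad = pad)
  e$forward <- function(x, training = FALSE) {
    d <- dim(x)
    m <- e$meta
    key <- paste(d, collapse = "x")
    if (is.null(e$idxKey) || e$idxKey != key) {
      e$ii <- im2colIndex(d[1], d[2], d[3], m$k, m$k, m$stride, m$pad)
      n <- d[4]
      off <- rep((seq_len(n) - 1L) * e$ii$planeSize,
                 each = length(e$ii$idx))
      fullIdx <- as.vector(e$ii$idx) + off
      e$fullIdx <- fullIdx
      # within one kernel offset, scatter destinations never collide, so
      # col2im can be done in k*k disjoint vectorized scatter-adds
      R <- nrow(e$ii$idx)
      kk <- m$k * m$k
      idxArr <- array(fullIdx, c(R, length(fullIdx) / R))
      e$sliceRows <- lapply(seq_len(kk), function(o)
        o + kk * (seq_len(m$inC) - 1L))
      e$sliceIdx <- lapply(e$sliceRows, function(rs)
        as.vector(idxArr[rs, , drop = FALSE]))
      e$idxKey <- key
      e$n <- n
    }
    xp <- padInput(x, m$pad)
    Xc <- xp[e$fullIdx]
    dim(Xc) <- c(nrow(e$ii$idx), e$ii$OH * e$ii$OW * d[4])
    out <- crossprod(e$params$W, Xc) + e$params$b
    e$cacheXc <- Xc
    dim(out) <- c(m$outC, e$ii$OH, e$ii$OW, d[4])
    aperm(out, c(2, 3, 1, 4))
  }
  e$backward <- function(dy) {
    m <- e$meta
    d <- dim(dy)                               # (OH, OW, outC, N)
    dyMat <- aperm(dy, c(3, 1, 2, 4))
    dim(dyMat) <- c(m$outC, d[1] * d[2] * d[4])
    e$grads <- list(W = tcrossprod(e$cacheXc, dyMat),
                    b = rowSums(dyMat))
    dXc <- e$params$W %*% dyMat
    dxp <- numeric(e$ii$planeSize * d[4])
    for (o in seq_along(e$sliceIdx)) {
      iv <- e$sliceIdx[[o]]
      dxp[iv] <- dxp[iv] + as.vector(dXc[e$sliceRows[[o]], , drop = FALSE])
    }
    dim(dxp) <- c(e$ii$Hp, e$ii$Wp, m$inC, d[4])
    if (m$pad > 0)
      dxp <- dxp[m$pad + seq_len(e$ii$Hp - 2 * m$pad),
                 m$pad + seq_len(e$ii$Wp - 2 * m$pad), , , drop = FALSE]
    dxp
  }
  e
}

newBatchNorm2d <- function(C, momentum = 0.1, eps = 1e-5) {
  e <- newLayer("batchnorm2d")
  e$params <- list(gamma = rep(1, C), beta = numeric(C))
  e$runMean <- numeric(C)
  e$runVar <- rep(1, C)
  e$calib <- NULL
  e$meta <- list(C = C, momentum = momentum, eps = eps)
  # channel-first layout (C, H*W*N) lets length-C vectors recycle down
  # columns with no sweep() allocations
  e$forward <- function(x, training = FALSE) {
    d <- dim(x)
    xm <- aperm(x, c(3, 1, 2, 4))
    dim(xm) <- c(d[3], d[1] * d[2] * d[4])
    if (training) {
      mu <- rowMeans(xm)
      xc <- xm - mu
      v <- rowMeans(xc^2)
      m <- e$meta$momentum
      e$runMean <- (1 - m) * e$runMean + m * mu
      e$runVar <- (1 - m) * e$runVar + m * v
      if (!is.null(e$calib)) {
        n <- ncol(xm)
        e$calib$sum <- e$calib$sum + mu * n
        e$calib$sumsq <- e$calib$sumsq + (v + mu^2) * n
        e$calib$n <- e$calib$n + n
      }
    } else {
      mu <- e$runMean
      v <- e$runVar
      xc <- xm - mu
    }
    istd <- 1 / sqrt(v + e$meta$eps)
    xhat <- xc * istd
    y <- xhat * e$params$gamma + e$params$beta
    e$cache <- list(xhat = xhat, istd = istd, d = d, training = training)
    dim(y) <- c(d[3], d[1], d[2], d[4])
    aperm(y, c(2, 3, 1, 4))
  }
  e$backward <- function(dy) {
    cc <- e$cache
    d <- cc$d
    dym <- aperm(dy, c(3, 1, 2, 4))
    dim(dym) <- c(d[3], d[1] * d[2] * d[4])
    e$grads <- list(gamma = rowSums(dym * cc$xhat), beta = rowSums(dym))
    dxhat <- dym * e$params$gamma
    if (cc$training) {
      dx <- (dxhat - rowMeans(dxhat) -
               cc$xhat * rowMeans(dxhat * cc$xhat)) * cc$istd
    } else {
      dx <- dxhat * cc$istd
    }
    dim(dx) <- c(d[3], d[1], d[2], d[4])
    aperm(dx, c(2, 3, 1, 4))
  }
  e
}

# Walk the layer tree, applying fn to every layer of the given type.
walkLayers <- function(layer, type, fn) {
  if (identical(layer$type, type)) fn(layer)
  for (ch in layer$children) walkLayers(ch, type, fn)
  invisible(NULL)
}

# Recompute exact batch-norm population statistics from a calibration set.
# Running averages collected with momentum lag behind the weights they
# normalize for; a calibration pass pins the inference-time statistics to
# the current weights.
calibrateBatchNorm <- function(net, batches) {
  walkLayers(net, "batchnorm2d", function(l)
    l$calib <- list(sum = numeric(l$meta$C), sumsq = numeric(l$meta$C),
                    n = 0))
  saved <- list()
  walkLayers(net, "dropout", function(l) {
    saved[[length(saved) + 1L]] <<- list(l = l, p = l$p)
    l$p <- 0
  })
  for (x in batches) net$forward(x, training = TRUE)
  walkLayers(net, "batchnorm2d", function(l) {
    if (l$calib$n > 0) {
      mu <- l$calib$sum / l$calib$n
      l$runMean <- mu
      l$runVar <- l$calib$sumsq / l$calib$n - mu^2
    }
    l$calib <- NULL
  })
  for (s in saved) s$l$p <- s$p
  invisible(NULL)
}

newReLU <- function() {
  e <- newLayer("relu")
  e$forward <- function(x, training = FALSE) {
    e$mask <- x > 0
    x * e$mask
  }
  e$backward <- function(dy) dy * e$mask
  e
}

newDropout <- function(p) {
  e <- newLayer("dropout")
  e$p <- p
  e$forward <- function(x, training = FALSE) {
    if (!training || e$p <= 0) {
      e$mask <- NULL
      return(x)
    }
    e$mask <- array(stats::runif(length(x)) >= e$p, dim(x) %||% length(x)) /
      (1 - e$p)
    x * e$mask
  }
  e$backward <- function(dy) if (is.null(e$mask)) dy else dy * e$mask
  e
}

`%||%` <- function(a, b) if (is.null(a)) b else a

newMaxPool2 <- function(k = 2L) {
  e <- newLayer("maxpool")
  e$k <- k
  e$forward <- function(x, training = FALSE) {
    d <- dim(x)
    k <- e$k
    OH <- d[1] %/% k; OW <- d[2] %/% k
    x <- x[seq_len(OH * k), seq_len(OW * k), , , drop = FALSE]
    # split each k x k block into k^2 planes
    dim(x) <- c(k, OH, k, OW, d[3], d[4])
    x <- aperm(x, c(2, 4, 5, 6, 1, 3))
    dim(x) <- c(OH * OW * d[3] * d[4], k * k)
    e$arg <- max.col(x, ties.method = "first")
    mx <- x[cbind(seq_len(nrow(x)), e$arg)]
    e$d <- d
    e$odims <- c(OH, OW, d[3], d[4])
    array(mx, e$odims)
  }
  e$backward <- function(dy) {
    k <- e$k
    od <- e$odims
    d <- e$d
    g <- matrix(0, od[1] * od[2] * od[3] * od[4], k * k)
    g[cbind(seq_len(nrow(g)), e$arg)] <- as.vector(dy)
    dim(g) <- c(od[1], od[2], od[3], od[4], k, k)
    g <- aperm(g, c(5, 1, 6, 2, 3, 4))
    dim(g) <- c(od[1] * k, od[2] * k, od[3], od[4])
    if (od[1] * k != d[1] || od[2] * k != d[2]) {
      full <- array(0, d)
      full[seq_len(od[1] * k), seq_len(od[2] * k), , ] <- g
      g <- full
    }
    g
  }
  e
}

newGlobalAvgPool <- function() {
  e <- newLayer("gap")
  e$forward <- function(x, training = FALSE) {
    d <- dim(x)
    e$d <- d
    xm <- x
    dim(xm) <- c(d[1] * d[2], d[3] * d[4])
    out <- colMeans(xm)
    dim(out) <- c(d[3], d[4])
    out
  }
  e$backward <- function(dy) {
    d <- e$d
    g <- array(rep(as.vector(dy), each = d[1] * d[2]) / (d[1] * d[2]), d)
    g
  }
  e
}

newDense <- function(inF, outF) {
  e <- newLayer("dense")
  e$params <- list(W = matrix(heInit(inF, inF * outF), outF, inF),
                   b = numeric(outF))
  e$forward <- function(x, training = FALSE) {
    if (!is.matrix(x)) {
      d <- dim(x)
      if (is.null(d)) d <- c(length(x), 1L)
      dim(x) <- c(prod(d) / d[length(d)], d[length(d)])
    }
    e$x <- x
    e$params$W %*% x + e$params$b
  }
  e$backward <- function(dy) {
    e$grads <- list(W = tcrossprod(dy, e$x), b = rowSums(dy))
    crossprod(e$params$W, dy)
  }
  e
}

newFlatten <- function() {
  e <- newLayer("flatten")
  e$forward <- function(x, training = FALSE) {
    e$d <- dim(x)
    n <- e$d[length(e$d)]
    dim(x) <- c(length(x) / n, n)
    x
  }
  e$backward <- function(dy) {
    dim(dy) <- e$d
    dy
  }
  e
}

newSequential <- function(...) {
  e <- newLayer("sequential")
  e$children <- list(...)
  e$forward <- function(x, training = FALSE) {
    for (l in e$children) x <- l$forward(x, training)
    x
  }
  e$backward <- function(dy) {
    for (l in rev(e$children)) dy <- l$backward(dy)
    dy
  }
  e
}

# Residual basic block (two 3x3 convs with batch norm; projection shortcut
# when shape changes).
newResBlock <- function(inC, outC, stride = 1L) {
  e <- newLayer("resblock")
  main <- newSequential(newConv2d(inC, outC, 3L, stride),
                        newBatchNorm2d(outC), newReLU(),
                        newConv2d(outC, outC, 3L, 1L),
                        newBatchNorm2d(outC))
  short <- if (stride != 1L || inC != outC)
    newSequential(newConv2d(inC, outC, 1L, stride, pad = 0L),
                  newBatchNorm2d(outC))
  else NULL
  e$children <- c(list(main), if (!is.null(short)) list(short))
  e$main <- main
  e$short <- short
  e$forward <- function(x, training = FALSE) {
    y <- e$main$forward(x, training)
    s <- if (is.null(e$short)) x else e$short$forward(x, training)
    out <- y + s
    e$mask <- out > 0
    out * e$mask
  }
  e$backward <- function(dy) {
    dy <- dy * e$mask
    dx <- e$main$backward(dy)
    ds <- if (is.null(e$short)) dy else e$short$backward(dy)
    dx + ds
  }
  e
}

## ---- transformer pieces (tokens as (D, T, N) arrays) ----

newLayerNorm <- function(D, eps = 1e-6) {
  e <- newLayer("layernorm")
  e$params <- list(gamma = rep(1, D), beta = numeric(D))
  e$eps <- eps
  e$forward <- function(x, training = FALSE) {
    d <- dim(x)
    xm <- x
    dim(xm) <- c(d[1], prod(d[-1]))
    mu <- colMeans(xm)
    xc <- sweep(xm, 2, mu)
    v <- colMeans(xc^2)
    istd <- 1 / sqrt(v + e$eps)
    xhat <- sweep(xc, 2, istd, `*`)
    y <- xhat * e$params$gamma + e$params$beta
    e$cache <- list(xhat = xhat, istd = istd, d = d)
    dim(y) <- d
    y
  }
  e$backward <- function(dy) {
    cc <- e$cache
    d <- cc$d
    dym <- dy
    dim(dym) <- c(d[1], prod(d[-1]))
    e$grads <- list(gamma = rowSums(dym * cc$xhat), beta = rowSums(dym))
    dxhat <- dym * e$params$gamma
    dx <- sweep(dxhat, 2, colMeans(dxhat)) -
      sweep(cc$xhat, 2, colMeans(dxhat * cc$xhat), `*`)
    dx <- sweep(dx, 2, cc$istd, `*`)
    dim(dx) <- d
    dx
  }
  e
}

newGELU <- function() {
  e <- newLayer("gelu")
  e$forward <- function(x, training = FALSE) {
    e$x <- x
    x * stats::pnorm(x)
  }
  e$backward <- function(dy) {
    x <- e$x
    dy * (stats::pnorm(x) + x * stats::dnorm(x))
  }
  e
}

# Token-wise dense: x (D, T, N) treated as matrix (D, T*N).
newTokenDense <- function(inF, outF) {
  e <- newLayer("tokendense")
  sd0 <- 0.02
  e$params <- list(W = matrix(stats::rnorm(outF * inF, 0, sd0), outF, inF),
                   b = numeric(outF))
  e$forward <- function(x, training = FALSE) {
    d <- dim(x)
    xm <- x
    dim(xm) <- c(d[1], prod(d[-1]))
    e$x <- xm
    y <- e$params$W %*% xm + e$params$b
    dim(y) <- c(nrow(e$params$W), d[-1])
    y
  }
  e$backward <- function(dy) {
    d <- dim(dy)
    dym <- dy
    dim(dym) <- c(d[1], prod(d[-1]))
    e$grads <- list(W = tcrossprod(dym, e$x), b = rowSums(dym))
    dx <- crossprod(e$params$W, dym)
    dim(dx) <- c(ncol(e$params$W), d[-1])
    dx
  }
  e
}

softmaxRows <- function(S) {
  S <- S - apply(S, 1, max)
  E <- exp(S)
  E / rowSums(E)
}

newMultiHeadAttention <- function(D, heads) {
  e <- newLayer("mha")
  stopifnot(D %% heads == 0)
  dh <- D %/% heads
  sd0 <- 0.02
  mk <- function() matrix(stats::rnorm(D * D, 0, sd0), D, D)
  e$params <- list(Wq = mk(), Wk = mk(), Wv = mk(), Wo = mk(),
                   bq = numeric(D), bk = numeric(D), bv = numeric(D),
                   bo = numeric(D))
  e$meta <- list(D = D, heads = heads, dh = dh)
  e$forward <- function(x, training = FALSE) {
    d <- dim(x)                         # (D, T, N)
    D <- d[1]; T <- d[2]; N <- d[3]
    xm <- x; dim(xm) <- c(D, T * N)
    Q <- e$params$Wq %*% xm + e$params$bq
    K <- e$params$Wk %*% xm + e$params$bk
    V <- e$params$Wv %*% xm + e$params$bv
    O <- matrix(0, D, T * N)
    Ps <- vector("list", N * e$meta$heads)
    for (n in seq_len(N)) {
      cols <- (n - 1L) * T + seq_len(T)
      for (h in seq_len(e$meta$heads)) {
        rows <- (h - 1L) * e$meta$dh + seq_len(e$meta$dh)
        S <- crossprod(Q[rows, cols, drop = FALSE],
                       K[rows, cols, drop = FALSE]) / sqrt(e$meta$dh)
        P <- softmaxRows(S)
        Ps[[(n - 1L) * e$meta$heads + h]] <- P
        O[rows, cols] <- V[rows, cols, drop = FALSE] %*% t(P)
      }
    }
    Y <- e$params$Wo %*% O + e$params$bo
    e$cache <- list(xm = xm, Q = Q, K = K, V = V, O = O, Ps = Ps,
                    T = T, N = N)
    dim(Y) <- d
    Y
  }
  e$backward <- function(dy) {
    cc <- e$cache
    m <- e$meta
    d <- dim(dy)
    dym <- dy; dim(dym) <- c(m$D, cc$T * cc$N)
    gWo <- tcrossprod(dym, cc$O)
    gbo <- rowSums(dym)
    dO <- crossprod(e$params$Wo, dym)
    dQ <- matrix(0, m$D, cc$T * cc$N)
    dK <- matrix(0, m$D, cc$T * cc$N)
    dV <- matrix(0, m$D, cc$T * cc$N)
    for (n in seq_len(cc$N)) {
      cols <- (n - 1L) * cc$T + seq_len(cc$T)
      for (h in seq_len(m$heads)) {
        rows <- (h - 1L) * m$dh + seq_len(m$dh)
        P <- cc$Ps[[(n - 1L) * m$heads + h]]
        dOh <- dO[rows, cols, drop = FALSE]
        Vh <- cc$V[rows, cols, drop = FALSE]
        # O[, q] = sum_j P[q, j] V[, j]  =>  dP[q, j] = dO[, q] . V[, j]
        dP <- crossprod(dOh, Vh)
        dV[rows, cols] <- dOh %*% P
        # softmax backward per row
        dS <- P * (dP - rowSums(dP * P))
        dS <- dS / sqrt(m$dh)
        Qh <- cc$Q[rows, cols, drop = FALSE]
        Kh <- cc$K[rows, cols, drop = FALSE]
        dQ[rows, cols] <- Kh %*% t(dS)
        dK[rows, cols] <- Qh %*% dS
      }
    }
    e$grads <- list(Wq = tcrossprod(dQ, cc$xm), Wk = tcrossprod(dK, cc$xm),
                    Wv = tcrossprod(dV, cc$xm), Wo = gWo,
                    bq = rowSums(dQ), bk = rowSums(dK), bv = rowSums(dV),
                    bo = gbo)
    dx <- crossprod(e$params$Wq, dQ) + crossprod(e$params$Wk, dK) +
      crossprod(e$params$Wv, dV)
    dim(dx) <- d
    dx
  }
  e
}

newResidual <- function(inner) {
  e <- newLayer("residual")
  e$children <- list(inner)
  e$inner <- inner
  e$forward <- function(x, training = FALSE) x + e$inner$forward(x, training)
  e$backward <- function(dy) dy + e$inner$backward(dy)
  e
}

newTransformerBlock <- function(D, heads, mlpRatio = 4) {
  newSequential(
    newResidual(newSequential(newLayerNorm(D),
                              newMultiHeadAttention(D, heads))),
    newResidual(newSequential(newLayerNorm(D),
                              newTokenDense(D, D * mlpRatio), newGELU(),
                              newTokenDense(D * mlpRatio, D))))
}

# Patch embedding: image (H, W, C, N) -> tokens (D, T+1, N) with learned
# class token and positional embedding.
newPatchEmbed <- function(imgSize, patch, C, D) {
  e <- newLayer("patchembed")
  stopifnot(imgSize %% patch == 0)
  Tn <- (imgSize %/% patch)^2
  R <- patch * patch * C
  e$params <- list(W = matrix(stats::rnorm(D * R, 0, 0.02), D, R),
                   b = numeric(D),
                   cls = matrix(stats::rnorm(D, 0, 0.02), D, 1),
                   pos = matrix(stats::rnorm(D * (Tn + 1), 0, 0.02), D,
                                Tn + 1))
  e$meta <- list(imgSize = imgSize, patch = patch, C = C, D = D, Tn = Tn)
  e$forward <- function(x, training = FALSE) {
    m <- e$meta
    d <- dim(x)
    key <- paste(d, collapse = "x")
    if (is.null(e$idxKey) || e$idxKey != key) {
      ii <- im2colIndex(d[1], d[2], d[3], m$patch, m$patch, m$patch, 0L)
      off <- rep((seq_len(d[4]) - 1L) * ii$planeSize,
                 each = length(ii$idx))
      e$fullIdx <- as.vector(ii$idx) + off
      e$rows <- nrow(ii$idx)
      e$idxKey <- key
    }
    Xc <- x[e$fullIdx]
    dim(Xc) <- c(e$rows, m$Tn * d[4])
    e$Xc <- Xc
    E <- e$params$W %*% Xc + e$params$b          # (D, Tn*N)
    dim(E) <- c(m$D, m$Tn, d[4])
    out <- array(0, c(m$D, m$Tn + 1L, d[4]))
    out[, 1, ] <- matrix(e$params$cls, m$D, d[4])
    out[, -1, ] <- E
    out <- out + as.vector(e$params$pos)         # recycles over N
    e$N <- d[4]
    e$din <- d
    out
  }
  e$backward <- function(dy) {
    m <- e$meta
    N <- e$N
    gpos <- rowSums(array(dy, c(m$D * (m$Tn + 1L), N)))
    dim(gpos) <- c(m$D, m$Tn + 1L)
    gcls <- matrix(rowSums(matrix(dy[, 1, ], m$D, N)), m$D, 1)
    dE <- dy[, -1, , drop = FALSE]
    dim(dE) <- c(m$D, m$Tn * N)
    e$grads <- list(W = tcrossprod(dE, e$Xc), b = rowSums(dE),
                    cls = gcls, pos = gpos)
    dXc <- crossprod(e$params$W, dE)
    dx <- numeric(prod(e$din))
    dx[e$fullIdx] <- as.vector(dXc)              # patches do not overlap
    dim(dx) <- e$din
    dx
  }
  e
}

# Extract the class token: (D, T, N) -> (D, N).
newClsPool <- function() {
  e <- newLayer("clspool")
  e$forward <- function(x, training = FALSE) {
    e$d <- dim(x)
    x[, 1, ]
  }
  e$backward <- function(dy) {
    dx <- array(0, e$d)
    dx[, 1, ] <- dy
    dx
  }
  e
}

## ---- loss and optimizer ----

# Softmax cross-entropy on logits (K, N) with integer labels 1..K.
# Returns list(loss, probs, dlogits).
softmaxCrossEntropy <- function(logits, labels) {
  K <- nrow(logits); N <- ncol(logits)
  z <- sweep(logits, 2, apply(logits, 2, max))
  ez <- exp(z)
  p <- sweep(ez, 2, colSums(ez), `/`)
  picked <- p[cbind(labels, seq_len(N))]
  loss <- -mean(log(pmax(picked, 1e-12)))
  d <- p
  d[cbind(labels, seq_len(N))] <- d[cbind(labels, seq_len(N))] - 1
  list(loss = loss, probs = p, dlogits = d / N)
}

# Decoupled-weight-decay Adam over all parameter-owning layers.
newAdamW <- function(layers, lr = 5e-5, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8, weightDecay = 1e-2) {
  st <- new.env(parent = emptyenv())
  st$t <- 0L
  st$m <- lapply(layers, function(l) lapply(l$params, function(p) p * 0))
  st$v <- st$m
  list(
    step = function() {
      st$t <- st$t + 1L
      b1t <- 1 - beta1^st$t
      b2t <- 1 - beta2^st$t
      for (i in seq_along(layers)) {
        l <- layers[[i]]
        for (nm in names(l$params)) {
          g <- l$grads[[nm]]
          if (is.null(g)) next
          st$m[[i]][[nm]] <- beta1 * st$m[[i]][[nm]] + (1 - beta1) * g
          st$v[[i]][[nm]] <- beta2 * st$v[[i]][[nm]] + (1 - beta2) * g^2
          mh <- st$m[[i]][[nm]] / b1t
          vh <- st$v[[i]][[nm]] / b2t
          decay <- if (nm %in% c("W", "Wq", "Wk", "Wv", "Wo"))
            weightDecay else 0
          l$params[[nm]] <- l$params[[nm]] -
            lr * (mh / (sqrt(vh) + eps) + decay * l$params[[nm]])
        }
      }
    })
}

# Deep-copy / restore parameter values and normalization statistics (for
# best-epoch checkpointing).
snapshotParams <- function(layers) {
  lapply(layers, function(l)
    list(params = l$params, runMean = l$runMean, runVar = l$runVar))
}

restoreParams <- function(layers, snap) {
  for (i in seq_along(layers)) {
    layers[[i]]$params <- snap[[i]]$params
    if (!is.null(snap[[i]]$runMean)) {
      layers[[i]]$runMean <- snap[[i]]$runMean
      layers[[i]]$runVar <- snap[[i]]$runVar
    }
  }
  invisible(NULL)
}
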