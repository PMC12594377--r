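# Reverse-mode automatic differentiation on matrices.
#
# The networks in this package (Bi-LSTM encoders, attention-GCN, gated fusion,
# MFM) are trained with gradients computed by a small tape-based reverse-mode
# engine. Values are dense base-R matrices (BLAS-backed); every operation
# records a node with a backward closure while a tape is active. With no tape
# active the same operations run value-only, which is what evaluation-mode
# forward passes use.
#
# All of this is internal; nothing here is exported.

.ad <- new.env(parent = emptyenv())
.ad$tape <- NULL

ad_begin <- function() {
  t <- new.env(parent = emptyenv())
  t$head <- NULL   # linked list of recorded nodes, most recent first
  .ad$tape <- t
  invisible(t)
}

ad_end <- function() {
  .ad$tape <- NULL
  invisible(NULL)
}

ad_active <- function() !is.null(.ad$tape)

# leaf holding a constant (no gradient is accumulated into it)
ad_const <- function(v) {
  nd <- new.env(parent = emptyenv())
  nd$v <- v
  nd$g <- NULL
  nd$k <- TRUE
  nd
}

# leaf holding a trainable parameter
ad_leaf <- function(v) {
  nd <- new.env(parent = emptyenv())
  nd$v <- v
  nd$g <- NULL
  nd$k <- FALSE
  nd
}

ad_op <- function(v, bk) {
  nd <- new.env(parent = emptyenv())
  nd$v <- v
  nd$g <- NULL
  nd$k <- FALSE
  t <- .ad$tape
  if (!is.null(t)) {
    nd$bk <- bk
    t$head <- list(nd = nd, prev = t$head)
  }
  nd
}

ad_acc <- function(nd, g) {
  if (isTRUE(nd$k)) return(invisible(NULL))
  nd$g <- if (is.null(nd$g)) g else nd$g + g
  invisible(NULL)
}

# seed the root gradient and sweep the tape in reverse
ad_backward <- function(root, seed = 1) {
  t <- .ad$tape
  if (is.null(t)) stop("ad_backward() called with no active tape")
  root$g <- seed
  p <- t$head
  while (!is.null(p)) {
    nd <- p$nd
    if (!is.null(nd$g)) nd$bk(nd$g)
    p <- p$prev
  }
  invisible(NULL)
}

# ---- elementary operations -------------------------------------------------

ad_mm <- function(a, b) {
  av <- a$v; bv <- b$v
  ad_op(av %*% bv, function(g) {
    ad_acc(a, g %*% t(bv))
    ad_acc(b, crossprod(av, g))
  })
}

ad_add <- function(a, b) {
  ad_op(a$v + b$v, function(g) {
    ad_acc(a, g)
    ad_acc(b, g)
  })
}

ad_sub <- function(a, b) {
  ad_op(a$v - b$v, function(g) {
    ad_acc(a, g)
    ad_acc(b, -g)
  })
}

ad_hadamard <- function(a, b) {
  av <- a$v; bv <- b$v
  ad_op(av * bv, function(g) {
    ad_acc(a, g * bv)
    ad_acc(b, g * av)
  })
}

# x: n x f matrix node, b: length-f numeric parameter (bias row broadcast)
ad_add_bias <- function(x, b) {
  n <- nrow(x$v)
  ad_op(x$v + rep(b$v, each = n), function(g) {
    ad_acc(x, g)
    ad_acc(b, colSums(g))
  })
}

ad_scale <- function(x, k) {
  ad_op(x$v * k, function(g) ad_acc(x, g * k))
}

ad_sigmoid <- function(x) {
  s <- 1 / (1 + exp(-x$v))
  ad_op(s, function(g) ad_acc(x, g * s * (1 - s)))
}

ad_tanh <- function(x) {
  h <- tanh(x$v)
  ad_op(h, function(g) ad_acc(x, g * (1 - h * h)))
}

ad_one_minus <- function(x) {
  ad_op(1 - x$v, function(g) ad_acc(x, -g))
}

ad_relu <- function(x) {
  m <- x$v > 0
  ad_op(x$v * m, function(g) ad_acc(x, g * m))
}

ad_cols <- function(x, idx) {
  nr <- nrow(x$v); nc <- ncol(x$v)
  ad_op(x$v[, idx, drop = FALSE], function(g) {
    z <- matrix(0, nr, nc)
    z[, idx] <- g
    ad_acc(x, z)
  })
}

ad_rows <- function(x, idx) {
  nr <- nrow(x$v); nc <- ncol(x$v)
  ad_op(x$v[idx, , drop = FALSE], function(g) {
    z <- matrix(0, nr, nc)
    z[idx, ] <- g
    ad_acc(x, z)
  })
}

ad_cbind <- function(xs) {
  widths <- vapply(xs, function(x) ncol(x$v), integer(1))
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  ad_op(do.call(cbind, lapply(xs, function(x) x$v)), function(g) {
    for (i in seq_along(xs)) ad_acc(xs[[i]], g[, starts[i]:ends[i], drop = FALSE])
  })
}

ad_rbind <- function(xs) {
  heights <- vapply(xs, function(x) nrow(x$v), integer(1))
  ends <- cumsum(heights)
  starts <- ends - heights + 1L
  ad_op(do.call(rbind, lapply(xs, function(x) x$v)), function(g) {
    for (i in seq_along(xs)) ad_acc(xs[[i]], g[starts[i]:ends[i], , drop = FALSE])
  })
}

# column-major reshape (free re-layout); inverse is the same reshape back
ad_reshape <- function(x, nrow_out) {
  nr <- nrow(x$v)
  ad_op(matrix(as.vector(x$v), nrow = nrow_out), function(g) {
    ad_acc(x, matrix(as.vector(g), nrow = nr))
  })
}

ad_softmax_rows <- function(x) {
  v <- x$v - apply(x$v, 1L, max)
  e <- exp(v)
  s <- e / rowSums(e)
  ad_op(s, function(g) {
    ad_acc(x, s * (g - rowSums(g * s)))
  })
}

# multiply every row of x (n x f) by the matching entry of w (n x 1 node)
ad_scale_rows <- function(x, w) {
  wv <- as.vector(w$v)
  xv <- x$v
  ad_op(xv * wv, function(g) {
    ad_acc(x, g * wv)
    ad_acc(w, matrix(rowSums(g * xv), ncol = 1L))
  })
}

# multiply every column of x (n x f) by the matching entry of w (length-f node)
ad_scale_cols <- function(x, w) {
  n <- nrow(x$v)
  wr <- rep(w$v, each = n)
  xv <- x$v
  ad_op(xv * wr, function(g) {
    ad_acc(x, g * wr)
    ad_acc(w, colSums(g * xv))
  })
}

# row-wise inner product of two n x f nodes -> n x 1
ad_rowdot <- function(a, b) {
  av <- a$v; bv <- b$v
  ad_op(matrix(rowSums(av * bv), ncol = 1L), function(g) {
    gv <- as.vector(g)
    ad_acc(a, bv * gv)
    ad_acc(b, av * gv)
  })
}

# Graph-signal multiply for node-major layout.
# x is (S*J) x F with row index (j-1)*S + s; A is a J x J (constant) matrix;
# output row ((i-1)*S + s, f) = sum_j A[i, j] * x[(j-1)*S + s, f].
ad_adj_mul <- function(x, A) {
  J <- nrow(A)
  SJ <- nrow(x$v)
  S <- SJ %/% J
  f_apply <- function(m, M) {
    # m: (S*J) x F; per feature block multiply by t(M)
    wide <- matrix(as.vector(m), nrow = S)        # S x (J*F), col (f-1)*J + j
    Fb <- ncol(wide) %/% J
    out <- wide
    for (f in seq_len(Fb)) {
      cols <- ((f - 1L) * J + 1L):(f * J)
      out[, cols] <- wide[, cols, drop = FALSE] %*% t(M)
    }
    matrix(as.vector(out), nrow = SJ)
  }
  ad_op(f_apply(x$v, A), function(g) {
    ad_acc(x, f_apply(g, t(A)))
  })
}

# mean over the time axis of a frame matrix ((B*T) x F, row (t-1)*B + b) -> B x F
ad_time_mean <- function(x, B, T) {
  Fw <- ncol(x$v)
  v <- matrix(0, B, Fw)
  for (f in seq_len(Fw)) v[, f] <- rowMeans(matrix(x$v[, f], nrow = B))
  ad_op(v, function(g) {
    ad_acc(x, g[rep(seq_len(B), T), , drop = FALSE] / T)
  })
}

# tile a B x F node to the frame-matrix layout (B*T) x F
ad_tile_rows <- function(m, T) {
  B <- nrow(m$v)
  idx <- rep(seq_len(B), T)
  ad_op(m$v[idx, , drop = FALSE], function(g) {
    ad_acc(m, rowsum(g, idx))
  })
}

ad_dropout <- function(x, mask) {
  ad_op(x$v * mask, function(g) ad_acc(x, g * mask))
}

# root-mean-square error over all elements; the training loss of every model
ad_rmse <- function(a, b) {
  d <- a$v - b$v
  n <- length(d)
  L <- sqrt(mean(d * d))
  ad_op(L, function(g) {
    if (L > 0) {
      s <- g / (n * L)
      ad_acc(a, d * s)
      ad_acc(b, -d * s)
    }
  })
}

# weighted sum of scalar nodes: sum(w_i * x_i)
ad_scalar_sum <- function(xs, w = rep(1, length(xs))) {
  v <- 0
  for (i in seq_along(xs)) v <- v + w[i] * xs[[i]]$v
  ad_op(v, function(g) {
    for (i in seq_along(xs)) ad_acc(xs[[i]], g * w[i])
  })
}

# One LSTM direction over a frame matrix as a single tape node, with
# hand-written backpropagation through time. x is (B*T) x F (row index
# (t-1)*B + b); Wx (F x 4H), Wh (H x 4H), b (4H); gate order i, f, g, o.
# Returns the (B*T) x H frame matrix of hidden states (in forward time
# order regardless of direction).
ad_lstm_dir <- function(x, Wx, Wh, b, B, T, reverse = FALSE) {
  H <- nrow(Wh$v)
  xv <- x$v
  n <- nrow(xv)
  XW <- xv %*% Wx$v + rep(b$v, each = n)
  times <- if (reverse) rev(seq_len(T)) else seq_len(T)
  Whv <- Wh$v
  GI <- vector("list", T); GF <- GI; GG <- GI; GO <- GI
  TC <- GI; CP <- GI; HP <- GI
  out <- matrix(0, n, H)
  h <- matrix(0, B, H); cv <- h
  for (step in seq_len(T)) {
    tt <- times[step]
    rows <- ((tt - 1L) * B + 1L):(tt * B)
    pre <- XW[rows, , drop = FALSE]
    if (step > 1L) pre <- pre + h %*% Whv
    gi <- 1 / (1 + exp(-pre[, 1:H, drop = FALSE]))
    gf <- 1 / (1 + exp(-pre[, (H + 1L):(2L * H), drop = FALSE]))
    gg <- tanh(pre[, (2L * H + 1L):(3L * H), drop = FALSE])
    go <- 1 / (1 + exp(-pre[, (3L * H + 1L):(4L * H), drop = FALSE]))
    CP[[step]] <- cv
    HP[[step]] <- h
    cv <- gf * cv + gi * gg
    tc <- tanh(cv)
    h <- go * tc
    GI[[step]] <- gi; GF[[step]] <- gf; GG[[step]] <- gg; GO[[step]] <- go
    TC[[step]] <- tc
    out[rows, ] <- h
  }
  ad_op(out, function(g) {
    dXW <- matrix(0, n, 4L * H)
    dh_rec <- matrix(0, B, H)
    dc <- matrix(0, B, H)
    dWh <- matrix(0, H, 4L * H)
    for (step in T:1L) {
      tt <- times[step]
      rows <- ((tt - 1L) * B + 1L):(tt * B)
      dh <- g[rows, , drop = FALSE] + dh_rec
      gi <- GI[[step]]; gf <- GF[[step]]; gg <- GG[[step]]
      go <- GO[[step]]; tc <- TC[[step]]; cp <- CP[[step]]
      dct <- dc + dh * go * (1 - tc * tc)
      dpre <- cbind(dct * gg * gi * (1 - gi),
                    dct * cp * gf * (1 - gf),
                    dct * gi * (1 - gg * gg),
                    dh * tc * go * (1 - go))
      dXW[rows, ] <- dpre
      if (step > 1L) {
        dh_rec <- dpre %*% t(Whv)
        dWh <- dWh + crossprod(HP[[step]], dpre)
      }
      dc <- dct * gf
    }
    ad_acc(Wh, dWh)
    ad_acc(Wx, crossprod(xv, dXW))
    ad_acc(b, colSums(dXW))
    ad_acc(x, dXW %*% t(Wx$v))
  })
}

# Batch normalization over rows (batch x time) per column (channel).
# Training mode: batch statistics, with the state's running statistics updated
# as a side effect. Evaluation mode: frozen running statistics.
# state: environment with $mu, $va (running mean / variance), $momentum.
ad_batchnorm <- function(x, gamma, beta, state, training, eps = 1e-5) {
  n <- nrow(x$v)
  if (training) {
    mu <- colMeans(x$v)
    xc <- x$v - rep(mu, each = n)
    va <- colMeans(xc * xc)
    if (any(va < eps)) va <- pmax(va, eps)   # zero-variance channels clamped
    state$mu <- (1 - state$momentum) * state$mu + state$momentum * mu
    state$va <- (1 - state$momentum) * state$va + state$momentum * va
    inv_sd <- 1 / sqrt(va + eps)
    xh <- xc * rep(inv_sd, each = n)
    v <- xh * rep(gamma$v, each = n) + rep(beta$v, each = n)
    ad_op(v, function(g) {
      ad_acc(gamma, colSums(g * xh))
      ad_acc(beta, colSums(g))
      dxh <- g * rep(gamma$v, each = n)
      t1 <- rep(colMeans(dxh), each = n)
      t2 <- xh * rep(colMeans(dxh * xh), each = n)
      ad_acc(x, (dxh - t1 - t2) * rep(inv_sd, each = n))
    })
  } else {
    inv_sd <- 1 / sqrt(state$va + eps)
    sc <- gamma$v * inv_sd
    sh <- beta$v - state$mu * sc
    v <- x$v * rep(sc, each = n) + rep(sh, each = n)
    ad_op(v, function(g) {
      ad_acc(x, g * rep(sc, each = n))
      ad_acc(gamma, colSums(g * (x$v - rep(state$mu, each = n)) * rep(inv_sd, each = n)))
      ad_acc(beta, colSums(g))
    })
  }
}
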