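# Network building blocks: parameter initialisation, Bi-LSTM encoders,
# node attention, graph convolution, gated fusion and the multi-fusion
# module (MFM). All layers operate on "frame matrices": a [B x dT x F]
# window batch stored as a (B*dT) x F matrix whose row index is
# (t-1)*B + b, so the rows of time step t form one contiguous block.

par_mat <- function(nr, nc) {
  k <- 1 / sqrt(nr)
  ad_leaf(matrix(stats::runif(nr * nc, -k, k), nr, nc))
}

par_vec <- function(n, value = 0) ad_leaf(rep(value, n))

new_bn_state <- function(width) {
  st <- new.env(parent = emptyenv())
  st$mu <- rep(0, width)
  st$va <- rep(1, width)
  st$momentum <- 0.1
  st
}

make_linear <- function(fin, fout) {
  list(W = par_mat(fin, fout), b = par_vec(fout))
}

linear_fwd <- function(lay, x) ad_add_bias(ad_mm(x, lay$W), lay$b)

make_bn <- function(width) {
  list(gamma = par_vec(width, 1), beta = par_vec(width), state = new_bn_state(width))
}

bn_fwd <- function(lay, x, training) {
  ad_batchnorm(x, lay$gamma, lay$beta, lay$state, training)
}

# ---- LSTM ------------------------------------------------------------------

# One direction of one LSTM layer. Gate order i, f, g, o; forget-gate bias
# initialised to 1 (standard practice for gradient flow early in training).
make_lstm_dir <- function(fin, H) {
  b <- par_vec(4 * H)
  b$v[(H + 1):(2 * H)] <- 1
  list(Wx = par_mat(fin, 4 * H), Wh = par_mat(H, 4 * H), b = b, H = H)
}

run_lstm_dir <- function(lay, x, B, T, reverse = FALSE) {
  ad_lstm_dir(x, lay$Wx, lay$Wh, lay$b, B, T, reverse = reverse)
}

# Two stacked bidirectional layers; dropout after each layer during training.
make_bilstm <- function(fin, C, nlayers = 2, dropout = 0.2) {
  stopifnot(C %% 2 == 0)
  H <- C %/% 2
  layers <- vector("list", nlayers)
  fi <- fin
  for (l in seq_len(nlayers)) {
    layers[[l]] <- list(fwd = make_lstm_dir(fi, H), bwd = make_lstm_dir(fi, H))
    fi <- C
  }
  list(layers = layers, C = C, dropout = dropout)
}

bilstm_fwd <- function(enc, x, B, T, training) {
  out <- x
  for (l in seq_along(enc$layers)) {
    lay <- enc$layers[[l]]
    out <- ad_cbind(list(
      run_lstm_dir(lay$fwd, out, B, T, reverse = FALSE),
      run_lstm_dir(lay$bwd, out, B, T, reverse = TRUE)
    ))
    if (training && enc$dropout > 0) {
      keep <- 1 - enc$dropout
      mask <- matrix((stats::runif(length(out$v)) < keep) / keep, nrow(out$v), ncol(out$v))
      out <- ad_dropout(out, mask)
    }
  }
  out
}

# ---- attention over skeleton nodes -----------------------------------------

# x_nodes: (S*J) x Fn node-major matrix, row index (j-1)*S + s.
# A shared per-node linear score is softmax-normalized over the J nodes of
# each frame, then broadcast-multiplied onto the node features.
make_node_attention <- function(fn) {
  list(w = par_mat(fn, 1), b = par_vec(1))
}

node_attention_fwd <- function(lay, x_nodes, S, J) {
  score <- ad_add_bias(ad_mm(x_nodes, lay$w), lay$b)   # (S*J) x 1
  wide <- ad_reshape(score, S)                          # S x J
  attn <- ad_softmax_rows(wide)
  wcol <- ad_reshape(attn, S * J)                       # (S*J) x 1
  list(weights = attn, attended = ad_scale_rows(x_nodes, wcol))
}

# ---- graph convolution -----------------------------------------------------

# ReLU(A V W + b) with a shared node-feature transform, followed by a
# fully connected projection of the flattened node features to width C.
make_gcn <- function(fn, node_out, J, C) {
  list(
    W = par_mat(fn, node_out), b = par_vec(node_out),
    proj = make_linear(J * node_out, C),
    node_out = node_out, J = J
  )
}

gcn_fwd <- function(lay, x_nodes, A, S) {
  conv <- ad_relu(ad_add_bias(ad_mm(ad_adj_mul(x_nodes, A), lay$W), lay$b))
  wide <- ad_reshape(conv, S)                           # S x (J * node_out)
  linear_fwd(lay$proj, wide)                            # S x C
}

# ---- gated fusion ----------------------------------------------------------

make_gate <- function(width) {
  list(fc = make_linear(2 * width, width))
}

gate_fwd <- function(lay, x_bilstm, x_gcn) {
  w <- ad_sigmoid(linear_fwd(lay$fc, ad_cbind(list(x_bilstm, x_gcn))))
  fused <- ad_add(ad_hadamard(w, x_bilstm), ad_hadamard(ad_one_minus(w), x_gcn))
  list(gate = w, fused = fused)
}

# ---- multi-fusion module ---------------------------------------------------

# Composite of four fusion submodules applied to a fused feature stream of
# width 3C (three C-wide modality blocks). The module output is the input
# plus the sum of the selected submodule outputs, so any subset of
# submodules preserves the feature width and the empty set is the identity.
#
#  LWF  - learned per-channel (sigmoid) reweighting of the fused features.
#  WFF  - per-frame softmax weights over the three modality blocks.
#  MHAF - scaled dot-product attention across the three modality blocks.
#  TMF  - temporal-context gate from the window-mean features.
make_mfm <- function(width, submodules, attn_dim = NULL) {
  stopifnot(width %% 3 == 0)
  C <- width %/% 3
  if (is.null(attn_dim)) attn_dim <- max(4L, C %/% 4L)
  subs <- list()
  if ("LWF" %in% submodules) subs$LWF <- list(w = par_vec(width))
  if ("WFF" %in% submodules) subs$WFF <- list(fc = make_linear(width, 3))
  if ("MHAF" %in% submodules) {
    subs$MHAF <- list(Wq = par_mat(C, attn_dim), Wk = par_mat(C, attn_dim),
                      Wv = par_mat(C, C), d = attn_dim)
  }
  if ("TMF" %in% submodules) subs$TMF <- list(fc = make_linear(2 * width, width))
  list(subs = subs, width = width, C = C)
}

mfm_fwd <- function(lay, x, B, T) {
  if (length(lay$subs) == 0) return(x)
  C <- lay$C
  blocks_idx <- lapply(0:2, function(m) (m * C + 1L):((m + 1L) * C))
  out <- x
  for (nm in names(lay$subs)) {
    sub <- lay$subs[[nm]]
    y <- switch(nm,
      LWF = ad_scale_cols(x, ad_sigmoid(sub$w)),
      WFF = {
        sw <- ad_softmax_rows(linear_fwd(sub$fc, x))   # S x 3
        parts <- lapply(1:3, function(m) {
          ad_scale(ad_scale_rows(ad_cols(x, blocks_idx[[m]]), ad_cols(sw, m)), 3)
        })
        ad_cbind(parts)
      },
      MHAF = {
        blocks <- lapply(blocks_idx, function(ix) ad_cols(x, ix))
        Q <- lapply(blocks, function(bk) ad_mm(bk, sub$Wq))
        K <- lapply(blocks, function(bk) ad_mm(bk, sub$Wk))
        V <- lapply(blocks, function(bk) ad_mm(bk, sub$Wv))
        sc <- 1 / sqrt(sub$d)
        outs <- lapply(1:3, function(m) {
          scores <- ad_cbind(lapply(1:3, function(n) ad_scale(ad_rowdot(Q[[m]], K[[n]]), sc)))
          aw <- ad_softmax_rows(scores)                 # S x 3
          acc <- NULL
          for (n in 1:3) {
            term <- ad_scale_rows(V[[n]], ad_cols(aw, n))
            acc <- if (is.null(acc)) term else ad_add(acc, term)
          }
          acc
        })
        ad_cbind(outs)
      },
      TMF = {
        ctx <- ad_tile_rows(ad_time_mean(x, B, T), T)
        gate <- ad_sigmoid(linear_fwd(sub$fc, ad_cbind(list(x, ctx))))
        ad_hadamard(x, gate)
      }
    )
    out <- ad_add(out, y)
  }
  out
}

# collect every ad_leaf parameter in a (nested) layer structure
collect_params <- function(x, prefix = "") {
  if (is.environment(x)) {
    if (!is.null(x$v) && is.null(x$momentum)) {
      out <- list(x)
      names(out) <- prefix
      return(out)
    }
    return(list())
  }
  if (is.list(x)) {
    out <- list()
    nms <- names(x)
    for (i in seq_along(x)) {
      if (is.null(x[[i]])) next
      nm <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else as.character(i)
      child <- collect_params(x[[i]], paste0(prefix, if (nzchar(prefix)) "." else "", nm))
      out <- c(out, child)
    }
    return(out)
  }
  list()
}

# collect every batch-normalization state environment
collect_bn_states <- function(x, prefix = "") {
  if (is.environment(x)) {
    if (!is.null(x$momentum)) {
      out <- list(x)
      names(out) <- prefix
      return(out)
    }
    return(list())
  }
  if (is.list(x)) {
    out <- list()
    nms <- names(x)
    for (i in seq_along(x)) {
      if (is.null(x[[i]])) next
      nm <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else as.character(i)
      out <- c(out, collect_bn_states(x[[i]], paste0(prefix, if (nzchar(prefix)) "." else "", nm)))
    }
    return(out)
  }
  list()
}
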