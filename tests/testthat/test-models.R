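# Architecture invariants of the student and teacher networks.

ns <- asNamespace("gaitkt")

test_that("forward passes produce framewise 5-component predictions", {
  w <- tiny_windows()
  for (variant in c("aug_mfm_gate_bilstm_attngcn", "imu_jcp_mfm",
                    "joint_pos_bilstm", "aug_concat_attngcn")) {
    m <- gait_model(variant, tiny_model_config())
    b <- tiny_batch(m, w, idx = 1:3)
    out <- ns$model_forward(m, b, training = FALSE)
    expect_identical(dim(out$pred$v), c(3L * 50L, 5L))
    # identical windows in one batch give identical predictions
    b2 <- tiny_batch(m, w, idx = c(1, 1, 2))
    p2 <- ns$model_forward(m, b2, training = FALSE)$pred$v
    arr <- array(p2, c(3, 50, 5))
    expect_equal(arr[1, , ], arr[2, , ])
    # and evaluation-mode forwards are deterministic
    expect_identical(out$pred$v, ns$model_forward(m, b, training = FALSE)$pred$v)
  }
})

test_that("attention weights are a distribution over the 11 joints", {
  m <- gait_model("aug_mfm_gate_bilstm_attngcn", tiny_model_config(seed = 3))
  b <- tiny_batch(m, idx = 1:4)
  out <- ns$model_forward(m, b, training = FALSE)
  for (aw in out$extras$attn_weights) {
    expect_identical(ncol(aw$v), 11L)
    expect_true(all(aw$v >= 0))
    expect_lt(max(abs(rowSums(aw$v) - 1)), 1e-6)
  }
  # equal scores give the uniform 1/11 weight
  at <- ns$make_node_attention(4)
  at$w$v[] <- 0; at$b$v[] <- 0
  x <- ns$ad_const(matrix(rnorm(11 * 6 * 4), 66, 4))
  res <- ns$node_attention_fwd(at, x, 6, 11)
  expect_equal(res$weights$v, matrix(1 / 11, 6, 11))
  # zero features are annihilated regardless of the weights
  x0 <- ns$ad_const(matrix(0, 66, 4))
  expect_true(all(ns$node_attention_fwd(at, x0, 6, 11)$attended$v == 0))
})

test_that("the gate is a strict convex combination of its branches", {
  m <- gait_model("aug_mfm_gate_bilstm_attngcn", tiny_model_config(seed = 4))
  b <- tiny_batch(m, idx = 1:4)
  out <- ns$model_forward(m, b, training = FALSE)
  g <- out$extras$gate$v
  expect_true(all(g > 0 & g < 1))

  gate <- ns$make_gate(6)
  set.seed(5)
  x <- ns$ad_const(matrix(rnorm(60), 10, 6))
  y <- ns$ad_const(matrix(rnorm(60), 10, 6))
  # equal branches pass through unchanged for any gate values
  same <- ns$gate_fwd(gate, x, x)
  expect_equal(same$fused$v, x$v, tolerance = 1e-12)
  # saturated gate reproduces the first branch
  gate$fc$W$v[] <- 0
  gate$fc$b$v[] <- 20
  sat <- ns$gate_fwd(gate, x, y)
  expect_lt(max(abs(sat$fused$v - x$v)), 1e-6)
})

test_that("the graph convolution matches hand arithmetic on a two-node toy", {
  A <- matrix(c(0.7, 0.3, 0.4, 0.6), 2, 2, byrow = TRUE)
  W <- matrix(c(1, -1, 0.5, 2), 2, 2)
  bb <- c(0.1, -0.2)
  V <- matrix(c(1, 2, -1, 0.5, 3, -2, 0.25, 1), 4, 2)  # 2 samples x 2 nodes
  lay <- list(W = ns$ad_leaf(W), b = ns$ad_leaf(bb))
  conv <- ns$ad_relu(ns$ad_add_bias(ns$ad_mm(ns$ad_adj_mul(ns$ad_const(V), A),
                                             lay$W), lay$b))
  # oracle: per sample s, ReLU(A V_s W + b) with V_s the 2 x 2 node block
  for (s in 1:2) {
    Vs <- V[c(s, s + 2), ]
    expect_equal(conv$v[c(s, s + 2), ],
                 pmax(A %*% Vs %*% W + rep(bb, each = 2), 0),
                 ignore_attr = TRUE)
  }
  expect_true(all(conv$v >= 0))
})

test_that("the full graph branch equals a brute-force per-frame loop", {
  cfg <- tiny_model_config(seed = 6)
  m <- gait_model("aug_concat_attngcn", cfg)
  b <- tiny_batch(m, idx = 1:2)
  out <- ns$model_forward(m, b, training = FALSE)
  # brute force for the velocity modality: bn -> attention -> A V W -> relu
  lay_bn <- m$layers$bn$vel
  at <- m$layers$attn$vel
  gc <- m$layers$gcn$vel
  x <- b$vel
  S <- nrow(x)
  sc <- lay_bn$gamma$v / sqrt(lay_bn$state$va + 1e-5)
  xn <- sweep(sweep(x, 2, lay_bn$state$mu), 2, sc, "*")
  xn <- sweep(xn, 2, lay_bn$beta$v, "+")
  pred_block <- matrix(0, S, 11 * cfg$gcn_node_out)
  for (s in seq_len(S)) {
    Vs <- matrix(xn[s, ], 11, 4)          # joints x (cam coords)
    score <- Vs %*% at$w$v + at$b$v
    wgt <- exp(score - max(score)); wgt <- wgt / sum(wgt)
    Va <- Vs * as.vector(wgt)
    H <- pmax(m$A %*% Va %*% gc$W$v + rep(gc$b$v, each = 11), 0)
    pred_block[s, ] <- as.vector(H)
  }
  proj <- pred_block %*% gc$proj$W$v + rep(gc$proj$b$v, each = S)
  # the velocity modality occupies the first C columns of the GCN concat
  enc <- ns$model_encode(m, b, training = FALSE)
  expect_equal(enc$features$v[, 1:cfg$hidden_dim], proj, tolerance = 1e-10)
})

test_that("the multi-fusion module keeps width and supports all subsets", {
  set.seed(7)
  B <- 2; T <- 5; w3 <- 12
  x <- ns$ad_const(matrix(rnorm(B * T * w3), B * T, w3))
  # empty subset is the identity (concat fallback)
  mfm0 <- ns$make_mfm(w3, character(0))
  expect_identical(ns$mfm_fwd(mfm0, x, B, T)$v, x$v)
  for (sub in c("LWF", "WFF", "MHAF", "TMF")) {
    mfm <- ns$make_mfm(w3, sub)
    y <- ns$mfm_fwd(mfm, x, B, T)
    expect_identical(dim(y$v), dim(x$v))
    expect_identical(ns$mfm_fwd(mfm, x, B, T)$v, y$v)  # deterministic
  }
  full <- ns$make_mfm(w3, c("LWF", "WFF", "MHAF", "TMF"))
  expect_identical(dim(ns$mfm_fwd(full, x, B, T)$v), dim(x$v))
  # the config layer rejects an empty submodule set under mfm_gate fusion
  expect_error(model_config(fusion = "mfm_gate", mfm_submodules = character(0)),
               "non-empty")
})

test_that("batch normalization standardizes and freezes correctly", {
  set.seed(8)
  bn <- ns$make_bn(3)
  x <- matrix(rnorm(3000, 5, 2), 1000, 3)
  y <- ns$bn_fwd(bn, ns$ad_const(x), training = TRUE)$v
  expect_lt(max(abs(colMeans(y))), 0.05)
  expect_lt(max(abs(apply(y, 2, sd) - 1)), 0.05)
  # constant channel: clamped variance, finite output
  xc <- x; xc[, 2] <- 3
  yc <- ns$bn_fwd(bn, ns$ad_const(xc), training = TRUE)$v
  expect_true(all(is.finite(yc)))
  # evaluation mode with the stored statistics reproduces the training
  # transform of the same batch up to the running-average warm-up
  bn2 <- ns$make_bn(3)
  bn2$state$momentum <- 1   # running stats = last batch stats
  yt <- ns$bn_fwd(bn2, ns$ad_const(x), training = TRUE)$v
  ye <- ns$bn_fwd(bn2, ns$ad_const(x), training = FALSE)$v
  expect_equal(ye, yt, tolerance = 1e-6)
})

test_that("Bi-LSTM encoders respect batch structure and are direction-sensitive", {
  set.seed(9)
  enc <- ns$make_bilstm(6, 8, nlayers = 2, dropout = 0)
  B <- 4; T <- 10
  x <- matrix(rnorm(B * T * 6), B * T, 6)
  y <- ns$bilstm_fwd(enc, ns$ad_const(x), B, T, FALSE)$v
  expect_identical(dim(y), as.integer(c(B * T, 8)))
  # permuting the batch permutes the outputs identically
  perm <- c(3, 1, 4, 2)
  idx <- as.vector(outer(perm, (0:(T - 1)) * B, "+"))
  yp <- ns$bilstm_fwd(enc, ns$ad_const(x[idx, ]), B, T, FALSE)$v
  expect_equal(yp, y[idx, ], tolerance = 1e-12)
  # time reversal changes the output (both directions are live)
  rev_idx <- as.vector(outer(1:B, ((T - 1):0) * B, "+"))
  yr <- ns$bilstm_fwd(enc, ns$ad_const(x[rev_idx, ]), B, T, FALSE)$v
  expect_gt(max(abs(yr[rev_idx, ] - y)), 1e-4)
})

test_that("the variant factory builds the documented input rosters", {
  cfg <- tiny_model_config()
  jp <- gait_model("joint_pos_bilstm", cfg)
  expect_identical(nrow(jp$layers$bilstm$pos$layers[[1]]$fwd$Wx$v), 44L)
  ef <- gait_model("aug_early_fusion_bilstm", cfg)
  expect_identical(nrow(ef$layers$bilstm$kin$layers[[1]]$fwd$Wx$v), 132L)
  ief <- gait_model("imu_jcp_early_fusion", cfg)
  expect_identical(nrow(ief$layers$bilstm$all$layers[[1]]$fwd$Wx$v), 92L)
  # the imu_jcp_mfm variant is the teacher architecture
  tv <- gait_model("imu_jcp_mfm", cfg)
  expect_identical(tv$spec, ns$variant_spec("imu_jcp_mfm"))
  expect_identical(sort(names(tv$spec$modalities)), c("imu_acc", "imu_gyr", "pos"))
  expect_null(tv$layers$head$hidden)   # teacher head is a single linear map
  expect_error(gait_model("no_such_model", cfg), "unknown")
  expect_length(student_variants(), 8L)
  expect_length(teacher_variants(), 4L)
})
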