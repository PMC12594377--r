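#' Model configuration
#'
#' Hyperparameters shared by the student and teacher architectures. The
#' window length is fixed at 50 frames (0.5 s at 100 Hz) throughout the
#' package.
#'
#' @param hidden_dim Feature width \eqn{C} produced by each modality encoder
#'   (must be even; the two Bi-LSTM directions contribute \eqn{C/2} each).
#' @param bilstm_layers Number of stacked bidirectional LSTM layers.
#' @param dropout Dropout probability applied after each Bi-LSTM layer
#'   during training.
#' @param gcn_node_out Node-feature width \eqn{M'} produced by the graph
#'   convolution.
#' @param fusion How the Bi-LSTM and attention-GCN streams are combined:
#'   \code{"mfm_gate"} (gated fusion followed by the multi-fusion module),
#'   \code{"gate"}, \code{"add"}, or \code{"concat"}.
#' @param mfm_submodules Subset of \code{c("LWF","WFF","MHAF","TMF")} enabled
#'   inside the multi-fusion module.
#' @param projection_dim Width of the linear projections used for feature
#'   alignment during knowledge transfer.
#' @param head_hidden Width of the hidden layer in the student output head.
#' @param graph Skeleton graph (see [skeleton_graph()]); defaults to the
#'   11-joint gait skeleton.
#' @param seed Integer seed controlling weight initialisation.
#' @return An object of class \code{gait_model_config}.
#' @export
model_config <- function(hidden_dim = 64, bilstm_layers = 2, dropout = 0.2,
                         gcn_node_out = 16, fusion = "mfm_gate",
                         mfm_submodules = c("LWF", "WFF", "MHAF", "TMF"),
                         projection_dim = 128, head_hidden = 64,
                         graph = skeleton_graph(), seed = 1L) {
  fusion <- match.arg(fusion, c("mfm_gate", "gate", "add", "concat"))
  if (hidden_dim <= 0 || hidden_dim %% 2 != 0) {
    stop("hidden_dim must be a positive even integer")
  }
  if (dropout < 0 || dropout >= 1) stop("dropout must lie in [0, 1)")
  if (fusion == "mfm_gate" && length(mfm_submodules) == 0) {
    stop("mfm_submodules must be non-empty when fusion = 'mfm_gate'")
  }
  if (length(mfm_submodules) > 0) {
    mfm_submodules <- match.arg(mfm_submodules, c("LWF", "WFF", "MHAF", "TMF"),
                                several.ok = TRUE)
  }
  structure(list(
    hidden_dim = hidden_dim, bilstm_layers = bilstm_layers, dropout = dropout,
    gcn_node_out = gcn_node_out, fusion = fusion,
    mfm_submodules = mfm_submodules, projection_dim = projection_dim,
    head_hidden = head_hidden, graph = graph, seed = as.integer(seed)
  ), class = "gait_model_config")
}

#' Skeleton graph of the tracked joint centers
#'
#' The 11-node joint graph whose (self-looped, row-normalized) adjacency
#' matrix drives the graph convolution. The default roster is a tree:
#' head-neck, neck-shoulders, neck-mid-hip, mid-hip-hips, hips-knees,
#' knees-ankles.
#'
#' @param node_labels Character vector of joint names.
#' @param edges Two-column matrix of undirected edges (indices or labels).
#' @param normalize Add self-loops and row-normalize the adjacency matrix
#'   (the form the graph convolution expects). \code{FALSE} keeps the raw
#'   binary adjacency.
#' @return Object of class \code{skeleton_graph} with elements
#'   \code{node_labels}, \code{edges} and \code{adjacency}.
#' @export
skeleton_graph <- function(node_labels = c("head", "neck", "mid_hip",
                                           "l_shoulder", "r_shoulder",
                                           "l_hip", "r_hip", "l_knee",
                                           "r_knee", "l_ankle", "r_ankle"),
                           edges = NULL, normalize = TRUE) {
  J <- length(node_labels)
  if (is.null(edges)) {
    ed <- c("head", "neck", "neck", "l_shoulder", "neck", "r_shoulder",
            "neck", "mid_hip", "mid_hip", "l_hip", "mid_hip", "r_hip",
            "l_hip", "l_knee", "r_hip", "r_knee",
            "l_knee", "l_ankle", "r_knee", "r_ankle")
    edges <- matrix(match(ed, node_labels), ncol = 2, byrow = TRUE)
  } else if (is.character(edges)) {
    edges <- matrix(match(edges, node_labels), ncol = 2, byrow = TRUE)
  }
  A <- matrix(0, J, J, dimnames = list(node_labels, node_labels))
  for (i in seq_len(nrow(edges))) {
    A[edges[i, 1], edges[i, 2]] <- 1
    A[edges[i, 2], edges[i, 1]] <- 1
  }
  if (normalize) {
    diag(A) <- 1
    A <- A / rowSums(A)
  }
  structure(list(node_labels = node_labels, edges = edges, adjacency = A),
            class = "skeleton_graph")
}

#' Architecture variant rosters
#'
#' Names of the student-family and teacher-family network variants that
#' [gait_model()] can build (the ablation grid plus the two final models).
#' @return Character vector of variant names.
#' @export
student_variants <- function() {
  c("joint_pos_bilstm", "aug_early_fusion_bilstm", "aug_concat_bilstm",
    "aug_concat_gcn", "aug_concat_attngcn", "aug_concat_bilstm_attngcn",
    "aug_gate_bilstm_attngcn", "aug_mfm_gate_bilstm_attngcn")
}

#' @rdname student_variants
#' @export
teacher_variants <- function() {
  c("imu_bilstm", "imu_jcp_early_fusion", "imu_jcp_concat", "imu_jcp_mfm")
}

variant_spec <- function(name) {
  specs <- list(
    joint_pos_bilstm = list(family = "student", modalities = list(pos = "pos"),
                            bilstm = TRUE, gcn = FALSE, attn = FALSE,
                            combine = "bilstm", mfm = FALSE),
    aug_early_fusion_bilstm = list(family = "student",
                                   modalities = list(kin = c("vel", "acc", "pos")),
                                   bilstm = TRUE, gcn = FALSE, attn = FALSE,
                                   combine = "bilstm", mfm = FALSE),
    aug_concat_bilstm = list(family = "student",
                             modalities = list(vel = "vel", acc = "acc", pos = "pos"),
                             bilstm = TRUE, gcn = FALSE, attn = FALSE,
                             combine = "bilstm", mfm = FALSE),
    aug_concat_gcn = list(family = "student",
                          modalities = list(vel = "vel", acc = "acc", pos = "pos"),
                          bilstm = FALSE, gcn = TRUE, attn = FALSE,
                          combine = "gcn", mfm = FALSE),
    aug_concat_attngcn = list(family = "student",
                              modalities = list(vel = "vel", acc = "acc", pos = "pos"),
                              bilstm = FALSE, gcn = TRUE, attn = TRUE,
                              combine = "gcn", mfm = FALSE),
    aug_concat_bilstm_attngcn = list(family = "student",
                                     modalities = list(vel = "vel", acc = "acc", pos = "pos"),
                                     bilstm = TRUE, gcn = TRUE, attn = TRUE,
                                     combine = "add", mfm = FALSE),
    aug_gate_bilstm_attngcn = list(family = "student",
                                   modalities = list(vel = "vel", acc = "acc", pos = "pos"),
                                   bilstm = TRUE, gcn = TRUE, attn = TRUE,
                                   combine = "gate", mfm = FALSE),
    aug_mfm_gate_bilstm_attngcn = list(family = "student",
                                       modalities = list(vel = "vel", acc = "acc", pos = "pos"),
                                       bilstm = TRUE, gcn = TRUE, attn = TRUE,
                                       combine = "gate", mfm = TRUE),
    imu_bilstm = list(family = "teacher",
                      modalities = list(imu = c("imu_acc", "imu_gyr")),
                      bilstm = TRUE, gcn = FALSE, attn = FALSE,
                      combine = "bilstm", mfm = FALSE),
    imu_jcp_early_fusion = list(family = "teacher",
                                modalities = list(all = c("imu_acc", "imu_gyr", "pos")),
                                bilstm = TRUE, gcn = FALSE, attn = FALSE,
                                combine = "bilstm", mfm = FALSE),
    imu_jcp_concat = list(family = "teacher",
                          modalities = list(imu_acc = "imu_acc",
                                            imu_gyr = "imu_gyr", pos = "pos"),
                          bilstm = TRUE, gcn = FALSE, attn = FALSE,
                          combine = "bilstm", mfm = FALSE),
    imu_jcp_mfm = list(family = "teacher",
                       modalities = list(imu_acc = "imu_acc",
                                         imu_gyr = "imu_gyr", pos = "pos"),
                       bilstm = TRUE, gcn = FALSE, attn = FALSE,
                       combine = "bilstm", mfm = TRUE)
  )
  if (!name %in% names(specs)) {
    stop("unknown model variant '", name, "'; see student_variants() and teacher_variants()")
  }
  specs[[name]]
}

channel_width <- function(src) {
  widths <- c(pos = 44L, vel = 44L, acc = 44L, imu_acc = 24L, imu_gyr = 24L)
  sum(widths[src])
}

#' Build a gait-kinetics network
#'
#' Constructs one of the student or teacher architecture variants. The final
#' student is \code{"aug_mfm_gate_bilstm_attngcn"} (three Bi-LSTM encoders
#' over position/velocity/acceleration, an attention-GCN branch, gated
#' fusion and the MFM); the final teacher is \code{"imu_jcp_mfm"} (Bi-LSTM
#' encoders over IMU accelerations, angular velocities and joint positions,
#' then the MFM). The remaining variants form the ablation grid.
#'
#' @param variant Variant name; one of [student_variants()] or
#'   [teacher_variants()].
#' @param config A [model_config()].
#' @return Object of class \code{gait_model}.
#' @export
gait_model <- function(variant = "aug_mfm_gate_bilstm_attngcn",
                       config = model_config()) {
  spec <- variant_spec(variant)
  cfg <- config
  C <- cfg$hidden_dim
  J <- length(cfg$graph$node_labels)
  A <- cfg$graph$adjacency
  n_mod <- length(spec$modalities)
  enc_width <- n_mod * C

  combine <- spec$combine
  if (combine %in% c("add", "gate") && !(spec$bilstm && spec$gcn)) {
    stop("combine mode requires both encoder branches")
  }

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(cfg$seed)

  layers <- list()
  # one batch-normalization per modality, on the raw channel widths
  layers$bn <- lapply(spec$modalities, function(src) make_bn(channel_width(src)))
  if (spec$bilstm) {
    layers$bilstm <- lapply(spec$modalities, function(src) {
      make_bilstm(channel_width(src), C, cfg$bilstm_layers, cfg$dropout)
    })
  }
  if (spec$gcn) {
    # graph branch exists only for the 44-channel video modalities
    layers$attn <- if (spec$attn) lapply(spec$modalities, function(src) make_node_attention(4L))
    layers$gcn <- lapply(spec$modalities, function(src) {
      make_gcn(4L, cfg$gcn_node_out, J, C)
    })
  }
  if (combine == "gate") layers$gate <- make_gate(enc_width)
  if (spec$mfm) {
    if (n_mod != 3) stop("the multi-fusion module expects three modality blocks")
    layers$mfm <- make_mfm(enc_width, cfg$mfm_submodules)
  }
  if (spec$family == "student") {
    layers$head <- list(hidden = make_linear(enc_width, cfg$head_hidden),
                        out = make_linear(cfg$head_hidden, 5L))
  } else {
    layers$head <- list(out = make_linear(enc_width, 5L))
  }

  if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()) else {
    rm(".Random.seed", envir = globalenv())
  }

  params <- collect_params(layers)
  enc_names <- names(collect_params(layers[intersect(names(layers),
                      c("bn", "bilstm", "attn", "gcn", "gate"))]))
  dec_names <- setdiff(names(params), enc_names)

  structure(list(
    variant = variant, spec = spec, config = cfg, layers = layers,
    params = params, bn_states = collect_bn_states(layers),
    param_groups = list(encoder = enc_names, decoder = dec_names),
    enc_width = enc_width, J = J, A = A
  ), class = "gait_model")
}

#' @rdname gait_model
#' @param name Variant name.
#' @export
build_variant <- function(name, config = model_config()) gait_model(name, config)

# ---- forward passes --------------------------------------------------------

# batch: list of frame matrices keyed by raw source name
# ("pos","vel","acc","imu_acc","imu_gyr") plus $B and $T.
model_encode <- function(model, batch, training = FALSE) {
  spec <- model$spec
  layers <- model$layers
  B <- batch$B; T <- batch$T
  S <- B * T
  extras <- list()

  normed <- list()
  for (nm in names(spec$modalities)) {
    src <- spec$modalities[[nm]]
    x <- if (length(src) == 1) ad_const(batch[[src]]) else {
      ad_const(do.call(cbind, batch[src]))
    }
    normed[[nm]] <- bn_fwd(layers$bn[[nm]], x, training)
  }

  x_bilstm <- NULL
  if (spec$bilstm) {
    x_bilstm <- ad_cbind(lapply(names(spec$modalities), function(nm) {
      bilstm_fwd(layers$bilstm[[nm]], normed[[nm]], B, T, training)
    }))
  }

  x_gcn <- NULL
  if (spec$gcn) {
    extras$attn_weights <- list()
    parts <- lapply(names(spec$modalities), function(nm) {
      # frame matrix (S x 44) -> node-major ((S*J) x 4); the 44 channels are
      # ordered coordinate-major with joints fastest, so this is a plain
      # column-major reshape
      x_nodes <- ad_reshape(normed[[nm]], S * model$J)
      if (spec$attn) {
        at <- node_attention_fwd(layers$attn[[nm]], x_nodes, S, model$J)
        extras$attn_weights[[nm]] <<- at$weights
        x_nodes <- at$attended
      }
      gcn_fwd(layers$gcn[[nm]], x_nodes, model$A, S)
    })
    x_gcn <- ad_cbind(parts)
  }

  features <- switch(spec$combine,
    bilstm = x_bilstm,
    gcn = x_gcn,
    add = ad_add(x_bilstm, x_gcn),
    gate = {
      g <- gate_fwd(layers$gate, x_bilstm, x_gcn)
      extras$gate <- g$gate
      g$fused
    }
  )
  list(features = features, extras = extras)
}

model_decode <- function(model, features, B, T, training = FALSE) {
  x <- features
  if (model$spec$mfm) x <- mfm_fwd(model$layers$mfm, x, B, T)
  head <- model$layers$head
  if (!is.null(head$hidden)) {
    x <- ad_relu(linear_fwd(head$hidden, x))
  }
  linear_fwd(head$out, x)
}

model_forward <- function(model, batch, training = FALSE) {
  enc <- model_encode(model, batch, training)
  pred <- model_decode(model, enc$features, batch$B, batch$T, training)
  list(pred = pred, features = enc$features, extras = enc$extras)
}

# ---- parameter bookkeeping -------------------------------------------------

#' Extract the numeric parameter values of a model
#'
#' Used for exact freeze-contract checks: two snapshots compare with
#' \code{identical()}.
#'
#' @param model A \code{gait_model} (or \code{gait_fit}).
#' @param group Optionally \code{"encoder"} or \code{"decoder"} to restrict
#'   to one parameter group.
#' @return Named list of numeric arrays.
#' @export
gait_param_values <- function(model, group = NULL) {
  if (inherits(model, "gait_fit")) model <- model$model
  nms <- names(model$params)
  if (!is.null(group)) nms <- model$param_groups[[group]]
  out <- lapply(model$params[nms], function(p) p$v)
  names(out) <- nms
  out
}

n_params <- function(model) {
  if (inherits(model, "gait_fit")) model <- model$model
  sum(vapply(model$params, function(p) length(p$v), numeric(1)))
}

snapshot_model <- function(model) {
  list(values = lapply(model$params, function(p) p$v),
       bn = lapply(model$bn_states, function(st) list(mu = st$mu, va = st$va)))
}

restore_model <- function(model, snap) {
  for (nm in names(snap$values)) model$params[[nm]]$v <- snap$values[[nm]]
  for (nm in names(snap$bn)) {
    model$bn_states[[nm]]$mu <- snap$bn[[nm]]$mu
    model$bn_states[[nm]]$va <- snap$bn[[nm]]$va
  }
  invisible(model)
}
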