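# Two-step multi-modal knowledge transfer and the knowledge-distillation
# baseline.
#
# Step 1 trains the student encoder (Bi-LSTM + attention-GCN + gate) so
# that a linear projection of its fused features matches a linear
# projection of the frozen, already-trained teacher's concatenated encoder
# features (feature-alignment RMSE loss). Step 2 freezes the pretrained
# encoder and trains only the MFM and output head on the kinetics RMSE.

#' Knowledge-distillation configuration
#'
#' @param alpha Weight of the distillation term (>= 0).
#' @param variant \code{"vanilla"} (prediction matching only) or
#'   \code{"vanilla_plus_layer_loss"} (adds the RMSE between linearly
#'   projected encoder features).
#' @return Object of class \code{gait_kd_config}.
#' @export
kd_config <- function(alpha = 0.5, variant = "vanilla") {
  variant <- match.arg(variant, c("vanilla", "vanilla_plus_layer_loss"))
  if (alpha < 0) stop("alpha must be non-negative")
  structure(list(alpha = alpha, variant = variant), class = "gait_kd_config")
}

#' Feature-alignment loss
#'
#' Root-mean-square difference between two equally shaped feature arrays;
#' zero exactly when the projections coincide, and symmetric in its
#' arguments.
#'
#' @param s,t Numeric arrays of equal shape.
#' @return Non-negative scalar.
#' @export
feature_alignment_loss <- function(s, t) {
  if (!identical(dim(s), dim(t))) stop("projected features must have equal shapes")
  sqrt(mean((s - t)^2))
}

#' Knowledge-distillation loss
#'
#' \code{L = L_student + alpha * L_KD} with
#' \code{L_student = RMSE(truth, pred_s)} and
#' \code{L_KD = RMSE(pred_s, pred_t)} (vanilla), plus
#' \code{RMSE(proj_s, proj_t)} under the layer-loss variant.
#'
#' @param pred_s,pred_t Student / teacher predictions (equal shapes).
#' @param truth Ground-truth kinetics.
#' @param proj_s,proj_t Projected encoder features (layer-loss variant).
#' @param config A [kd_config()].
#' @return Scalar loss.
#' @export
kd_loss <- function(pred_s, pred_t, truth, proj_s = NULL, proj_t = NULL,
                    config = kd_config()) {
  if (!identical(dim(pred_s), dim(truth)) ||
      !identical(dim(pred_s), dim(pred_t))) {
    stop("prediction and truth arrays must have equal shapes")
  }
  l <- sqrt(mean((truth - pred_s)^2))
  lkd <- sqrt(mean((pred_s - pred_t)^2))
  if (config$variant == "vanilla_plus_layer_loss") {
    if (is.null(proj_s) || is.null(proj_t)) {
      stop("layer-loss variant needs projected features")
    }
    lkd <- lkd + feature_alignment_loss(proj_s, proj_t)
  }
  l + config$alpha * lkd
}

# encoder-only forward of the teacher in evaluation mode, off-tape
teacher_features <- function(teacher, batch) {
  rec <- ad_active()
  if (rec) {
    tp <- .ad$tape
    ad_end()
    on.exit(.ad$tape <- tp)
  }
  model_encode(teacher, batch, training = FALSE)$features$v
}

#' Pretrain the student encoder by feature alignment (transfer step 1)
#'
#' Optimises the student encoder together with a linear projection layer
#' so that the projected student features match a fixed linear projection
#' of the frozen, trained teacher's features. The teacher-side projection
#' is frozen at its random initialisation: if both projections were free,
#' the zero map would be a trivial minimiser of the alignment loss and the
#' encoder could collapse. The teacher's parameters are untouched; the
#' retained weights are those with the smallest validation alignment
#' loss.
#'
#' @param student A student [gait_model()] (its encoder is updated in
#'   place).
#' @param teacher_fit A trained teacher (\code{gait_fit}).
#' @param data \code{gait_windows} or a list with \code{train} / \code{val}.
#' @param config A [train_config()].
#' @return Object of class \code{gait_pretrain} with the student model,
#'   both projection layers and the training history.
#' @export
pretrain_student_encoder <- function(student, teacher_fit, data,
                                     config = train_config()) {
  if (!inherits(teacher_fit, "gait_fit")) {
    stop("teacher must be a trained gait_fit (train the teacher first)")
  }
  teacher <- teacher_fit$model
  if (inherits(data, "gait_windows")) data <- split_train_val(data, config)
  train <- data$train; val <- data$val
  n <- n_windows(train)
  if (n == 0) stop("empty training set")
  s_src <- model_sources(student)
  t_src <- model_sources(teacher)
  sources <- union(s_src, t_src)

  restore_rng <- local_rng(config$seed)
  on.exit(restore_rng())

  P <- student$config$projection_dim
  proj_s <- make_linear(student$enc_width, P)
  proj_t <- make_linear(teacher$enc_width, P)
  enc_params <- student$params[student$param_groups$encoder]
  params <- c(enc_params, collect_params(list(proj_s = proj_s)))
  opt <- adam_new(params, config$learning_rate)

  fa_batch <- function(batch, training) {
    tf <- ad_const(teacher_features(teacher, batch))
    enc <- model_encode(student, batch, training)
    ad_rmse(linear_fwd(proj_s, enc$features), linear_fwd(proj_t, tf))
  }

  best <- Inf; best_snap <- snapshot_model(student)
  best_proj <- list(Ws = proj_s$W$v, bs = proj_s$b$v, Wt = proj_t$W$v, bt = proj_t$b$v)
  best_epoch <- 0L; wait <- 0L
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())

  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    tot <- 0
    for (start in seq(1L, n, by = config$batch_size)) {
      idx <- ord[start:min(n, start + config$batch_size - 1L)]
      batch <- batch_frames(train, idx, sources)
      ad_begin()
      loss <- fa_batch(batch, training = TRUE)
      ad_backward(loss)
      ad_end()
      adam_step(opt)
      zero_grads(student$params)
      tot <- tot + loss$v^2 * length(idx)
    }
    train_loss <- sqrt(tot / n)
    vtot <- 0
    nv <- n_windows(val)
    for (start in seq(1L, nv, by = 256L)) {
      idx <- start:min(nv, start + 255L)
      batch <- batch_frames(val, idx, sources)
      vtot <- vtot + fa_batch(batch, training = FALSE)$v^2 * length(idx)
    }
    val_loss <- sqrt(vtot / nv)
    history <- rbind(history, data.frame(epoch = epoch, train_loss = train_loss,
                                         val_loss = val_loss))
    if (val_loss < best) {
      best <- val_loss
      best_snap <- snapshot_model(student)
      best_proj <- list(Ws = proj_s$W$v, bs = proj_s$b$v,
                        Wt = proj_t$W$v, bt = proj_t$b$v)
      best_epoch <- epoch; wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) break
    }
  }
  restore_model(student, best_snap)
  proj_s$W$v <- best_proj$Ws; proj_s$b$v <- best_proj$bs
  proj_t$W$v <- best_proj$Wt; proj_t$b$v <- best_proj$bt
  structure(list(model = student, proj_student = proj_s, proj_teacher = proj_t,
                 history = history, best_epoch = best_epoch,
                 best_val_loss = best, train_config = config),
            class = "gait_pretrain")
}

#' Fine-tune the student head on frozen pretrained encoders (step 2)
#'
#' The pretrained encoder is frozen (weights and batch-normalization
#' statistics); only the MFM and the fully connected head are trained on
#' the kinetics RMSE. Encoder features are computed off-tape in evaluation
#' mode, so no gradient ever reaches the encoder.
#'
#' @param pretrained A \code{gait_pretrain} from
#'   [pretrain_student_encoder()].
#' @param data \code{gait_windows} or a list with \code{train} / \code{val}.
#' @param config A [train_config()].
#' @return A \code{gait_fit} for the full student model.
#' @export
finetune_student <- function(pretrained, data, config = train_config()) {
  if (!inherits(pretrained, "gait_pretrain")) {
    stop("finetune_student() needs the pretrained encoder from step 1")
  }
  student <- pretrained$model
  if (inherits(data, "gait_windows")) data <- split_train_val(data, config)
  train <- data$train; val <- data$val
  n <- n_windows(train)
  if (n == 0) stop("empty training set")
  sources <- model_sources(student)

  restore_rng <- local_rng(config$seed)
  on.exit(restore_rng())

  ts <- fit_target_scale(train)
  dec_params <- student$params[student$param_groups$decoder]
  opt <- adam_new(dec_params, config$learning_rate)

  frozen_features <- function(batch) {
    rec <- ad_active()
    if (rec) {
      tp <- .ad$tape
      ad_end()
      on.exit(.ad$tape <- tp)
    }
    model_encode(student, batch, training = FALSE)$features$v
  }

  run_loss <- function(batch, training) {
    feats <- ad_const(frozen_features(batch))
    pred <- model_decode(student, feats, batch$B, batch$T, training)
    ad_rmse(pred, ad_const(batch$kin))
  }

  best <- Inf; best_snap <- snapshot_model(student); best_epoch <- 0L; wait <- 0L
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    tot <- 0
    for (start in seq(1L, n, by = config$batch_size)) {
      idx <- ord[start:min(n, start + config$batch_size - 1L)]
      batch <- batch_frames(train, idx, sources, ts)
      ad_begin()
      loss <- run_loss(batch, training = TRUE)
      ad_backward(loss)
      ad_end()
      adam_step(opt)
      zero_grads(student$params)
      tot <- tot + loss$v^2 * length(idx)
    }
    train_loss <- sqrt(tot / n)
    nv <- n_windows(val)
    vtot <- 0
    for (start in seq(1L, nv, by = 256L)) {
      idx <- start:min(nv, start + 255L)
      batch <- batch_frames(val, idx, sources, ts)
      vtot <- vtot + run_loss(batch, training = FALSE)$v^2 * length(idx)
    }
    val_loss <- sqrt(vtot / nv)
    history <- rbind(history, data.frame(epoch = epoch, train_loss = train_loss,
                                         val_loss = val_loss))
    if (val_loss < best) {
      best <- val_loss; best_snap <- snapshot_model(student)
      best_epoch <- epoch; wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) break
    }
  }
  restore_model(student, best_snap)
  structure(list(model = student, history = history, best_epoch = best_epoch,
                 best_val_loss = best, train_config = config,
                 target_scale = ts, variant = student$variant,
                 knowledge_transfer = TRUE),
            class = "gait_fit")
}

#' Train a student with the knowledge-distillation baseline
#'
#' Joint loss \code{L_student + alpha * L_KD} against a frozen trained
#' teacher (predictions matched on the standardized target scale; the
#' layer-loss variant adds the projected-feature RMSE).
#'
#' @param student A student [gait_model()].
#' @param teacher_fit Trained teacher \code{gait_fit}.
#' @param data \code{gait_windows} or train/val list.
#' @param config A [train_config()].
#' @param kd A [kd_config()].
#' @return A \code{gait_fit}.
#' @export
train_student_kd <- function(student, teacher_fit, data,
                             config = train_config(), kd = kd_config()) {
  if (!inherits(teacher_fit, "gait_fit")) stop("teacher must be a trained gait_fit")
  teacher <- teacher_fit$model
  with_layer <- kd$variant == "vanilla_plus_layer_loss"
  P <- student$config$projection_dim

  proj_s <- NULL; proj_t <- NULL
  params <- student$params
  if (with_layer) {
    restore_rng <- local_rng(config$seed + 2000L)
    proj_s <- make_linear(student$enc_width, P)
    proj_t <- make_linear(teacher$enc_width, P)
    restore_rng()
    params <- c(params, collect_params(list(proj_s = proj_s, proj_t = proj_t)))
  }

  t_src <- model_sources(teacher)

  teacher_out <- function(batch, ts) {
    rec <- ad_active()
    if (rec) {
      tp <- .ad$tape
      ad_end()
      on.exit(.ad$tape <- tp)
    }
    out <- model_forward(teacher, batch, training = FALSE)
    # teacher predictions mapped onto the student's standardized scale
    pv <- sweep(sweep(out$pred$v, 2, teacher_fit$target_scale$sd, "*"),
                2, teacher_fit$target_scale$mu, "+")
    list(pred = sweep(sweep(pv, 2, ts$mu), 2, ts$sd, "/"),
         features = out$features$v)
  }

  loss_fn <- function(out, batch, ts) {
    tout <- teacher_out(batch, ts)
    l <- ad_rmse(out$pred, ad_const(batch$kin))
    lkd <- ad_rmse(out$pred, ad_const(tout$pred))
    parts <- list(l, lkd)
    wts <- c(1, kd$alpha)
    if (with_layer) {
      fa <- ad_rmse(linear_fwd(proj_s, out$features),
                    linear_fwd(proj_t, ad_const(tout$features)))
      parts <- c(parts, list(fa))
      wts <- c(wts, kd$alpha)
    }
    ad_scalar_sum(parts, wts)
  }
  loss_eval <- function(out, batch) {
    # validation on the plain student loss so model selection matches the
    # other training routes
    sqrt(mean((out$pred$v - batch$kin)^2))
  }

  # teacher consumes the union of sources; extend the student batch
  old_sources <- model_sources(student)
  need <- union(old_sources, t_src)
  fit <- train_model(student, data, config, loss_fn, loss_eval, params,
                     sources = need)
  fit$kd_config <- kd
  fit
}

#' Sweep the distillation weight alpha
#'
#' Trains one knowledge-distillation student per (alpha, variant)
#' combination and reports overall NRMSE and PCC on a held-out subject.
#'
#' @param student_factory Zero-argument function returning a fresh student
#'   [gait_model()].
#' @param teacher_fit Trained teacher.
#' @param data Train/val list of \code{gait_windows}.
#' @param test Windows of the held-out test subject.
#' @param alphas Numeric vector of distillation weights.
#' @param variants KD variants to cross with the alphas.
#' @param config A [train_config()].
#' @return Data frame with one row per (variant, alpha): NRMSE (%), PCC.
#' @export
alpha_sweep <- function(student_factory, teacher_fit, data, test,
                        alphas = c(0.1, 0.3, 0.5, 0.7, 0.9),
                        variants = c("vanilla", "vanilla_plus_layer_loss"),
                        config = train_config()) {
  if (length(alphas) == 0) stop("empty alpha grid")
  grid <- expand.grid(alpha = alphas, variant = variants,
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    student <- student_factory()
    fit <- train_student_kd(student, teacher_fit, data, config,
                            kd_config(grid$alpha[i], grid$variant[i]))
    m <- evaluate_fit(fit, test)
    data.frame(variant = grid$variant[i], alpha = grid$alpha[i],
               nrmse = mean(m$nrmse), pcc = mean(m$pcc))
  })
  do.call(rbind, res)
}
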