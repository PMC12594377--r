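#' Training configuration
#'
#' Optimisation settings shared by every model in the package: Adam with
#' learning rate 0.001, an RMSE loss over all predicted frames, batch size
#' 64, at most 40 epochs with early stopping at a patience of 10 epochs,
#' keeping the weights with the smallest validation loss.
#'
#' @param learning_rate Adam learning rate.
#' @param epochs Maximum number of epochs.
#' @param patience Early-stopping patience (epochs without validation
#'   improvement); must not exceed \code{epochs}.
#' @param batch_size Windows per gradient step.
#' @param validation_policy \code{"subject"} (hold out one training subject)
#'   or \code{"fraction"} (hold out a random fraction of windows).
#' @param validation_fraction Fraction held out under the fraction policy.
#' @param seed Integer seed for shuffling, dropout and the validation split.
#' @return Object of class \code{gait_train_config}.
#' @export
train_config <- function(learning_rate = 0.001, epochs = 40, patience = 10,
                         batch_size = 64, validation_policy = "subject",
                         validation_fraction = 0.2, seed = 1L) {
  validation_policy <- match.arg(validation_policy, c("subject", "fraction"))
  if (patience > epochs) stop("patience must not exceed epochs")
  if (batch_size < 1) stop("batch_size must be at least 1")
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 patience = as.integer(patience),
                 batch_size = as.integer(batch_size),
                 validation_policy = validation_policy,
                 validation_fraction = validation_fraction,
                 seed = as.integer(seed)),
            class = "gait_train_config")
}

# ---- Adam ------------------------------------------------------------------

adam_new <- function(params, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt <- new.env(parent = emptyenv())
  opt$params <- params
  opt$lr <- lr; opt$b1 <- beta1; opt$b2 <- beta2; opt$eps <- eps
  opt$m <- lapply(params, function(p) p$v * 0)
  opt$s <- lapply(params, function(p) p$v * 0)
  opt$t <- 0L
  opt
}

adam_step <- function(opt) {
  opt$t <- opt$t + 1L
  c1 <- 1 - opt$b1^opt$t
  c2 <- 1 - opt$b2^opt$t
  for (i in seq_along(opt$params)) {
    p <- opt$params[[i]]
    if (is.null(p$g)) next
    opt$m[[i]] <- opt$b1 * opt$m[[i]] + (1 - opt$b1) * p$g
    opt$s[[i]] <- opt$b2 * opt$s[[i]] + (1 - opt$b2) * p$g^2
    p$v <- p$v - opt$lr * (opt$m[[i]] / c1) / (sqrt(opt$s[[i]] / c2) + opt$eps)
    p$g <- NULL
  }
  invisible(NULL)
}

zero_grads <- function(params) {
  for (p in params) p$g <- NULL
  invisible(NULL)
}

# ---- batches ---------------------------------------------------------------

# build the frame-matrix batch for a window subset
batch_frames <- function(windows, idx, sources, target_scale = NULL) {
  B <- length(idx)
  T <- windows$window
  out <- list(B = B, T = T)
  for (src in sources) {
    arr <- windows[[src]][idx, , , drop = FALSE]
    out[[src]] <- matrix(arr, nrow = B * T)
  }
  out$kin <- matrix(windows$kin[idx, , , drop = FALSE], nrow = B * T)
  if (!is.null(target_scale)) {
    out$kin <- sweep(sweep(out$kin, 2, target_scale$mu), 2, target_scale$sd, "/")
  }
  out
}

# per-component standardization of the kinetics targets, fitted on the
# training windows; predictions are mapped back to physical units
fit_target_scale <- function(windows) {
  m <- matrix(windows$kin, ncol = 5L)
  mu <- colMeans(m)
  sd <- apply(m, 2, stats::sd)
  sd[sd < 1e-8] <- 1
  list(mu = mu, sd = sd)
}

model_sources <- function(model) {
  unique(unlist(model$spec$modalities, use.names = FALSE))
}

n_windows <- function(windows) length(windows$subject)

subset_windows <- function(windows, idx) {
  out <- windows
  for (nm in c("pos", "vel", "acc", "imu_acc", "imu_gyr", "kin")) {
    out[[nm]] <- windows[[nm]][idx, , , drop = FALSE]
  }
  out$subject <- windows$subject[idx]
  out$trial <- windows$trial[idx]
  out$start <- windows$start[idx]
  out
}

#' Split windows into training and validation sets
#'
#' @param windows A \code{gait_windows} set.
#' @param config A [train_config()]; its validation policy and seed decide
#'   the split.
#' @return List with elements \code{train} and \code{val}.
#' @export
split_train_val <- function(windows, config = train_config()) {
  n <- n_windows(windows)
  rng <- local_rng(config$seed + 1000L)
  on.exit(rng())
  if (config$validation_policy == "subject") {
    subjects <- sort(unique(windows$subject))
    if (length(subjects) < 2) stop("subject validation policy needs at least 2 subjects")
    val_subject <- sample(subjects, 1)
    vi <- which(windows$subject == val_subject)
  } else {
    vi <- sample(n, max(1L, round(config$validation_fraction * n)))
  }
  list(train = subset_windows(windows, setdiff(seq_len(n), vi)),
       val = subset_windows(windows, vi))
}

# run expr-style deterministic RNG without disturbing the caller's stream
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  function() {
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
  }
}

# ---- training loop ---------------------------------------------------------

eval_loss <- function(model, windows, sources, loss_eval = NULL,
                      target_scale = NULL, batch_size = 256L) {
  n <- n_windows(windows)
  tot <- 0
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(n, start + batch_size - 1L)
    batch <- batch_frames(windows, idx, sources, target_scale)
    out <- model_forward(model, batch, training = FALSE)
    l <- if (is.null(loss_eval)) {
      sqrt(mean((out$pred$v - batch$kin)^2))
    } else loss_eval(out, batch)
    tot <- tot + l^2 * length(idx)
  }
  sqrt(tot / n)
}

#' Train a gait-kinetics model
#'
#' Mini-batch Adam on the RMSE between predicted and measured kinetics,
#' with per-epoch validation, early stopping and best-weight retention.
#'
#' @param model A [gait_model()] (modified in place and returned inside the
#'   fit).
#' @param data Either a \code{gait_windows} set (split internally according
#'   to the config's validation policy) or a list with elements \code{train}
#'   and \code{val}.
#' @param config A [train_config()].
#' @param loss_fn Optional custom training loss:
#'   \code{function(out, batch)} returning an autodiff scalar node
#'   (used for the knowledge-distillation baseline).
#' @param loss_eval Optional matching numeric validation loss
#'   \code{function(out, batch)}.
#' @param params Parameters to optimise (defaults to all model parameters).
#' @return Object of class \code{gait_fit} with elements \code{model},
#'   \code{history}, \code{best_epoch} and \code{train_config}.
#' @export
train_model <- function(model, data, config = train_config(), loss_fn = NULL,
                        loss_eval = NULL, params = NULL, sources = NULL) {
  if (inherits(data, "gait_windows")) data <- split_train_val(data, config)
  train <- data$train; val <- data$val
  n <- n_windows(train)
  if (n == 0) stop("empty training set")
  if (is.null(sources)) sources <- model_sources(model)
  if (is.null(params)) params <- model$params

  restore_rng <- local_rng(config$seed)
  on.exit(restore_rng())

  ts <- fit_target_scale(train)
  opt <- adam_new(params, config$learning_rate)
  best <- Inf; best_snap <- snapshot_model(model); best_epoch <- 0L; wait <- 0L
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())

  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    tot <- 0
    for (start in seq(1L, n, by = config$batch_size)) {
      idx <- ord[start:min(n, start + config$batch_size - 1L)]
      batch <- batch_frames(train, idx, sources, ts)
      ad_begin()
      out <- model_forward(model, batch, training = TRUE)
      loss <- if (is.null(loss_fn)) ad_rmse(out$pred, ad_const(batch$kin)) else loss_fn(out, batch, ts)
      ad_backward(loss)
      ad_end()
      adam_step(opt)
      zero_grads(model$params)
      tot <- tot + loss$v^2 * length(idx)
    }
    train_loss <- sqrt(tot / n)
    val_loss <- eval_loss(model, val, sources, loss_eval, ts)
    history <- rbind(history, data.frame(epoch = epoch, train_loss = train_loss,
                                         val_loss = val_loss))
    if (val_loss < best) {
      best <- val_loss; best_snap <- snapshot_model(model)
      best_epoch <- epoch; wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) break
    }
  }
  restore_model(model, best_snap)
  structure(list(model = model, history = history, best_epoch = best_epoch,
                 best_val_loss = best, train_config = config,
                 target_scale = ts, variant = model$variant),
            class = "gait_fit")
}

# batched evaluation-mode forward pass over a window set -> [N x dT x 5]
predict_windows <- function(model, windows, batch_size = 256L) {
  ts <- NULL
  if (inherits(model, "gait_fit")) {
    ts <- model$target_scale
    model <- model$model
  }
  n <- n_windows(windows)
  T <- windows$window
  sources <- model_sources(model)
  out <- array(0, c(n, T, 5L))
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(n, start + batch_size - 1L)
    batch <- batch_frames(windows, idx, sources)
    pred <- model_forward(model, batch, training = FALSE)$pred$v
    if (!is.null(ts)) {
      pred <- sweep(sweep(pred, 2, ts$sd, "*"), 2, ts$mu, "+")
    }
    out[idx, , ] <- array(pred, c(length(idx), T, 5L))
  }
  out
}
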