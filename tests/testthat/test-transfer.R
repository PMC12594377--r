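# Knowledge transfer: losses, freeze contracts and the training loop.

ns <- asNamespace("gaitkt")

test_that("the distillation loss follows its closed form", {
  truth <- matrix(c(0, 0), 1, 2)
  ps <- matrix(c(1, 1), 1, 2)
  pt <- matrix(c(1, 1), 1, 2)
  # alpha = 0 reduces to the plain RMSE loss exactly
  expect_identical(kd_loss(ps, pt, truth, config = kd_config(alpha = 0)),
                   sqrt(mean((truth - ps)^2)))
  # hand arithmetic: RMSE(truth, pred) = 1, teacher term 0
  expect_equal(kd_loss(ps, pt, truth, config = kd_config(alpha = 0.5)), 1)
  # perfect student and teacher: zero loss (with layer loss too)
  expect_equal(kd_loss(truth, truth, truth, proj_s = ps, proj_t = ps,
                       config = kd_config(0.7, "vanilla_plus_layer_loss")), 0)
  # layer-loss variant adds the projected-feature RMSE
  expect_equal(kd_loss(ps, pt, truth, proj_s = ps, proj_t = ps + 2,
                       config = kd_config(0.5, "vanilla_plus_layer_loss")),
               1 + 0.5 * (0 + 2))
  expect_error(kd_config(alpha = -1), "non-negative")
  expect_error(kd_loss(ps, pt, truth[, 1, drop = FALSE]), "equal shapes")
})

test_that("the feature-alignment loss is an RMSE metric on projections", {
  set.seed(1)
  s <- matrix(rnorm(20), 4, 5)
  expect_identical(feature_alignment_loss(s, s), 0)
  expect_equal(feature_alignment_loss(s, s + 0.3), 0.3)
  t2 <- matrix(rnorm(20), 4, 5)
  expect_identical(feature_alignment_loss(s, t2), feature_alignment_loss(t2, s))
  expect_gt(feature_alignment_loss(s, t2), 0)
  expect_error(feature_alignment_loss(s, t2[, 1:3]), "equal shapes")
})

test_that("training stops on a plateau and retains the best-validation weights", {
  w <- tiny_windows()
  sp <- subject_split(w)
  m <- gait_model("joint_pos_bilstm", tiny_model_config())
  # rigged plateau: a constant loss can never improve after epoch 1
  const_loss <- function(out, batch, ts) ns$ad_op(1, function(g) NULL)
  fit <- train_model(m, sp$data,
                     tiny_train_config(epochs = 20, patience = 3),
                     loss_fn = const_loss,
                     loss_eval = function(out, batch) 1)
  expect_identical(nrow(fit$history), 1L + 3L)   # epoch 1 improves from Inf
  expect_identical(fit$best_epoch, 1L)

  m2 <- gait_model("joint_pos_bilstm", tiny_model_config(seed = 2))
  fit2 <- train_model(m2, sp$data, tiny_train_config(epochs = 3, seed = 5))
  expect_identical(fit2$best_epoch, which.min(fit2$history$val_loss))
  # determinism: same seeds reproduce the history exactly
  m3 <- gait_model("joint_pos_bilstm", tiny_model_config(seed = 2))
  fit3 <- train_model(m3, sp$data, tiny_train_config(epochs = 3, seed = 5))
  expect_identical(fit2$history, fit3$history)
  empty <- ns$subset_windows(w, integer(0))
  expect_error(train_model(m2, list(train = empty, val = sp$data$val),
                           tiny_train_config()), "empty training set")
})

test_that("step 1 never touches the teacher and step 2 never touches the encoder", {
  w <- tiny_windows()
  sp <- subject_split(w)
  mc <- tiny_model_config(seed = 3)
  tc <- tiny_train_config(epochs = 2, seed = 7)
  teacher_fit <- train_model(gait_model("imu_jcp_mfm", mc), sp$data, tc)

  student <- gait_model("aug_mfm_gate_bilstm_attngcn", mc)
  teacher_before <- gait_param_values(teacher_fit$model)
  pre <- pretrain_student_encoder(student, teacher_fit, sp$data, tc)
  expect_identical(gait_param_values(teacher_fit$model), teacher_before)
  # the retained checkpoint is at least as good as the first epoch
  expect_lte(pre$best_val_loss, pre$history$val_loss[1])

  enc_before <- gait_param_values(pre$model, group = "encoder")
  dec_before <- gait_param_values(pre$model, group = "decoder")
  fit <- finetune_student(pre, sp$data, tc)
  expect_identical(gait_param_values(fit$model, group = "encoder"), enc_before)
  # the decoder (MFM + head) did train
  dec_after <- gait_param_values(fit$model, group = "decoder")
  expect_false(identical(dec_after, dec_before))
  # untrained teacher and missing pretraining are configuration errors
  expect_error(pretrain_student_encoder(student, teacher_fit$model, sp$data, tc),
               "trained")
  expect_error(finetune_student(fit, sp$data, tc), "pretrained")
})

test_that("feature alignment learns an identity-like teacher at small scale", {
  # noiseless data and a position-only teacher: the alignment target then
  # factors through the student's own inputs, so the feature-alignment
  # loss must fall well below its starting value
  ds <- simulate_gait(sim_config(n_subjects = 3, trials_per_subject = 1,
                                 trial_length = 400, camera_noise_sd = 0,
                                 imu_noise_sd = 0, kinetics_noise_sd = 0,
                                 seed = 21))
  w <- window_dataset(ds)
  sp <- subject_split(w)
  mc <- model_config(hidden_dim = 16, gcn_node_out = 4, projection_dim = 8,
                     head_hidden = 8, dropout = 0, seed = 4)
  tc <- tiny_train_config(epochs = 2, seed = 8)
  teacher_fit <- train_model(gait_model("joint_pos_bilstm", mc), sp$data, tc)
  pre <- pretrain_student_encoder(gait_model("aug_mfm_gate_bilstm_attngcn", mc),
                                  teacher_fit, sp$data,
                                  tiny_train_config(epochs = 40, seed = 9,
                                                    learning_rate = 0.005))
  expect_lt(min(pre$history$train_loss),
            0.1 * pre$history$train_loss[1])
})

test_that("the alpha sweep produces the expected grid", {
  w <- tiny_windows()
  sp <- subject_split(w)
  mc <- tiny_model_config(seed = 5)
  tc <- tiny_train_config(epochs = 1, seed = 11)
  teacher_fit <- train_model(gait_model("imu_jcp_mfm", mc), sp$data, tc)
  grid <- alpha_sweep(function() gait_model("aug_mfm_gate_bilstm_attngcn", mc),
                      teacher_fit, sp$data, sp$test,
                      alphas = c(0.1, 0.9), variants = "vanilla",
                      config = tc)
  expect_identical(nrow(grid), 2L)
  expect_identical(names(grid), c("variant", "alpha", "nrmse", "pcc"))
  expect_true(all(is.finite(grid$nrmse)))
  expect_error(alpha_sweep(function() NULL, teacher_fit, sp$data, sp$test,
                           alphas = numeric(0)), "empty")
})
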