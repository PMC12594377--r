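# Experiment orchestration: fold-wise training/evaluation and the scaled
# knowledge-transfer benefit experiment.

# windows split helpers keyed by subject
windows_for_subjects <- function(w, subjects) {
  subset_windows(w, which(w$subject %in% subjects))
}

fold_data <- function(w, fold) {
  list(train = windows_for_subjects(w, fold$train_subjects),
       val = windows_for_subjects(w, fold$validation_subject))
}

#' Knowledge-transfer benefit experiment
#'
#' The package's headline property check at desk scale: on the default
#' synthetic dataset, train (per seed) the teacher, a student without
#' knowledge transfer, and a student with the two-step transfer, then
#' compare overall NRMSE on a held-out test subject. The expected ordering
#' is teacher <= student+KT <= student-without-KT on seed-averaged means,
#' with the transfer helping in most seeds.
#'
#' @param seeds Integer vector; one experiment replicate per seed.
#' @param n_subjects Simulated cohort size.
#' @param hidden_dim Encoder width for the desk-scale profile.
#' @param epochs Training epochs per stage.
#' @param learning_rate,batch_size Desk-scale optimisation settings.
#' @param verbose Print per-seed results.
#' @return Data frame with one row per seed: overall NRMSE of teacher,
#'   student with KT, student without KT.
#' @export
kt_benefit_experiment <- function(seeds = 1:5, n_subjects = 10,
                                  hidden_dim = 32, epochs = 12,
                                  learning_rate = 0.003, batch_size = 32,
                                  verbose = FALSE) {
  res <- NULL
  for (seed in seeds) {
    cfg <- sim_config(n_subjects = n_subjects, seed = 100L + seed)
    w <- window_dataset(simulate_gait(cfg))
    subs <- sort(unique(w$subject))
    ns <- length(subs)
    test_s <- subs[ns]; val_s <- subs[ns - 1L]
    data <- list(train = windows_for_subjects(w, setdiff(subs, c(test_s, val_s))),
                 val = windows_for_subjects(w, val_s))
    test_w <- windows_for_subjects(w, test_s)
    mc <- model_config(hidden_dim = hidden_dim, projection_dim = 64,
                       seed = 10L + seed)
    tc <- train_config(learning_rate = learning_rate, epochs = epochs,
                       patience = epochs, batch_size = batch_size,
                       seed = 20L + seed)

    teacher_fit <- train_model(gait_model("imu_jcp_mfm", mc), data, tc)
    n_teacher <- mean(evaluate_fit(teacher_fit, test_w)$nrmse)

    nokt_fit <- train_model(gait_model("aug_mfm_gate_bilstm_attngcn", mc),
                            data, tc)
    n_nokt <- mean(evaluate_fit(nokt_fit, test_w)$nrmse)

    pre <- pretrain_student_encoder(gait_model("aug_mfm_gate_bilstm_attngcn", mc),
                                    teacher_fit, data, tc)
    kt_fit <- finetune_student(pre, data, tc)
    n_kt <- mean(evaluate_fit(kt_fit, test_w)$nrmse)

    if (verbose) {
      message(sprintf("seed %d: teacher %.2f  student+KT %.2f  student %.2f",
                      seed, n_teacher, n_kt, n_nokt))
    }
    res <- rbind(res, data.frame(seed = seed, teacher = n_teacher,
                                 student_kt = n_kt, student_nokt = n_nokt))
  }
  res
}

#' Run a full leave-one-subject-out experiment
#'
#' Simulates (or takes) a dataset, builds LOSO folds and, per fold, trains
#' the teacher, runs the two knowledge-transfer steps for the student and
#' evaluates both on the fold's test subject; results are aggregated to
#' the package's reporting convention.
#'
#' @param cfg An [experiment_config()].
#' @param dataset Optional pre-built \code{gait_dataset}; simulated from
#'   \code{cfg$sim} when missing.
#' @param folds Optional subset of fold indices (all by default).
#' @param variants Additional ablation variants to train per fold
#'   (character vector of [student_variants()] / [teacher_variants()]
#'   names).
#' @param verbose Print fold progress.
#' @return List with per-model \code{gait_report}s (elements
#'   \code{teacher}, \code{student_kt}, plus one per extra variant) and
#'   the per-fold metric rows under \code{per_fold}.
#' @export
run_experiment <- function(cfg = experiment_config(), dataset = NULL,
                           folds = NULL, variants = character(0),
                           verbose = FALSE) {
  if (is.null(dataset)) dataset <- simulate_gait(cfg$sim)
  w <- window_dataset(dataset, stride = cfg$stride)
  subs <- sort(unique(w$subject))
  fold_list <- loso_folds(subs, seed = cfg$seed)
  if (!is.null(folds)) fold_list <- fold_list[folds]

  models <- c("teacher", "student_kt", variants)
  rows <- list()
  for (fi in seq_along(fold_list)) {
    fold <- fold_list[[fi]]
    if (verbose) message("fold ", fi, ": test subject ", fold$test_subject)
    fd <- fold_data(w, fold)
    test_w <- windows_for_subjects(w, fold$test_subject)
    sub_seed <- (cfg$seed * 131L + fi) %% 1000000L
    mc <- cfg$model
    mc$seed <- sub_seed
    tc <- cfg$train
    tc$seed <- sub_seed + 1L

    teacher_fit <- train_model(gait_model("imu_jcp_mfm", mc), fd, tc)
    pre <- pretrain_student_encoder(gait_model("aug_mfm_gate_bilstm_attngcn", mc),
                                    teacher_fit, fd, tc)
    kt_fit <- finetune_student(pre, fd, tc)
    fits <- list(teacher = teacher_fit, student_kt = kt_fit)
    for (vn in variants) {
      fits[[vn]] <- train_model(gait_model(vn, mc), fd, tc)
    }
    for (mn in names(fits)) {
      m <- evaluate_fit(fits[[mn]], test_w)
      m$subject <- fold$test_subject
      m$model <- mn
      rows[[length(rows) + 1L]] <- m
    }
  }
  per_fold <- do.call(rbind, rows)
  reports <- lapply(models, function(mn) {
    aggregate_report(per_fold[per_fold$model == mn, ])
  })
  names(reports) <- models
  c(reports, list(per_fold = per_fold))
}
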