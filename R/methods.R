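# S3 methods for the package's classed objects.

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic gait simulator configuration\n")
  cat(sprintf("  subjects: %d, trials each: %d, frames: %d @ %g Hz\n",
              x$n_subjects, x$trials_per_subject, x$trial_length,
              x$sampling_rate))
  cat(sprintf("  gait frequency: %.2f-%.2f Hz, %d harmonics\n",
              x$gait_frequency_range[1], x$gait_frequency_range[2],
              x$n_harmonics))
  cat(sprintf("  noise sd: camera %g, IMU %g, kinetics %g; subject effect %g\n",
              x$camera_noise_sd, x$imu_noise_sd, x$kinetics_noise_sd,
              x$subject_effect_sd))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

#' @export
print.gait_dataset <- function(x, ...) {
  nt <- sum(vapply(x, function(s) length(s$trials), integer(1)))
  cat(sprintf("Synthetic gait dataset: %d subjects, %d trials\n",
              length(x), nt))
  if (length(x) > 0) {
    cat(sprintf("  frames per trial: %d; channels: 44 video, 24+24 IMU, 5 kinetics\n",
                nrow(x[[1]]$trials[[1]]$cam)))
  }
  invisible(x)
}

#' @export
print.gait_windows <- function(x, ...) {
  cat(sprintf("Windowed gait samples: %d windows of %d frames (stride %d)\n",
              n_windows(x), x$window, x$stride))
  cat(sprintf("  subjects: %s\n",
              paste(sort(unique(x$subject)), collapse = ", ")))
  invisible(x)
}

#' @export
print.skeleton_graph <- function(x, ...) {
  cat(sprintf("Skeleton graph: %d joints, %d edges (row-normalized adjacency)\n",
              length(x$node_labels), nrow(x$edges)))
  cat("  joints:", paste(x$node_labels, collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.gait_model <- function(x, ...) {
  cat(sprintf("Gait-kinetics network '%s' (%s family)\n",
              x$variant, x$spec$family))
  cat(sprintf("  modalities: %s\n",
              paste(vapply(x$spec$modalities, paste, "", collapse = "+"),
                    collapse = ", ")))
  cat(sprintf("  encoder width: %d, parameters: %s\n", x$enc_width,
              format(n_params(x), big.mark = ",")))
  invisible(x)
}

#' @export
print.gait_fit <- function(x, ...) {
  cat(sprintf("Trained gait-kinetics model '%s'\n", x$variant))
  cat(sprintf("  epochs run: %d, best epoch: %d, best validation RMSE: %.4f\n",
              nrow(x$history), x$best_epoch, x$best_val_loss))
  if (isTRUE(x$knowledge_transfer)) {
    cat("  trained with two-step multi-modal knowledge transfer\n")
  }
  invisible(x)
}

#' @export
summary.gait_fit <- function(object, ...) {
  print(object)
  cat("\nTraining history (last epochs):\n")
  print(utils::tail(object$history, 5), row.names = FALSE)
  invisible(object)
}

#' @export
coef.gait_fit <- function(object, ...) gait_param_values(object)

#' @export
coef.gait_model <- function(object, ...) gait_param_values(object)

#' Predict kinetics for windowed samples
#'
#' @param object A \code{gait_fit}.
#' @param newdata A \code{gait_windows} set.
#' @param ... Unused.
#' @return Array [windows x frames x 5] of kinetics predictions (KAM, KFM,
#'   GRF ml/v/ap) in target units.
#' @export
predict.gait_fit <- function(object, newdata, ...) {
  predict_windows(object, newdata)
}

#' @export
residuals.gait_fit <- function(object, newdata, ...) {
  predict_windows(object, newdata) - newdata$kin
}

#' @export
plot.gait_fit <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("steelblue", "firebrick"),
                    xlab = "epoch", ylab = "RMSE loss", ...)
  graphics::legend("topright", c("training", "validation"), lty = 1,
                   col = c("steelblue", "firebrick"), bty = "n")
  graphics::abline(v = x$best_epoch, lty = 3)
  invisible(x)
}

#' @export
print.gait_report <- function(x, ...) {
  cat("Evaluation report (leave-one-subject-out)\n")
  cat(sprintf("  overall NRMSE: %.2f%% (sd %.2f), PCC: %.3f (sd %.3f)\n",
              x$overall$nrmse_mean, x$overall$nrmse_sd,
              x$overall$pcc_mean, x$overall$pcc_sd))
  cat("  per component:\n")
  bc <- x$by_component
  for (i in seq_len(nrow(bc))) {
    cat(sprintf("    %-7s NRMSE %5.2f%% +/- %.2f   PCC %.3f +/- %.3f\n",
                bc$component[i], bc$nrmse_mean[i], bc$nrmse_sd[i],
                bc$pcc_mean[i], bc$pcc_sd[i]))
  }
  invisible(x)
}

#' Plot predicted and measured kinetics over gait cycles
#'
#' Convenience plot of a stretch of frames of one subject: measured (dark)
#' and predicted (red) series per kinetic component.
#'
#' @param fit A \code{gait_fit}.
#' @param windows \code{gait_windows} of one subject.
#' @param frames How many frames to display.
#' @export
plot_gait_cycles <- function(fit, windows, frames = 200) {
  pred <- predict_windows(fit, windows)
  comps <- kinetics_names()
  old <- graphics::par(mfrow = c(5, 1), mar = c(2, 4, 1, 1))
  on.exit(graphics::par(old))
  for (k in 1:5) {
    tr <- as.vector(aperm(windows$kin[, , k], c(2, 1)))[seq_len(frames)]
    pr <- as.vector(aperm(pred[, , k], c(2, 1)))[seq_len(frames)]
    graphics::plot(tr, type = "l", col = "grey20", ylab = comps[k],
                   xlab = "", ylim = range(c(tr, pr)))
    graphics::lines(pr, col = "firebrick")
  }
  invisible(fit)
}
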