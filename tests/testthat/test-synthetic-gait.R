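# Synthetic multimodal gait generator: determinism, shape contracts, the
# linear forward model, windowing and padding.

test_that("identical configurations produce identical datasets", {
  cfg <- sim_config(n_subjects = 2, trials_per_subject = 1,
                    trial_length = 120, seed = 9)
  expect_identical(simulate_gait(cfg), simulate_gait(cfg))
  # and a different seed produces different data
  cfg2 <- sim_config(n_subjects = 2, trials_per_subject = 1,
                     trial_length = 120, seed = 10)
  expect_false(identical(simulate_gait(cfg)[[1]]$trials[[1]]$cam,
                         simulate_gait(cfg2)[[1]]$trials[[1]]$cam))
})

test_that("arrays have the documented shapes", {
  cfg <- sim_config(n_subjects = 2, trials_per_subject = 1,
                    trial_length = 600, seed = 3)
  ds <- simulate_gait(cfg)
  expect_length(ds, 2)
  trl <- ds[[1]]$trials[[1]]
  expect_identical(dim(trl$cam), c(600L, 44L))         # 11 joints x 2 cams x 2 axes
  expect_identical(dim(trl$imu_acc), c(600L, 24L))     # 8 IMUs x 3 axes
  expect_identical(dim(trl$imu_gyr), c(600L, 24L))
  expect_identical(dim(trl$kinetics), c(600L, 5L))
  expect_identical(colnames(trl$kinetics), c("kam", "kfm", "grf_ml", "grf_v", "grf_ap"))
})

test_that("camera channels are mid-hip centered and height-normalized", {
  trl <- tiny_dataset()[[1]]$trials[[1]]
  cn <- colnames(trl$cam)
  for (cam in c("cam1", "cam2")) {
    for (ax in c("x", "y")) {
      hips <- trl$cam[, paste0(cam, "_", c("l_hip", "r_hip"), "_", ax)]
      expect_lt(max(abs(rowMeans(hips))), 1e-9)
    }
  }
  # normalized positions are order-of-one body fractions, not metres
  expect_lt(max(abs(trl$cam)), 1.2)
})

test_that("with zero noise the kinetics equal the forward model recomputed from scratch", {
  ds <- clean_dataset()
  rec <- ds[[1]]
  trl <- rec$trials[[1]]
  expect_identical(trl$cam, trl$cam_true)
  # independent recomputation: plain matrix algebra on the stored arrays
  co <- rec$forward_coefficients
  vel <- derive_velocity(trl$cam_true, scale_by_rate = TRUE, sampling_rate = 100)
  k_oracle <- trl$cam_true %*% co$Cp + vel %*% co$Cv + trl$seg_acc %*% co$Ca
  expect_equal(unname(trl$kinetics), unname(k_oracle), tolerance = 1e-12)
})

test_that("the forward model is linear and exposes its coefficients", {
  set.seed(4)
  co <- clean_dataset()[[1]]$forward_coefficients
  Tn <- 20
  p <- matrix(rnorm(Tn * 44), Tn, 44)
  v <- matrix(rnorm(Tn * 44), Tn, 44)
  a <- matrix(rnorm(Tn * 24), Tn, 24)
  expect_true(all(forward_kinetics(p * 0, v * 0, a * 0, co) == 0))
  expect_equal(forward_kinetics(2 * p, 2 * v, 2 * a, co),
               2 * forward_kinetics(p, v, a, co))
  # unit impulse on one input channel reads back a coefficient column
  imp <- matrix(0, 1, 44); imp[1, 7] <- 1
  k <- forward_kinetics(imp, matrix(0, 1, 44), matrix(0, 1, 24), co)
  expect_equal(as.vector(k), co$Cp[7, ])
  imp_a <- matrix(0, 1, 24); imp_a[1, 3] <- 1
  k2 <- forward_kinetics(matrix(0, 1, 44), matrix(0, 1, 44), imp_a, co)
  expect_equal(as.vector(k2), co$Ca[3, ])
  expect_error(forward_kinetics(p, v[1:5, ], a, co), "same number of frames")
})

test_that("least squares on noise-free kinematics recovers the forward coefficients", {
  rec <- clean_dataset()[[1]]
  est <- recover_forward_coefficients(rec)
  tru <- rec$forward_coefficients
  scale <- max(abs(unlist(tru)))
  for (nm in c("Cp", "Cv", "Ca")) {
    expect_lt(max(abs(est[[nm]] - tru[[nm]])) / scale, 1e-6)
  }
})

test_that("IMU accelerations carry the privileged signal cameras cannot", {
  ds <- simulate_gait(sim_config(n_subjects = 1, trials_per_subject = 1,
                                 trial_length = 600, seed = 11))
  trl <- ds[[1]]$trials[[1]]
  aug <- augment(trl$cam, scale_by_rate = TRUE, sampling_rate = 100)
  # left-ankle sagittal acceleration: true signal vs IMU vs camera-derived
  true_ax <- trl$seg_acc[, 19]   # l_foot sensor, x axis
  r_imu <- cor(true_ax, trl$imu_acc[, 19])
  cam_col <- which(video_channel_names() == "cam1_l_ankle_x")
  r_cam <- cor(true_ax, aug$accelerations[, cam_col])
  expect_gt(r_imu, r_cam)
  expect_gt(r_imu, 0.99)
})

test_that("window counts, skipping and stride validation behave as specified", {
  mk <- function(len) simulate_gait(sim_config(n_subjects = 1,
                                               trials_per_subject = 1,
                                               trial_length = len, seed = 5))
  w1 <- window_dataset(mk(50), window = 50, stride = 50)
  expect_identical(length(w1$subject), 1L)
  w3 <- window_dataset(mk(152), window = 50, stride = 50)
  expect_identical(length(w3$subject), 3L)
  expect_identical(w3$start, c(1L, 51L, 101L))
  expect_error(window_dataset(mk(60), window = 50, stride = 0), "stride")
  # a 49-frame trial is skipped with a warning; with a long trial present
  # the remaining windows are still produced
  short <- mk(60)
  short[[1]]$trials[[1]]$cam <- short[[1]]$trials[[1]]$cam[1:49, ]
  expect_warning(expect_error(window_dataset(short), "no trial"), "skipped")
  both <- mk(120)
  both[[1]]$trials[[2]] <- lapply(both[[1]]$trials[[1]],
                                  function(m) m[1:49, , drop = FALSE])
  expect_warning(w <- window_dataset(both), "skipped")
  expect_true(all(w$trial == 1L))
})

test_that("windows carry all modalities with per-trial differencing", {
  w <- tiny_windows()
  expect_identical(dim(w$pos)[2:3], c(50L, 44L))
  expect_identical(dim(w$vel), dim(w$pos))
  expect_identical(dim(w$acc), dim(w$pos))
  expect_identical(dim(w$imu_acc)[2:3], c(50L, 24L))
  expect_identical(dim(w$kin)[2:3], c(50L, 5L))
  # velocity was derived per trial before windowing: the second window's
  # first frame is a cross-window difference, not zero
  second <- which(w$start == 51L)[1]
  expect_false(all(w$vel[second, 1, ] == 0))
  # while the very first window starts at the trial edge rule
  first <- which(w$start == 1L)[1]
  expect_true(all(w$vel[first, 1, ] == 0))
})

test_that("zero padding of steps round-trips", {
  m <- matrix(rnorm(100 * 3), 100, 3)
  p <- pad_step_to_length(m, 152)
  expect_identical(dim(p$data), c(152L, 3L))
  expect_true(all(p$data[101:152, ] == 0))
  expect_identical(trim_padded_step(p), m)
  same <- pad_step_to_length(matrix(1, 152, 2), 152)
  expect_identical(dim(same$data), c(152L, 2L))
  expect_error(pad_step_to_length(matrix(1, 153, 2), 152), "longer")
  # vectors work too
  pv <- pad_step_to_length(1:10, 15)
  expect_identical(trim_padded_step(pv), as.numeric(1:10))
})
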