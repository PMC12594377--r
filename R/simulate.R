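# Synthetic multimodal gait generator.
#
# Emulates the structure of the treadmill gait recordings the models are
# designed for: 11 joint centers seen by two smartphone cameras (sagittal
# and frontal, perspective projection, mid-hip origin, height-normalized),
# eight IMUs reporting 3-axis specific force and angular velocity, and five
# per-frame kinetics targets (KAM, KFM, 3-D GRF) produced by a known linear
# forward model with an IMU-privileged segment-acceleration term.

#' Simulator configuration
#'
#' @param n_subjects Number of simulated subjects.
#' @param trials_per_subject Trials recorded per subject.
#' @param trial_length Frames per trial (>= the 50-frame window).
#' @param sampling_rate Hz.
#' @param gait_frequency_range Stride-frequency range (Hz) subjects are
#'   drawn from.
#' @param n_harmonics Gait harmonics per joint path.
#' @param camera_noise_sd Gaussian camera noise, in height-normalized
#'   position units (0.005 corresponds to roughly 9 mm of pose-estimation
#'   jitter on a 1.76 m subject).
#' @param imu_noise_sd IMU noise (m/s^2 and rad/s).
#' @param kinetics_noise_sd Measurement noise on the kinetics targets.
#' @param subject_effect_sd Relative between-subject jitter applied to gait
#'   amplitudes and forward-model coefficients.
#' @param camera_distance Camera distance from the subject (m) for the
#'   perspective projection.
#' @param seed Integer seed; the full dataset is reproducible from the
#'   configuration alone.
#' @return Object of class \code{sim_config}.
#' @export
sim_config <- function(n_subjects = 10, trials_per_subject = 2,
                       trial_length = 600, sampling_rate = 100,
                       gait_frequency_range = c(0.8, 1.2), n_harmonics = 3,
                       camera_noise_sd = 0.005, imu_noise_sd = 0.02,
                       kinetics_noise_sd = 0.02, subject_effect_sd = 0.1,
                       camera_distance = 3, seed = 1L) {
  stopifnot(n_subjects >= 1, trials_per_subject >= 1, n_harmonics >= 1,
            sampling_rate > 0, length(gait_frequency_range) == 2,
            camera_noise_sd >= 0, imu_noise_sd >= 0, kinetics_noise_sd >= 0,
            subject_effect_sd >= 0)
  if (trial_length < 50) stop("trial_length must be at least the 50-frame window")
  structure(list(n_subjects = as.integer(n_subjects),
                 trials_per_subject = as.integer(trials_per_subject),
                 trial_length = as.integer(trial_length),
                 sampling_rate = sampling_rate,
                 gait_frequency_range = gait_frequency_range,
                 n_harmonics = as.integer(n_harmonics),
                 camera_noise_sd = camera_noise_sd,
                 imu_noise_sd = imu_noise_sd,
                 kinetics_noise_sd = kinetics_noise_sd,
                 subject_effect_sd = subject_effect_sd,
                 camera_distance = camera_distance,
                 seed = as.integer(seed)),
            class = "sim_config")
}

joint_names <- function() {
  c("head", "neck", "mid_hip", "l_shoulder", "r_shoulder", "l_hip", "r_hip",
    "l_knee", "r_knee", "l_ankle", "r_ankle")
}

imu_names <- function() {
  c("pelvis", "trunk", "l_thigh", "r_thigh", "l_shank", "r_shank",
    "l_foot", "r_foot")
}

# standing joint positions (m) for a 1.76 m reference subject; axes are
# x anterior, y vertical, z mediolateral (subject's left positive)
base_skeleton <- function() {
  m <- matrix(c(
    0.00, 1.68,  0.00,   # head
    0.00, 1.45,  0.00,   # neck
    0.00, 0.95,  0.00,   # mid_hip
    0.00, 1.42,  0.20,   # l_shoulder
    0.00, 1.42, -0.20,   # r_shoulder
    0.00, 0.95,  0.10,   # l_hip
    0.00, 0.95, -0.10,   # r_hip
    0.00, 0.50,  0.10,   # l_knee
    0.00, 0.50, -0.10,   # r_knee
    0.00, 0.08,  0.12,   # l_ankle
    0.00, 0.08, -0.12    # r_ankle
  ), ncol = 3, byrow = TRUE, dimnames = list(joint_names(), c("x", "y", "z")))
  m
}

# fundamental gait amplitude (m) per joint and axis at the reference height
base_amplitudes <- function() {
  m <- matrix(c(
    0.020, 0.015, 0.010,   # head
    0.020, 0.015, 0.010,   # neck
    0.030, 0.020, 0.020,   # mid_hip
    0.050, 0.020, 0.015,   # l_shoulder
    0.050, 0.020, 0.015,   # r_shoulder
    0.060, 0.020, 0.020,   # l_hip
    0.060, 0.020, 0.020,   # r_hip
    0.180, 0.040, 0.020,   # l_knee
    0.180, 0.040, 0.020,   # r_knee
    0.300, 0.060, 0.030,   # l_ankle
    0.300, 0.060, 0.030    # r_ankle
  ), ncol = 3, byrow = TRUE, dimnames = list(joint_names(), c("x", "y", "z")))
  m
}

# phase of the fundamental per joint (left and right side in antiphase,
# arms in antiphase with the ipsilateral leg)
base_phases <- function() {
  c(head = 0, neck = 0, mid_hip = 0,
    l_shoulder = pi, r_shoulder = 0,
    l_hip = 0, r_hip = pi, l_knee = 0, r_knee = pi,
    l_ankle = 0, r_ankle = pi)
}

# Every joint-axis path is a table of sinusoids:
#   p(t) = offset + sum_i amp_i * sin(2*pi*freq_i * t + phase_i)
# which keeps the analytic first and second derivatives exact.
eval_sinusoids <- function(tab, offset, t, deriv = 0) {
  out <- if (deriv == 0) rep(offset, length(t)) else numeric(length(t))
  for (i in seq_len(nrow(tab))) {
    w <- 2 * pi * tab$freq[i]
    ph <- w * t + tab$phase[i]
    out <- out + switch(as.character(deriv),
      "0" = tab$amp[i] * sin(ph),
      "1" = tab$amp[i] * w * cos(ph),
      "2" = -tab$amp[i] * w * w * sin(ph))
  }
  out
}

# perspective projection: cam = 1 sagittal (u = x, v = y, depth = z),
# cam = 2 frontal (u = z, v = y, depth = x); camera at distance D with a
# small fixed roll of the image plane (handheld phones are rarely level)
camera_rolls <- function() c(0.08, 0.20)

project_camera <- function(P3, cam, D) {
  if (cam == 1) {
    s <- D / (D - P3[, 3])
    u <- P3[, 1] * s
    v <- (P3[, 2] - 0.9) * s
  } else {
    s <- D / (D - P3[, 1])
    u <- P3[, 3] * s
    v <- (P3[, 2] - 0.9) * s
  }
  th <- camera_rolls()[cam]
  cbind(cos(th) * u - sin(th) * v, sin(th) * u + cos(th) * v)
}

# slow multiplicative scale jitter of a handheld camera (autofocus /
# camera-subject distance drift); a rigid image shift would be removed by
# the mid-hip re-centering, but scale jitter survives it
draw_zoom <- function() {
  data.frame(freq = stats::runif(2, 0.2, 1.5),
             amp = stats::runif(2, 0.002, 0.006),
             phase = stats::runif(2, 0, 2 * pi))
}

zoom_factor <- function(tab, t) 1 + eval_sinusoids(tab, 0, t, 0)

# mid-hip re-centering (per frame, per camera) and height normalization
normalize_views <- function(u1, v1, u2, v2, height, jn = joint_names()) {
  hip <- match(c("l_hip", "r_hip"), jn)
  ctr <- function(m) (m - rowMeans(m[, hip, drop = FALSE])) / height
  list(u1 = ctr(u1), v1 = ctr(v1), u2 = ctr(u2), v2 = ctr(v2))
}

#' Video channel names
#'
#' The 44 camera channels in the package's internal order:
#' coordinate-major (camera-1 horizontal, camera-1 vertical, camera-2
#' horizontal, camera-2 vertical), joints fastest, in [skeleton_graph()]
#' node order. This ordering lets the graph branch reshape a frame matrix
#' into node-major form without copying.
#' @return Character vector of length 44.
#' @export
video_channel_names <- function() {
  jn <- joint_names()
  c(paste0("cam1_", jn, "_x"), paste0("cam1_", jn, "_y"),
    paste0("cam2_", jn, "_x"), paste0("cam2_", jn, "_y"))
}

imu_channel_names <- function(kind = c("acc", "gyr")) {
  kind <- match.arg(kind)
  as.vector(t(outer(imu_names(), paste0(kind, c("_x", "_y", "_z")),
                    function(a, b) paste(a, b, sep = "_"))))
}

kinetics_names <- function() c("kam", "kfm", "grf_ml", "grf_v", "grf_ap")

#' Linear forward model mapping kinematics to kinetics
#'
#' Each kinetic component is a fixed linear combination of the
#' height-normalized camera positions, their velocities, and the true
#' segment accelerations (the privileged signal the IMUs observe):
#' \deqn{K = P C_p + V C_v + A C_a.}
#' The map is strictly linear (no intercept), so zero input gives zero
#' output and doubling all inputs doubles the kinetics.
#'
#' @param positions T x 44 matrix of camera positions.
#' @param velocities T x 44 matrix of their time derivatives.
#' @param accelerations T x 24 matrix of segment accelerations.
#' @param coefficients List with matrices \code{Cp} (44 x 5), \code{Cv}
#'   (44 x 5), \code{Ca} (24 x 5).
#' @return T x 5 kinetics matrix (KAM, KFM, GRF ml/v/ap).
#' @export
forward_kinetics <- function(positions, velocities, accelerations, coefficients) {
  positions <- as.matrix(positions); velocities <- as.matrix(velocities)
  accelerations <- as.matrix(accelerations)
  if (nrow(positions) != nrow(velocities) ||
      nrow(positions) != nrow(accelerations)) {
    stop("positions, velocities and accelerations must have the same number of frames")
  }
  if (ncol(positions) != nrow(coefficients$Cp) ||
      ncol(velocities) != nrow(coefficients$Cv) ||
      ncol(accelerations) != nrow(coefficients$Ca)) {
    stop("kinematic feature widths do not match the coefficient matrices")
  }
  k <- positions %*% coefficients$Cp + velocities %*% coefficients$Cv +
    accelerations %*% coefficients$Ca
  colnames(k) <- kinetics_names()
  k
}

# Channels of the right hip are exact mirrors of the left hip after mid-hip
# re-centering (l + r = 0 per frame by construction), so the forward model
# carries all hip weight on the left-hip channels; the mirrored rows stay
# zero and the remaining coefficients are identifiable by least squares.
mirrored_channels <- function() grep("_r_hip_", video_channel_names())

draw_base_coefficients <- function() {
  co <- list(Cp = matrix(stats::rnorm(44 * 5, 0, 0.40), 44, 5),
             Cv = matrix(stats::rnorm(44 * 5, 0, 0.25), 44, 5),
             Ca = matrix(stats::rnorm(24 * 5, 0, 0.06), 24, 5))
  co$Cp[mirrored_channels(), ] <- 0
  co$Cv[mirrored_channels(), ] <- 0
  co
}

#' Recover the forward-model coefficients by least squares
#'
#' With all simulator noise at zero the kinetics are an exact linear
#' function of the camera positions, their velocities and the segment
#' accelerations, and ordinary least squares on those features reproduces
#' the generating coefficients. The mirrored right-hip camera channels
#' (identically the negated left-hip channels after mid-hip centering) are
#' excluded from the design and their rows returned as zero, matching the
#' generator's parameterization.
#'
#' @param recording One subject recording from [simulate_gait()].
#' @param sampling_rate Hz (must match the simulation).
#' @return List with \code{Cp}, \code{Cv}, \code{Ca} shaped like
#'   \code{recording$forward_coefficients}.
#' @export
recover_forward_coefficients <- function(recording, sampling_rate = 100) {
  drop <- mirrored_channels()
  Xs <- list(); Ys <- list()
  for (trl in recording$trials) {
    vel <- derive_velocity(trl$cam_true, scale_by_rate = TRUE,
                           sampling_rate = sampling_rate)
    Xs[[length(Xs) + 1L]] <- cbind(trl$cam_true[, -drop, drop = FALSE],
                                   vel[, -drop, drop = FALSE], trl$seg_acc)
    Ys[[length(Ys) + 1L]] <- trl$kinetics
  }
  X <- do.call(rbind, Xs); Y <- do.call(rbind, Ys)
  B <- qr.coef(qr(X, LAPACK = TRUE), Y)
  nk <- 44L - length(drop)
  keep <- setdiff(seq_len(44L), drop)
  Cp <- matrix(0, 44, 5); Cv <- matrix(0, 44, 5)
  Cp[keep, ] <- B[seq_len(nk), ]
  Cv[keep, ] <- B[nk + seq_len(nk), ]
  list(Cp = Cp, Cv = Cv, Ca = B[2 * nk + seq_len(24L), , drop = FALSE])
}

# build one subject's sinusoid tables: shared gait harmonics plus a small
# channel-specific sinusoid that gives every joint-axis path an
# identifiable component of its own
subject_motion <- function(cfg, skel, amps, phases) {
  f <- stats::runif(1, cfg$gait_frequency_range[1], cfg$gait_frequency_range[2])
  jn <- joint_names()
  tabs <- vector("list", 33L)
  k <- seq_len(cfg$n_harmonics)
  idx <- 0L
  for (j in seq_along(jn)) {
    for (ax in 1:3) {
      idx <- idx + 1L
      amp_jit <- 1 + stats::rnorm(1, 0, cfg$subject_effect_sd)
      # vertical motion oscillates at twice the stride frequency
      ff <- if (ax == 2) 2 * f else f
      harm <- data.frame(
        freq = ff * k,
        amp = amps[j, ax] * amp_jit / k,
        phase = phases[j] + stats::runif(cfg$n_harmonics, -0.3, 0.3)
      )
      # channel-specific soft-tissue / impact-vibration components on a
      # jittered frequency grid: well-separated frequencies keep every
      # joint-axis path linearly identifiable from finite recordings
      slots <- (idx - 1L) * 3L + 1:3
      slot_w <- (12 - 0.5) / 99
      fi <- 0.5 + (slots - stats::runif(3, 0.2, 0.8)) * slot_w
      idio <- data.frame(
        freq = fi,
        amp = stats::runif(3, 0.015, 0.03) / fi *
          (1 + stats::rnorm(1, 0, cfg$subject_effect_sd)),
        phase = stats::runif(3, 0, 2 * pi)
      )
      tabs[[idx]] <- rbind(harm, idio)
    }
  }
  list(freq = f, tabs = tabs)
}

# evaluate all 33 joint-axis paths at times t (+ derivatives)
motion_matrix <- function(motion, skel, scale, t, deriv = 0) {
  out <- matrix(0, length(t), 33L)
  idx <- 0L
  for (j in 1:11) {
    for (ax in 1:3) {
      idx <- idx + 1L
      off <- if (deriv == 0) skel[j, ax] * scale else 0
      out[, idx] <- eval_sinusoids(motion$tabs[[idx]], off, t, deriv)
    }
  }
  out
}

col3 <- function(m, j) m[, (j - 1L) * 3L + 1:3, drop = FALSE]

# angular velocity of each IMU's segment vector: w = (s x s') / |s|^2
segment_gyro <- function(P, V) {
  segs <- list(pelvis = c("mid_hip", "neck"), trunk = c("neck", "head"),
               l_thigh = c("l_hip", "l_knee"), r_thigh = c("r_hip", "r_knee"),
               l_shank = c("l_knee", "l_ankle"), r_shank = c("r_knee", "r_ankle"),
               l_foot = c("l_knee", "l_ankle"), r_foot = c("r_knee", "r_ankle"))
  jn <- joint_names()
  out <- matrix(0, nrow(P), 24L)
  for (i in seq_along(segs)) {
    a <- match(segs[[i]][1], jn); b <- match(segs[[i]][2], jn)
    s <- col3(P, b) - col3(P, a)
    sd1 <- col3(V, b) - col3(V, a)
    cx <- s[, 2] * sd1[, 3] - s[, 3] * sd1[, 2]
    cy <- s[, 3] * sd1[, 1] - s[, 1] * sd1[, 3]
    cz <- s[, 1] * sd1[, 2] - s[, 2] * sd1[, 1]
    n2 <- rowSums(s * s)
    out[, (i - 1L) * 3L + 1:3] <- cbind(cx, cy, cz) / n2
  }
  out
}

simulate_trial <- function(cfg, motion, skel, height, coef) {
  Tn <- cfg$trial_length
  t <- (seq_len(Tn) - 1L) / cfg$sampling_rate + stats::runif(1, 0, 10)
  scale <- height / 1.76
  P <- motion_matrix(motion, skel, scale, t, 0)       # T x 33 true 3-D paths
  V <- motion_matrix(motion, skel, scale, t, 1)
  Acc <- motion_matrix(motion, skel, scale, t, 2)

  P3 <- function(j) P[, (j - 1L) * 3L + 1:3, drop = FALSE]
  D <- cfg$camera_distance
  proj <- function(cam) {
    zf <- zoom_factor(draw_zoom(), t)
    u <- matrix(0, Tn, 11L); v <- matrix(0, Tn, 11L)
    for (j in 1:11) {
      pc <- project_camera(P3(j), cam, D)
      u[, j] <- pc[, 1] * zf; v[, j] <- pc[, 2] * zf
    }
    list(u = u, v = v)
  }
  c1 <- proj(1); c2 <- proj(2)

  noisy <- function(m) m + matrix(stats::rnorm(length(m), 0, cfg$camera_noise_sd * height),
                                  nrow(m), ncol(m))
  nv <- normalize_views(noisy(c1$u), noisy(c1$v), noisy(c2$u), noisy(c2$v), height)
  cam <- cbind(nv$u1, nv$v1, nv$u2, nv$v2)
  nv0 <- normalize_views(c1$u, c1$v, c2$u, c2$v, height)
  cam_true <- cbind(nv0$u1, nv0$v1, nv0$u2, nv0$v2)
  colnames(cam) <- colnames(cam_true) <- video_channel_names()

  # IMU sites sit on the joints listed in imu_names() order
  imu_joints <- match(c("mid_hip", "neck", "l_hip", "r_hip", "l_knee",
                        "r_knee", "l_ankle", "r_ankle"), joint_names())
  seg_acc <- do.call(cbind, lapply(imu_joints, function(j) col3(Acc, j)))
  imu_acc <- seg_acc
  imu_acc[, seq(2, 24, by = 3)] <- imu_acc[, seq(2, 24, by = 3)] + 9.81
  imu_acc <- imu_acc + matrix(stats::rnorm(length(imu_acc), 0, cfg$imu_noise_sd),
                              Tn, 24L)
  imu_gyr <- segment_gyro(P, V) +
    matrix(stats::rnorm(Tn * 24L, 0, cfg$imu_noise_sd), Tn, 24L)
  colnames(imu_acc) <- imu_channel_names("acc")
  colnames(imu_gyr) <- imu_channel_names("gyr")

  cam_vel_true <- derive_velocity(cam_true, scale_by_rate = TRUE,
                                  sampling_rate = cfg$sampling_rate)
  kin_true <- forward_kinetics(cam_true, cam_vel_true, seg_acc, coef)
  kin <- kin_true + matrix(stats::rnorm(Tn * 5L, 0, cfg$kinetics_noise_sd), Tn, 5L)
  colnames(kin) <- kinetics_names()

  list(cam = cam, cam_true = cam_true, imu_acc = imu_acc, imu_gyr = imu_gyr,
       seg_acc = seg_acc, kinetics = kin, kinetics_true = kin_true,
       joint_paths = P)
}

#' Generate a synthetic multimodal gait dataset
#'
#' Simulates \code{n_subjects} treadmill-walking subjects. Each subject has
#' their own stature, stride frequency, jittered gait-harmonic amplitudes
#' and jittered forward-model coefficients; each trial adds camera noise,
#' IMU noise and kinetics measurement noise. The full dataset is
#' reproducible from the configuration seed.
#'
#' @param cfg A [sim_config()].
#' @return Object of class \code{gait_dataset}: a list of subject
#'   recordings, each with fields \code{subject_id}, \code{height},
#'   \code{mass}, \code{gait_frequency}, \code{forward_coefficients} and
#'   \code{trials} (camera channels, IMU channels, kinetics, plus the
#'   noise-free ground-truth arrays).
#' @export
simulate_gait <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  restore <- local_rng(cfg$seed)
  on.exit(restore())
  skel <- base_skeleton(); amps <- base_amplitudes(); phases <- base_phases()
  base_coef <- draw_base_coefficients()
  subjects <- vector("list", cfg$n_subjects)
  for (s in seq_len(cfg$n_subjects)) {
    height <- stats::rnorm(1, 1.76, 0.06)
    mass <- stats::rnorm(1, 67.3, 8.3)
    motion <- subject_motion(cfg, skel, amps, phases)
    coef <- lapply(base_coef, function(m) {
      m * (1 + matrix(stats::rnorm(length(m), 0, cfg$subject_effect_sd),
                      nrow(m), ncol(m)))
    })
    trials <- vector("list", cfg$trials_per_subject)
    for (tr in seq_len(cfg$trials_per_subject)) {
      trials[[tr]] <- simulate_trial(cfg, motion, skel, height, coef)
    }
    subjects[[s]] <- list(subject_id = sprintf("S%02d", s), height = height,
                          mass = mass, gait_frequency = motion$freq,
                          forward_coefficients = coef, trials = trials)
  }
  structure(subjects, class = "gait_dataset", config = cfg)
}

#' @export
generate_dataset <- simulate_gait

#' Cut a dataset into fixed-length windows
#'
#' Half-open windows \code{[t, t + window)} at the given stride. Velocity
#' and acceleration modalities are derived per trial (before windowing)
#' from the noisy camera channels with [augment()].
#'
#' @param dataset A \code{gait_dataset} (or list of subject recordings).
#' @param window Window length in frames.
#' @param stride Step between window starts; defaults to \code{window}
#'   (non-overlapping).
#' @param scale_by_rate Passed to [augment()].
#' @return Object of class \code{gait_windows}: arrays \code{pos},
#'   \code{vel}, \code{acc} (N x window x 44), \code{imu_acc},
#'   \code{imu_gyr} (N x window x 24), \code{kin} (N x window x 5), and
#'   per-window \code{subject}, \code{trial}, \code{start} labels.
#' @export
window_dataset <- function(dataset, window = 50, stride = window,
                           scale_by_rate = FALSE) {
  if (stride <= 0) stop("stride must be positive")
  if (window < 3) stop("window must be at least 3 frames")
  window <- as.integer(window)
  stride <- as.integer(stride)
  rows <- list()
  for (rec in dataset) {
    for (tr in seq_along(rec$trials)) {
      Tn <- nrow(rec$trials[[tr]]$cam)
      if (Tn < window) {
        warning(sprintf("trial %d of subject %s has %d < %d frames; skipped",
                        tr, rec$subject_id, Tn, window))
        next
      }
      starts <- seq(1L, Tn - window + 1L, by = stride)
      rows[[length(rows) + 1L]] <- list(rec = rec, tr = tr, starts = starts)
    }
  }
  n <- sum(vapply(rows, function(r) length(r$starts), integer(1)))
  if (n == 0) stop("no trial long enough for the requested window")
  sr <- attr(dataset, "config")$sampling_rate
  if (is.null(sr)) sr <- 100
  pos <- array(0, c(n, window, 44L)); vel <- pos; acc <- pos
  iacc <- array(0, c(n, window, 24L)); igyr <- iacc
  kin <- array(0, c(n, window, 5L))
  subject <- character(n); trial <- integer(n); start <- integer(n)
  i <- 0L
  for (r in rows) {
    trl <- r$rec$trials[[r$tr]]
    aug <- augment(trl$cam, scale_by_rate = scale_by_rate, sampling_rate = sr)
    for (s0 in r$starts) {
      i <- i + 1L
      sl <- s0:(s0 + window - 1L)
      pos[i, , ] <- aug$positions[sl, ]
      vel[i, , ] <- aug$velocities[sl, ]
      acc[i, , ] <- aug$accelerations[sl, ]
      iacc[i, , ] <- trl$imu_acc[sl, ]
      igyr[i, , ] <- trl$imu_gyr[sl, ]
      kin[i, , ] <- trl$kinetics[sl, ]
      subject[i] <- r$rec$subject_id
      trial[i] <- r$tr
      start[i] <- s0
    }
  }
  structure(list(pos = pos, vel = vel, acc = acc, imu_acc = iacc,
                 imu_gyr = igyr, kin = kin, subject = subject, trial = trial,
                 start = start, window = as.integer(window),
                 stride = as.integer(stride)),
            class = "gait_windows")
}

#' Pad a step to a fixed length with trailing zeros
#'
#' Steps shorter than the longest step in a recording session are
#' zero-padded at the end to a common length (default 152 frames); the
#' padding is removed again with [trim_padded_step()].
#'
#' @param step Matrix (frames x channels) or vector.
#' @param target_length Padded length.
#' @return Object of class \code{padded_step} with fields \code{data} and
#'   \code{true_length}.
#' @export
pad_step_to_length <- function(step, target_length = 152) {
  vec <- is.null(dim(step))
  m <- if (vec) matrix(step, ncol = 1) else as.matrix(step)
  Tn <- nrow(m)
  if (Tn > target_length) {
    stop(sprintf("step has %d frames, longer than the target length %d",
                 Tn, target_length))
  }
  out <- rbind(m, matrix(0, target_length - Tn, ncol(m)))
  structure(list(data = if (vec) out[, 1] else out, true_length = Tn,
                 vector_input = vec),
            class = "padded_step")
}

#' @rdname pad_step_to_length
#' @param padded A \code{padded_step}.
#' @export
trim_padded_step <- function(padded) {
  stopifnot(inherits(padded, "padded_step"))
  if (padded$vector_input) {
    padded$data[seq_len(padded$true_length)]
  } else {
    padded$data[seq_len(padded$true_length), , drop = FALSE]
  }
}
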