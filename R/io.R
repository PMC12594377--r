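# Dataset and configuration I/O: one directory per subject, one CSV per
# trial with labelled columns, plus a JSON metadata sidecar per subject.

trial_table <- function(trial) {
  cam <- trial$cam
  # CSV columns are grouped per joint for readability; the loader maps
  # columns by name, so on-disk order is free
  df <- data.frame(cam, trial$imu_acc, trial$imu_gyr, trial$kinetics,
                   check.names = FALSE)
  names(df) <- c(colnames(cam), imu_channel_names("acc"),
                 imu_channel_names("gyr"), kinetics_names())
  df
}

fmt17 <- function(x) sprintf("%.17g", x)

#' Save a gait dataset to disk
#'
#' Writes one directory per subject containing \code{trial_XX.csv} files
#' (44 camera channels, 24 + 24 IMU channels, 5 kinetics columns) and a
#' \code{subject.json} sidecar (id, stature, mass, sampling rate, seed and
#' forward-model coefficients). Numbers are written with 17 significant
#' digits so a load round-trips bit-exactly.
#'
#' @param dataset A \code{gait_dataset}.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
save_gait_dataset <- function(dataset, dir) {
  cfg <- attr(dataset, "config")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (rec in dataset) {
    sdir <- file.path(dir, rec$subject_id)
    dir.create(sdir, showWarnings = FALSE)
    meta <- list(subject_id = rec$subject_id, height = fmt17(rec$height),
                 mass = fmt17(rec$mass),
                 gait_frequency = fmt17(rec$gait_frequency),
                 sampling_rate = cfg$sampling_rate, seed = cfg$seed,
                 forward_coefficients = lapply(rec$forward_coefficients,
                                               function(m) apply(m, 1:2, fmt17)))
    jsonlite::write_json(meta, file.path(sdir, "subject.json"),
                         auto_unbox = TRUE)
    for (tr in seq_along(rec$trials)) {
      df <- trial_table(rec$trials[[tr]])
      df[] <- lapply(df, fmt17)
      utils::write.csv(df, file.path(sdir, sprintf("trial_%02d.csv", tr)),
                       row.names = FALSE, quote = FALSE)
    }
  }
  invisible(dir)
}

#' Load a gait dataset from disk
#'
#' Reads the layout written by [save_gait_dataset()], mapping columns by
#' name, validating the channel roster and the mid-hip origin invariant of
#' the camera channels. Ground-truth arrays (noise-free camera channels,
#' segment accelerations) are not stored on disk and are absent from the
#' loaded recordings.
#'
#' @param dir Dataset directory.
#' @param tol Tolerance for the mid-hip origin check.
#' @return A \code{gait_dataset} (subjects sorted by id).
#' @export
load_gait_dataset <- function(dir, tol = 1e-8) {
  sdirs <- sort(list.dirs(dir, recursive = FALSE))
  if (length(sdirs) == 0) stop("no subject directories found in ", dir)
  want <- c(video_channel_names(), imu_channel_names("acc"),
            imu_channel_names("gyr"), kinetics_names())
  sampling_rate <- NULL
  seed <- NULL
  subjects <- lapply(sdirs, function(sdir) {
    mf <- file.path(sdir, "subject.json")
    if (!file.exists(mf)) stop("missing subject.json in ", sdir)
    meta <- jsonlite::read_json(mf)
    sampling_rate <<- meta$sampling_rate
    seed <<- meta$seed
    coef <- lapply(meta$forward_coefficients, function(m) {
      do.call(rbind, lapply(m, function(row) as.numeric(unlist(row))))
    })
    files <- sort(list.files(sdir, pattern = "^trial_\\d+\\.csv$",
                             full.names = TRUE))
    trials <- lapply(files, function(f) {
      df <- utils::read.csv(f, check.names = FALSE,
                            colClasses = "numeric")
      missing <- setdiff(want, names(df))
      if (length(missing) > 0) {
        stop("file ", f, " is missing columns: ",
             paste(utils::head(missing, 5), collapse = ", "))
      }
      cam <- as.matrix(df[, video_channel_names()])
      hip <- cam[, grep("_(l|r)_hip_", colnames(cam))]
      for (cc in c("cam1", "cam2")) {
        for (ax in c("x", "y")) {
          cols <- paste0(cc, "_", c("l_hip", "r_hip"), "_", ax)
          if (max(abs(rowMeans(cam[, cols]))) > tol) {
            stop("file ", f, ": camera channels are not mid-hip centered")
          }
        }
      }
      list(cam = cam,
           imu_acc = as.matrix(df[, imu_channel_names("acc")]),
           imu_gyr = as.matrix(df[, imu_channel_names("gyr")]),
           kinetics = as.matrix(df[, kinetics_names()]))
    })
    list(subject_id = meta$subject_id, height = as.numeric(meta$height),
         mass = as.numeric(meta$mass),
         gait_frequency = as.numeric(meta$gait_frequency),
         forward_coefficients = coef, trials = trials)
  })
  ids <- vapply(subjects, function(s) s$subject_id, character(1))
  subjects <- subjects[order(ids)]
  cfg <- list(sampling_rate = sampling_rate, seed = seed)
  structure(subjects, class = "gait_dataset", config = cfg)
}

#' Experiment configuration
#'
#' Bundle of the simulator, model, training and distillation
#' configurations plus evaluation options; serialises losslessly to YAML.
#'
#' @param sim [sim_config()].
#' @param model [model_config()].
#' @param train [train_config()].
#' @param kd [kd_config()].
#' @param stride Window stride for evaluation datasets.
#' @param seed Global experiment seed (drives per-fold sub-seeds).
#' @return Object of class \code{gait_experiment_config}.
#' @export
experiment_config <- function(sim = sim_config(), model = model_config(),
                              train = train_config(), kd = kd_config(),
                              stride = 50L, seed = 1L) {
  structure(list(sim = sim, model = model, train = train, kd = kd,
                 stride = as.integer(stride), seed = as.integer(seed)),
            class = "gait_experiment_config")
}

#' Write / read an experiment configuration as YAML
#'
#' @param cfg A [experiment_config()].
#' @param path YAML file path.
#' @return \code{read_experiment_config} returns the reconstructed
#'   \code{gait_experiment_config}.
#' @export
write_experiment_config <- function(cfg, path) {
  plain <- list(
    sim = unclass(cfg$sim),
    model = c(unclass(cfg$model)[setdiff(names(cfg$model), "graph")],
              list(graph_nodes = cfg$model$graph$node_labels)),
    train = unclass(cfg$train),
    kd = unclass(cfg$kd),
    stride = cfg$stride, seed = cfg$seed
  )
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname write_experiment_config
#' @export
read_experiment_config <- function(path) {
  y <- yaml::read_yaml(path)
  graph <- if (!is.null(y$model$graph_nodes)) {
    skeleton_graph(unlist(y$model$graph_nodes))
  } else skeleton_graph()
  y$model$graph_nodes <- NULL
  y$model$graph <- graph
  y$model$mfm_submodules <- unlist(y$model$mfm_submodules)
  y$sim$gait_frequency_range <- unlist(y$sim$gait_frequency_range)
  experiment_config(
    sim = do.call(sim_config, y$sim[setdiff(names(y$sim), character(0))]),
    model = do.call(model_config, y$model),
    train = do.call(train_config, y$train),
    kd = do.call(kd_config, y$kd),
    stride = y$stride, seed = y$seed
  )
}
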