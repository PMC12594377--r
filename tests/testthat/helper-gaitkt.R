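# Shared fixtures: all data are generated in code, at small sizes.

`%||%` <- function(a, b) if (is.null(a)) b else a

# tiny noisy dataset reused across tests (3 subjects, short trials)
tiny_dataset <- local({
  ds <- NULL
  function() {
    if (is.null(ds)) {
      ds <<- simulate_gait(sim_config(n_subjects = 3, trials_per_subject = 1,
                                      trial_length = 150, seed = 42))
    }
    ds
  }
})

tiny_windows <- local({
  w <- NULL
  function() {
    if (is.null(w)) w <<- window_dataset(tiny_dataset())
    w
  }
})

# noise-free dataset for forward-model checks
clean_dataset <- local({
  ds <- NULL
  function() {
    if (is.null(ds)) {
      ds <<- simulate_gait(sim_config(n_subjects = 2, trials_per_subject = 1,
                                      trial_length = 300, camera_noise_sd = 0,
                                      imu_noise_sd = 0, kinetics_noise_sd = 0,
                                      seed = 7))
    }
    ds
  }
})

# small model configuration used wherever architecture, not accuracy,
# is under test
tiny_model_config <- function(seed = 1) {
  model_config(hidden_dim = 8, gcn_node_out = 4, projection_dim = 8,
               head_hidden = 8, dropout = 0.2, seed = seed)
}

tiny_train_config <- function(epochs = 2, patience = epochs, seed = 1, ...) {
  train_config(epochs = epochs, patience = patience, batch_size = 8,
               seed = seed, ...)
}

# build a frame-matrix batch straight from a window set
tiny_batch <- function(model, windows = tiny_windows(), idx = 1:4) {
  gaitkt:::batch_frames(windows, idx, gaitkt:::model_sources(model))
}

# subject-keyed train/val/test split used by the smoke-scale training tests
subject_split <- function(w, n_train = NULL) {
  subs <- sort(unique(w$subject))
  ns <- length(subs)
  list(
    data = list(
      train = gaitkt:::windows_for_subjects(w, subs[seq_len(ns - 2L)]),
      val = gaitkt:::windows_for_subjects(w, subs[ns - 1L])
    ),
    test = gaitkt:::windows_for_subjects(w, subs[ns])
  )
}

# central-difference numeric gradient
numeric_gradient <- function(f, x, eps = 1e-6) {
  g <- x
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}
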