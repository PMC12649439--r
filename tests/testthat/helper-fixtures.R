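# Shared fixtures, all generated in code.

# Small separable world: three gestures with disjoint active channels and
# full-repetition activation, so windows are linearly separable.
separable_bank <- function(n_gestures = 3, n_channels = 4) {
  bank <- lapply(seq_len(n_gestures), function(g) {
    prof <- data.frame(
      onset_fraction = rep(0, n_channels),
      duration_fraction = rep(0.95, n_channels),
      peak_amplitude = rep(0, n_channels),
      shape = rep("trapezoid", n_channels),
      stringsAsFactors = FALSE
    )
    prof$peak_amplitude[(g - 1) %% n_channels + 1] <- 6
    gesture_template(sprintf("G%02d", g), prof, baseline_amplitude = 0.3)
  })
  names(bank) <- vapply(bank, function(t) t$gesture_id, character(1))
  structure(bank, class = "gesture_bank")
}

# The identity phenotype: no jitter, mixing, noise or drift.
identity_phenotype <- function(user_id = "U01", n_channels = 4) {
  user_phenotype(user_id, gains = rep(1, n_channels), timing_jitter_sd = 0,
                 channel_mixing = diag(n_channels), noise_sd = 0,
                 drift_amplitude = 0)
}

# A small trained artifact for streaming / registry tests (cached per
# session; ~2 s to build).
cached_artifact <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    bank <- make_gesture_bank(3, 4, seed = 7)
    ph <- sample_phenotypes(1, 1, seed = 3)
    # 2 s repetitions: 100 samples, five 32-sample windows per repetition —
    # several tests rely on these counts
    cfg <- sim_config(repetition_duration = 2, rng_seed = 9)
    ds <- synthesize_dataset(bank, ph, 5, cfg)
    scaler <- fit_scaler(ds$recordings)
    batch <- bind_batches(lapply(ds$recordings, function(r) {
      segment_windows(apply_scaler(r, scaler), windowing_config())
    }))
    res <- train(batch, scaler,
                 train_cfg = train_config(seed = 2, max_epochs = 12))
    cache <<- list(artifact = res$artifact, report = res$report,
                   dataset = ds, scaler = scaler, batch = batch)
    cache
  }
})

# Independent oracle for window-count checks: brute-force enumeration of
# admissible start indices.
brute_force_starts <- function(n_samples, window_len, stride) {
  starts <- integer(0)
  s <- 1L
  while (s + window_len - 1L <= n_samples) {
    starts <- c(starts, s)
    s <- s + stride
  }
  starts
}

# Independent oracle for classifier sanity: nearest centroid on flattened
# windows.
nearest_centroid_accuracy <- function(train_w, train_y, test_w, test_y) {
  flat <- function(w) matrix(w, nrow = dim(w)[1])
  Xtr <- flat(train_w); Xte <- flat(test_w)
  classes <- sort(unique(train_y))
  centroids <- t(vapply(classes, function(cl) {
    colMeans(Xtr[train_y == cl, , drop = FALSE])
  }, numeric(ncol(Xtr))))
  pred <- classes[apply(Xte, 1, function(x) {
    which.min(colSums((t(centroids) - x)^2))
  })]
  mean(pred == test_y)
}
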