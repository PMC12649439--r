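test_that("model configuration enforces the two-conv five-dense contract", {
  cfg <- model_config(4, 3)
  expect_identical(cfg$dense_widths, c(256L, 128L, 64L, 32L, 3L))
  expect_error(model_config(4, 3, conv_blocks = list(c(32, 3, 2))),
               "exactly 2")
  expect_error(model_config(4, 3, dense_widths = c(64, 32, 3)), "exactly 5")
  expect_error(model_config(4, 4, dense_widths = c(64, 32, 16, 8, 3)),
               "must equal n_classes")
  expect_error(model_config(4, 3, window_len = 6), "minimum")
})

test_that("forward pass satisfies the shape contract", {
  cfg <- model_config(4, 3)
  m <- build_model(cfg, seed = 1)
  with_seed(1, {
    X <- array(rnorm(8 * 4 * 32), dim = c(8, 4, 32))
  })
  logits <- gesturekit:::cnn_forward(m, X)
  expect_equal(dim(logits), c(8, 3))
  # single-class degenerate model
  m1 <- build_model(model_config(4, 1, dense_widths = c(16, 8, 8, 4, 1)),
                    seed = 1)
  expect_equal(dim(gesturekit:::cnn_forward(m1, X)), c(8, 1))
})

test_that("initialization is deterministic under the seed", {
  cfg <- model_config(4, 3)
  expect_identical(build_model(cfg, seed = 42)$params,
                   build_model(cfg, seed = 42)$params)
  expect_false(identical(build_model(cfg, seed = 42)$params,
                         build_model(cfg, seed = 43)$params))
})

test_that("growing the class count only resizes the final dense layer", {
  p3 <- build_model(model_config(4, 3), seed = 1)$params
  p5 <- build_model(model_config(4, 5), seed = 1)$params
  for (nm in setdiff(names(p3), c("Wd5", "bd5"))) {
    expect_identical(dim(p3[[nm]]), dim(p5[[nm]]))
  }
  expect_identical(ncol(p5$Wd5), 5L)
})

test_that("analytic gradients match numerical differentiation", {
  cfg <- model_config(2, 3, window_len = 16,
                      conv_blocks = list(c(4L, 3L, 2L), c(5L, 3L, 2L)),
                      dense_widths = c(16L, 12L, 8L, 6L, 3L))
  m <- build_model(cfg, seed = 3)
  with_seed(2, {
    X <- array(rnorm(4 * 2 * 16), dim = c(4, 2, 16))
  })
  y <- c(0L, 1L, 2L, 1L)
  lg <- gesturekit:::cnn_loss_grads(m, X, y)
  eps <- 1e-6
  with_seed(3, {
    for (nm in names(m$params)) {
      for (i in sample(length(m$params[[nm]]), min(4, length(m$params[[nm]])))) {
        m2 <- m
        m2$params[[nm]][i] <- m$params[[nm]][i] + eps
        up <- gesturekit:::cnn_loss_grads(m2, X, y)$loss
        m2$params[[nm]][i] <- m$params[[nm]][i] - eps
        dn <- gesturekit:::cnn_loss_grads(m2, X, y)$loss
        expect_equal(lg$grads[[nm]][i], (up - dn) / (2 * eps),
                     tolerance = 1e-4)
      }
    }
  })
})

test_that("the early-stopping rule binds at min_epochs and on patience", {
  # loss improves once then plateaus: patience exhausts before min_epochs,
  # so the minimum binds and training stops exactly there
  losses <- c(1.0, 0.9, rep(0.9, 18))
  dec <- gesturekit:::stopping_point(losses, patience = 3, min_epochs = 10,
                                     max_epochs = 200)
  expect_identical(dec$stopped_epoch, 10L)
  expect_identical(dec$stop_reason, "early_stop")
  # steadily improving: runs to max_epochs
  dec2 <- gesturekit:::stopping_point(seq(1, 0.1, length.out = 20),
                                      patience = 3, min_epochs = 10,
                                      max_epochs = 20)
  expect_identical(dec2$stop_reason, "max_epochs")
  # plateau after min_epochs: stops patience epochs past the best
  losses3 <- c(seq(1, 0.5, length.out = 12), rep(0.5, 10))
  dec3 <- gesturekit:::stopping_point(losses3, patience = 4, min_epochs = 10,
                                      max_epochs = 200)
  expect_identical(dec3$stopped_epoch, 16L)
  expect_identical(dec3$stop_reason, "early_stop")
})

test_that("training is reproducible and restores the best epoch", {
  fx <- cached_artifact()
  tcfg <- train_config(seed = 31, max_epochs = 14)
  r1 <- train(fx$batch, fx$scaler, train_cfg = tcfg)
  r2 <- train(fx$batch, fx$scaler, train_cfg = tcfg)
  expect_identical(r1$report$val_loss, r2$report$val_loss)
  expect_identical(r1$artifact$weights, r2$artifact$weights)
  expect_lte(r1$report$best_val_loss, min(r1$report$val_loss) + 1e-12)
  expect_gte(r1$report$stopped_epoch, tcfg$min_epochs)
  expect_length(r1$report$val_loss, r1$report$stopped_epoch)
})

test_that("training rejects unsplittable or missing classes", {
  fx <- cached_artifact()
  b <- fx$batch
  keep <- which(b$labels != b$labels[1])[1] # a single window of one class
  small <- window_batch(b$windows[c(1, keep), , , drop = FALSE],
                        b$labels[c(1, keep)], b$user_id)
  expect_error(train(small, fx$scaler), "fewer than 2")
  expect_error(train(b, fx$scaler, class_levels = c(unique(b$labels), "GX")),
               "absent.*GX")
})

test_that("a separable three-gesture problem reaches the centroid oracle", {
  bank <- separable_bank(3)
  ph <- sample_phenotypes(1, 1, seed = 17, base_noise_sd = 0.2)
  cfg <- sim_config(rng_seed = 23)
  ds <- synthesize_dataset(bank, ph, 5, cfg)
  sc <- fit_scaler(ds$recordings)
  batch <- bind_batches(lapply(ds$recordings, function(r) {
    segment_windows(apply_scaler(r, sc), windowing_config())
  }))
  res <- train(batch, sc, train_cfg = train_config(seed = 5, max_epochs = 25))
  sp <- gesturekit:::stratified_split(batch$labels, 0.2, 5)
  oracle <- nearest_centroid_accuracy(
    batch$windows[sp$train, , , drop = FALSE], batch$labels[sp$train],
    batch$windows[sp$val, , , drop = FALSE], batch$labels[sp$val])
  expect_gte(res$report$best_val_accuracy, oracle - 0.01)
  expect_gte(res$report$best_val_accuracy, 0.95)
})

test_that("prediction is a pure function with normalized probabilities", {
  fx <- cached_artifact()
  w <- fx$batch$windows[3, , ]
  p1 <- predict_window(fx$artifact, w)
  p2 <- predict_window(fx$artifact, w)
  expect_identical(p1, p2)
  expect_equal(sum(p1$probabilities), 1, tolerance = 1e-9)
  expect_identical(p1$label, names(which.max(p1$probabilities)))
  expect_error(predict_window(fx$artifact, w[1:2, ]), "shape mismatch")
})

test_that("artifact save/load round-trips predictions exactly", {
  fx <- cached_artifact()
  f <- withr::local_tempfile(fileext = ".json")
  save_artifact(fx$artifact, f)
  back <- load_artifact(f)
  expect_identical(back$gesture_map, fx$artifact$gesture_map)
  expect_equal(back$scaler$mean, fx$artifact$scaler$mean)
  expect_identical(back$sensor_config$n_channels,
                   fx$artifact$sensor_config$n_channels)
  with_seed(11, {
    W <- array(rnorm(100 * 4 * 32), dim = c(100, 4, 32))
  })
  pa <- predict_window(fx$artifact, W)
  pb <- predict_window(back, W)
  expect_identical(pa$probabilities, pb$probabilities)
  expect_lt(file.size(f) / 1e6, 5) # ~MB-scale artifact
})

test_that("artifact loading fails loudly on damage or version mismatch", {
  fx <- cached_artifact()
  f <- withr::local_tempfile(fileext = ".json")
  save_artifact(fx$artifact, f)
  txt <- readLines(f, warn = FALSE)
  writeLines(substr(paste(txt, collapse = ""), 1, 500), f)
  expect_error(load_artifact(f), "cannot load artifact")
  save_artifact(fx$artifact, f)
  txt <- readLines(f, warn = FALSE)
  writeLines(gsub("gesturekit-artifact/1", "gesturekit-artifact/9", txt,
                  fixed = TRUE), f)
  expect_error(load_artifact(f), "incompatible")
})
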