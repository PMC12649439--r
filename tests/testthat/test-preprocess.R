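test_that("the fitted scaler standardizes its own training data", {
  expect_equal(unname(fit_scaler(matrix(c(0, 2), 2, 1))$mean), 1)
  expect_equal(unname(fit_scaler(matrix(c(0, 2), 2, 1))$sd), 1) # population sd
  expect_equal(as.numeric(apply_scaler(matrix(c(0, 2), 2, 1),
                                       fit_scaler(matrix(c(0, 2), 2, 1)))),
               c(-1, 1))
  with_seed(5, {
    m <- matrix(rnorm(600, 3, 2), 150, 4)
  })
  sc <- fit_scaler(m)
  z <- apply_scaler(m, sc)
  expect_lt(max(abs(colMeans(z))), 1e-9)
  popsd <- apply(z, 2, function(x) sqrt(mean((x - mean(x))^2)))
  expect_lt(max(abs(popsd - 1)), 1e-9)
  # refitting on standardized data is (numerically) the identity
  expect_lt(max(abs(apply_scaler(z, fit_scaler(z)) - z)), 1e-9)
})

test_that("scaler arithmetic matches the standardization equation", {
  sc <- structure(list(mean = 1, sd = 2, epsilon = 1e-8, degenerate = FALSE),
                  class = "scaler_params")
  expect_equal(as.numeric(apply_scaler(matrix(5), sc)), 2) # (5-1)/2
  expect_equal(as.numeric(apply_scaler(matrix(1), sc)), 0) # x = mu
})

test_that("degenerate channels are flagged and mapped to zero", {
  m <- cbind(rep(4, 10), 1:10)
  sc <- fit_scaler(m)
  expect_identical(unname(sc$degenerate), c(TRUE, FALSE))
  z <- apply_scaler(m, sc)
  expect_true(all(z[, 1] == 0))
  expect_error(fit_scaler(matrix(1, 1, 2)), "at least 2")
})

test_that("scaler round-trip inverts within 1e-9 on non-degenerate channels", {
  with_seed(6, {
    m <- matrix(runif(400, 0, 10), 100, 4)
  })
  sc <- fit_scaler(m)
  expect_lt(max(abs(inverse_scaler(apply_scaler(m, sc), sc) - m)), 1e-9)
})

test_that("transforming held-out data never mutates fitted parameters", {
  with_seed(7, {
    train_m <- matrix(runif(200), 50, 4)
    held <- matrix(runif(200, 5, 9), 50, 4)
  })
  sc <- fit_scaler(train_m)
  before <- unclass(sc)
  apply_scaler(held, sc)
  expect_identical(unclass(sc), before)
})

test_that("window segmentation matches brute-force start enumeration", {
  # printed geometry: 64 samples, window 32, 50% overlap -> starts 0,16,32
  cfg <- windowing_config(32, 0.5)
  expect_identical(cfg$stride, 16L)
  rec <- recording(matrix(seq_len(64 * 2) / 10, 64, 2), 50, "U", "G01")
  wb <- segment_windows(rec, cfg)
  expect_equal(dim(wb$windows), c(3, 2, 32))
  expect_equal(wb$windows[2, 1, ], rec$samples[17:48, 1])
  # boundary cases of the tail-drop rule
  expect_equal(dim(segment_windows(
    recording(matrix(1:64, 32, 2), 50, "U"), cfg)$windows)[1], 1)
  expect_equal(dim(segment_windows(
    recording(matrix(1:62, 31, 2), 50, "U"), cfg)$windows)[1], 0)
  # randomized geometries against the enumeration oracle
  with_seed(8, {
    for (i in 1:200) {
      n <- sample(0:300, 1)
      wl <- sample(1:64, 1)
      ov <- runif(1, 0, 0.95)
      c2 <- windowing_config(wl, ov)
      rec2 <- recording(matrix(rnorm(max(n, 1) * 2)[seq_len(n * 2)],
                               n, 2), 50, "U")
      got <- dim(segment_windows(rec2, c2)$windows)[1]
      expect_identical(got, length(brute_force_starts(n, wl, c2$stride)))
    }
  })
})

test_that("window labels follow the recording label and the majority rule", {
  rec <- recording(matrix(0, 64, 1), 50, "U", gesture_id = "G05")
  wb <- segment_windows(rec, windowing_config())
  expect_identical(wb$labels, rep("G05", 3))
  # per-sample labels, majority with center tie-break
  labs <- c(rep("A", 16), rep("B", 16))
  rec2 <- recording(matrix(0, 32, 1), 50, "U")
  w_maj <- segment_windows(rec2, windowing_config(32, 0, "majority"),
                           sample_labels = labs)
  expect_identical(w_maj$labels, "A") # tie; center sample (16th) is "A"
  w_c <- segment_windows(rec2, windowing_config(32, 0, "center"),
                         sample_labels = labs)
  expect_identical(w_c$labels, "A")
})

test_that("windows never span the boundary between concatenated recordings", {
  cfg <- windowing_config(32, 0.5)
  a <- recording(matrix(1, 50, 1), 50, "U", "A")
  b <- recording(matrix(2, 50, 1), 50, "U", "B")
  wb <- bind_batches(segment_windows(a, cfg), segment_windows(b, cfg))
  expect_equal(dim(wb$windows)[1], 4)
  for (i in seq_len(4)) {
    expect_length(unique(wb$windows[i, 1, ]), 1) # all-1 or all-2, never mixed
  }
})

test_that("raw-to-envelope emulation rectifies, smooths and settles at DC", {
  # constant zero in -> constant zero out
  z <- recording(matrix(0, 1000, 2), 1000, "U")
  expect_true(all(envelope_from_raw(z)$samples == 0))
  # DC offset +a settles at a (first-order low-pass has unit DC gain)
  a <- 3.7
  dc <- recording(matrix(a, 5000, 1), 1000, "U")
  env <- envelope_from_raw(dc)
  expect_equal(tail(env$samples[, 1], 1), a, tolerance = 1e-3)
  expect_equal(env$sampling_rate, 50)
  # any input -> nonnegative envelope
  with_seed(9, {
    noise <- recording(matrix(rnorm(2000, 0, 2), 1000, 2), 1000, "U")
  })
  expect_gte(min(envelope_from_raw(noise)$samples), 0)
  # guards
  expect_error(envelope_from_raw(recording(matrix(0, 10, 1), 5, "U")),
               "twice the low-pass cutoff")
  expect_error(envelope_from_raw(dc, lowpass_cutoff = 30, target_rate = 50),
               "Nyquist")
})
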