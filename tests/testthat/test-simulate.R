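test_that("sensor gain is linear in the potentiometer resistance", {
  expect_equal(sensor_gain(1), 200)
  expect_equal(sensor_gain(0), 0)
  expect_equal(sensor_gain(2.5), 500)
  expect_error(sensor_gain(-0.1), "non-negative")
})

test_that("gesture banks are distinct, in-range and seed-deterministic", {
  bank <- make_gesture_bank(10, 4, seed = 7)
  expect_length(bank, 10)
  rendered <- lapply(bank, gesturekit:::render_template, n_samples = 100)
  for (i in 1:9) {
    for (j in (i + 1):10) {
      expect_gt(mean(abs(rendered[[i]] - rendered[[j]])), 0)
    }
  }
  peaks <- unlist(lapply(bank, function(t) t$profiles$peak_amplitude))
  expect_true(all(peaks >= 0 & peaks <= 10))
  expect_identical(bank, make_gesture_bank(10, 4, seed = 7))
  expect_length(make_gesture_bank(1, 4, seed = 1), 1)
  expect_error(make_gesture_bank(0, 4, seed = 1), ">= 1")
})

test_that("zero variability forces identical phenotypes with identity mixing", {
  ph <- sample_phenotypes(5, 0, seed = 11)
  expect_length(ph, 5)
  for (p in ph) {
    expect_equal(p$gains, rep(1, 4))
    expect_equal(p$channel_mixing, diag(4))
    expect_equal(p$timing_offset, 0)
    expect_equal(p$timing_jitter_sd, ph[[1]]$timing_jitter_sd)
    expect_equal(p$drift_amplitude, ph[[1]]$drift_amplitude)
    expect_equal(p$noise_sd, ph[[1]]$noise_sd)
  }
})

test_that("positive variability yields pairwise-distinct phenotypes", {
  for (seed in 1:5) {
    ph <- sample_phenotypes(5, 1, seed = seed)
    for (i in 1:4) {
      for (j in (i + 1):5) {
        d <- sqrt(sum((ph[[i]]$gains - ph[[j]]$gains)^2) +
                    sum((ph[[i]]$channel_mixing - ph[[j]]$channel_mixing)^2))
        expect_gt(d, 0)
      }
    }
  }
})

test_that("phenotype invariants hold at every variability level", {
  for (v in c(0, 0.5, 1, 2)) {
    for (p in sample_phenotypes(4, v, seed = 5)) {
      expect_true(all(p$gains > 0))
      expect_true(all(p$channel_mixing >= 0))
      expect_equal(rowSums(p$channel_mixing), rep(1, 4), tolerance = 1e-12)
      expect_gte(p$noise_sd, 0)
    }
  }
})

test_that("an identity phenotype reproduces the rendered template exactly", {
  bank <- separable_bank()
  cfg <- sim_config(repetition_duration = 2, rng_seed = 1)
  rec <- synthesize_repetition(bank[[1]], identity_phenotype(), cfg, seed = 4)
  expected <- gesturekit:::render_template(bank[[1]], 100)
  expect_equal(unname(rec$samples), expected, tolerance = 1e-12)
})

test_that("repetition length and nonnegativity contracts hold", {
  bank <- make_gesture_bank(3, 4, seed = 2)
  ph <- sample_phenotypes(3, 1.5, seed = 8)
  cfg <- sim_config(repetition_duration = 2, sampling_rate = 50, rng_seed = 1)
  for (p in ph) {
    rec <- synthesize_repetition(bank[[2]], p, cfg, seed = 6)
    expect_equal(nrow(rec$samples), 100) # round(2 s x 50 Hz)
    expect_gte(min(rec$samples), 0)
  }
  # non-integer products round
  cfg2 <- sim_config(repetition_duration = 1.51, sampling_rate = 50,
                     rng_seed = 1)
  expect_equal(nrow(synthesize_repetition(bank[[1]], ph[[1]], cfg2, 1)$samples),
               round(1.51 * 50))
})

test_that("channel-count mismatches are rejected", {
  bank <- separable_bank(n_channels = 4)
  ph3 <- identity_phenotype(n_channels = 3)
  cfg <- sim_config(n_channels = 4)
  expect_error(synthesize_repetition(bank[[1]], ph3, cfg), "channel counts")
})

test_that("datasets have the protocol's cardinality and are reproducible", {
  bank <- make_gesture_bank(10, 4, seed = 7)
  ph <- sample_phenotypes(7, 1, seed = 3)
  cfg <- sim_config(rng_seed = 21)
  assign3 <- with_seed(1, {
    stats::setNames(lapply(1:7, function(u) sample(names(bank), 3)),
                    names(ph))
  })
  ds <- synthesize_dataset(bank, ph, 5, cfg, assign3)
  expect_length(ds$recordings, 7 * 3 * 5)
  ds2 <- synthesize_dataset(bank, ph, 5, cfg, assign3)
  expect_identical(lapply(ds$recordings, `[[`, "samples"),
                   lapply(ds2$recordings, `[[`, "samples"))
  # degenerate single-recording dataset
  ds1 <- synthesize_dataset(bank[1], ph[1], 1, cfg)
  expect_length(ds1$recordings, 1)
  expect_error(synthesize_dataset(structure(list(), class = "gesture_bank"),
                                  ph, 1, cfg), "non-empty")
})

test_that("zero-variability zero-noise cohorts are identical across users", {
  bank <- separable_bank()
  ph <- sample_phenotypes(3, 0, seed = 5, base_noise_sd = 0)
  cfg <- sim_config(rng_seed = 13)
  recs <- lapply(ph, function(p) {
    synthesize_repetition(bank[[1]], p, cfg, seed = 99)
  })
  expect_equal(recs[[1]]$samples, recs[[2]]$samples)
  expect_equal(recs[[2]]$samples, recs[[3]]$samples)
})

test_that("higher variability separates users' mean gesture signals more", {
  bank <- separable_bank()
  cfg <- sim_config(rng_seed = 3)
  mean_pairwise_dist <- function(v, seed) {
    ph <- sample_phenotypes(4, v, seed = seed, base_noise_sd = 0)
    sigs <- lapply(ph, function(p) {
      synthesize_repetition(bank[[1]], p, cfg, seed = derive_seed(seed, 1))$samples
    })
    d <- 0; n <- 0
    for (i in 1:3) for (j in (i + 1):4) {
      d <- d + sqrt(mean((sigs[[i]] - sigs[[j]])^2)); n <- n + 1
    }
    d / n
  }
  lows <- vapply(1:5, mean_pairwise_dist, numeric(1), v = 0.2)
  highs <- vapply(1:5, mean_pairwise_dist, numeric(1), v = 1.5)
  expect_gt(mean(highs), mean(lows))
})
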