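test_that("pattern invariants: motor range, positive durations, no overlap", {
  expect_error(motor_event(10, 0, 100), "motor_index")
  expect_error(motor_event(2, 0, 0), "duration")
  expect_error(motor_event(2, 0, 100, intensity = 1.5), "intensity")
  ev <- rbind(motor_event(1, 0, 100), motor_event(1, 50, 100))
  expect_error(haptic_pattern(ev), "overlapping")
  ok <- rbind(motor_event(1, 0, 100), motor_event(1, 100, 100),
              motor_event(2, 50, 100))
  p <- haptic_pattern(ok)
  expect_equal(p$total_duration, 200)
})

test_that("encoding concatenates symbols with gaps per the duration formula", {
  map <- default_letter_map() # 300 ms symbols, 100 ms gaps
  hello <- haptic_encode("HELLO", map)
  expect_equal(hello$total_duration, 5 * 300 + 4 * 100)
  # five symbol groups: events fall in 5 disjoint 300 ms slots
  slots <- findInterval(hello$events$start, seq(0, 1600, by = 400))
  expect_setequal(unique(slots), 1:5)
  # repeated symbol has an identical footprint in both slots
  ll <- haptic_encode("LL", map)
  l1 <- ll$events[ll$events$start < 300, ]
  l2 <- ll$events[ll$events$start >= 400, ]
  l2$start <- l2$start - 400
  rownames(l1) <- rownames(l2) <- NULL
  expect_equal(l1, l2)
  # empty message and unknown symbols
  empty <- haptic_encode("", map)
  expect_equal(nrow(empty$events), 0)
  expect_equal(empty$total_duration, 0)
  expect_error(haptic_encode("HI5", map), "not in the encoding map.*5")
})

test_that("decode inverts encode for random messages up to length 20", {
  map <- default_letter_map()
  expect_identical(haptic_decode(haptic_encode("HELLO", map), map),
                   c("H", "E", "L", "L", "O"))
  expect_identical(haptic_decode(haptic_encode("", map), map), character(0))
  with_seed(31, {
    for (len in c(1:5, 10, 15, 20)) {
      msg <- paste(sample(LETTERS, len, replace = TRUE), collapse = "")
      expect_identical(paste(haptic_decode(haptic_encode(msg, map), map),
                             collapse = ""), msg)
    }
  })
})

test_that("a foreign event makes a pattern undecodable with a located error", {
  map <- default_letter_map()
  pat <- haptic_encode("AB", map)
  pat$events <- rbind(pat$events, motor_event(7, 340, 17))
  pat$events <- pat$events[order(pat$events$start), ]
  expect_error(haptic_decode(pat, map), "decode error.*offset")
})

test_that("constructed maps are injective and respect capacity", {
  m3 <- map_from_gesture_bank(c("fist", "wave", "point"))
  sigs <- vapply(m3$patterns, gesturekit:::pattern_signature, character(1))
  expect_false(anyDuplicated(sigs) > 0)
  m1 <- map_from_gesture_bank("fist")
  expect_length(m1$patterns, 1)
  # the single-burst style over 10 motors x 3 durations holds 30 patterns
  expect_no_error(map_from_gesture_bank(sprintf("g%02d", 1:30)))
  expect_error(map_from_gesture_bank(sprintf("g%02d", 1:31)), "capacity")
  # letter map: 26 pairwise-distinct patterns within motor bounds
  lm <- default_letter_map()
  lsigs <- vapply(lm$patterns, gesturekit:::pattern_signature, character(1))
  expect_length(unique(lsigs), 26)
  ev <- do.call(rbind, lapply(lm$patterns, `[[`, "events"))
  expect_true(all(ev$motor_index >= 0 & ev$motor_index < 10))
  # duplicate patterns are rejected at map construction
  dup <- list(A = lm$patterns$A, B = lm$patterns$A)
  expect_error(encoding_map(dup), "not injective")
})

test_that("encoding maps round-trip through JSON", {
  map <- map_from_gesture_bank(c("fist", "wave", "point"), gap_ms = 80)
  f <- withr::local_tempfile(fileext = ".json")
  write_encoding_map(map, f)
  back <- read_encoding_map(f)
  expect_equal(back$gap_ms, 80)
  expect_identical(names(back$patterns), names(map$patterns))
  msg <- c("wave", "fist", "wave")
  expect_identical(haptic_decode(haptic_encode(msg, back), back), msg)
})
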