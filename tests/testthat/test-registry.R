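test_that("profile creation assigns sorted class indices and rejects duplicates", {
  root <- withr::local_tempdir()
  p <- create_profile(root, "U01", "s1", c("wave", "fist", "point"))
  expect_identical(p$gestures, c(fist = 0L, point = 1L, wave = 2L))
  expect_false(p$untrainable)
  expect_error(create_profile(root, "U01", "s1", "fist"), "conflict")
  # same user, later life stage is a distinct profile
  p2 <- create_profile(root, "U01", "s2", c("fist"))
  expect_identical(p2$gestures, c(fist = 0L))
  # empty bank: valid but untrainable
  p3 <- create_profile(root, "U02", "s1", character(0))
  expect_true(p3$untrainable)
})

test_that("bank edits create revisions and mark mismatched artifacts stale", {
  root <- withr::local_tempdir()
  fx <- cached_artifact()
  gestures <- names(fx$artifact$gesture_map)
  create_profile(root, "U01", "s1", gestures)
  v1 <- store_artifact(root, "U01", "s1", fx$artifact, fx$report)
  expect_identical(v1, 1L)
  expect_identical(latest_artifact(root, "U01", "s1")$version, 1L)
  # no-op edit: same revision, artifact untouched
  same <- edit_gesture_bank(root, "U01", "s1")
  expect_identical(same$revision, 1L)
  expect_identical(latest_artifact(root, "U01", "s1")$version, 1L)
  # real edit: new revision, artifact goes stale
  p2 <- edit_gesture_bank(root, "U01", "s1", add = "pinch")
  expect_identical(p2$revision, 2L)
  expect_length(p2$gestures, length(gestures) + 1)
  expect_error(latest_artifact(root, "U01", "s1"), "all versions stale")
  # remove-then-re-add recomputes indices; old artifact stays stale
  edit_gesture_bank(root, "U01", "s1", remove = "pinch")
  p4 <- edit_gesture_bank(root, "U01", "s1", add = "pinch")
  expect_identical(p4$revision, 4L)
  expect_error(latest_artifact(root, "U01", "s1"), "stale")
  expect_error(edit_gesture_bank(root, "U01", "s1", remove = "nope"),
               "unknown gesture")
  expect_error(edit_gesture_bank(root, "U01", "s1", add = "pinch"),
               "already present")
})

test_that("artifact versions are append-only and integrity-checked", {
  root <- withr::local_tempdir()
  fx <- cached_artifact()
  gestures <- names(fx$artifact$gesture_map)
  create_profile(root, "U01", "s1", gestures)
  v1 <- store_artifact(root, "U01", "s1", fx$artifact)
  v2 <- store_artifact(root, "U01", "s1", fx$artifact, fx$report)
  expect_identical(c(v1, v2), c(1L, 2L))
  expect_identical(latest_artifact(root, "U01", "s1")$version, 2L)
  # mismatched gesture map is an integrity error
  bad <- fx$artifact
  names(bad$gesture_map) <- paste0(names(bad$gesture_map), "_x")
  expect_error(store_artifact(root, "U01", "s1", bad), "integrity")
  expect_error(latest_artifact(root, "U99", "s1"), "not found")
})

test_that("prediction logging is append-only, ordered and referenced", {
  root <- withr::local_tempdir()
  fx <- cached_artifact()
  create_profile(root, "U01", "s1", names(fx$artifact$gesture_map))
  store_artifact(root, "U01", "s1", fx$artifact)
  probs <- c(0.7, 0.2, 0.1)
  names(probs) <- names(sort(fx$artifact$gesture_map))
  for (t in c(40, 0, 80, 20, 60, 100, 120, 140, 160, 180)) {
    log_prediction(root, "U01", "s1", t, names(probs)[1], probs, 1L)
  }
  all_rows <- query_predictions(root, "U01", "s1")
  expect_equal(nrow(all_rows), 10)
  expect_true(!is.unsorted(all_rows$ts_ms))
  expect_equal(nrow(query_predictions(root, "U01", "s1", 20, 60)), 3)
  expect_equal(nrow(query_predictions(root, "U01", "s1", 500, 600)), 0)
  expect_error(log_prediction(root, "U01", "s1", 10, "x", probs, 9L),
               "integrity")
})

test_that("the audit is clean after a scripted session and catches dangling refs", {
  root <- withr::local_tempdir()
  fx <- cached_artifact()
  gestures <- names(fx$artifact$gesture_map)
  create_profile(root, "U01", "s1", gestures)
  store_artifact(root, "U01", "s1", fx$artifact, fx$report)
  probs <- stats::setNames(rep(1 / 3, 3), names(sort(fx$artifact$gesture_map)))
  log_prediction(root, "U01", "s1", 0, gestures[1], probs, 1L)
  edit_gesture_bank(root, "U01", "s1", add = "extra")
  expect_identical(nrow(audit_registry(root)), 0L)
  # hand-damage the store: a log entry referencing a missing artifact
  cat('{"ts_ms":5,"label":"x","probabilities":{},"artifact_version":42}\n',
      file = file.path(root, "U01", "s1", "predictions.jsonl"),
      append = TRUE)
  bad <- audit_registry(root)
  expect_identical(nrow(bad), 1L)
  expect_match(bad$what, "missing artifact v42")
})

test_that("two independent readers see identical registry state", {
  root <- withr::local_tempdir()
  fx <- cached_artifact()
  create_profile(root, "U01", "s1", names(fx$artifact$gesture_map))
  store_artifact(root, "U01", "s1", fx$artifact)
  a <- latest_artifact(root, "U01", "s1")
  b <- latest_artifact(root, "U01", "s1") # fresh read, no shared cache
  expect_identical(a$version, b$version)
  expect_identical(a$artifact$weights, b$artifact$weights)
})
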