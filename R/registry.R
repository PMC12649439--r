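# File-backed per-user profile store. One directory per (user, life_stage)
# holds append-only profile revisions, versioned model artifacts with their
# training reports, and a JSON-lines prediction log:
#
#   <root>/<user_id>/<life_stage>/
#     profile_r<K>.json      profile revisions (r1, r2, ...)
#     artifacts/v<K>.json    model artifacts (versioned, append-only)
#     artifacts/v<K>_report.json
#     artifacts/v<K>.stale   marker: artifact no longer matches the bank
#     predictions.jsonl      append-only prediction log
#
# Nothing is ever deleted or rewritten: edits append a new profile revision,
# invalidated artifacts get a stale marker, and store state lives entirely
# on disk so independent readers agree.

stage_dir <- function(root, user_id, life_stage) {
  file.path(root, user_id, life_stage)
}

profile_revisions <- function(dir) {
  fs <- list.files(dir, pattern = "^profile_r[0-9]+\\.json$")
  sort(as.integer(sub("^profile_r([0-9]+)\\.json$", "\\1", fs)))
}

read_profile_file <- function(dir, rev) {
  p <- jsonlite::read_json(file.path(dir, sprintf("profile_r%d.json", rev)))
  structure(
    list(user_id = p$user_id, life_stage = p$life_stage,
         revision = as.integer(p$revision),
         gestures = stats::setNames(as.integer(unlist(p$gestures)),
                                    names(p$gestures)),
         sensor_config = list(
           n_channels = as.integer(p$sensor_config$n_channels),
           sampling_rate = as.numeric(p$sensor_config$sampling_rate)),
         untrainable = isTRUE(p$untrainable), created = p$created),
    class = "user_profile"
  )
}

write_profile_file <- function(dir, profile) {
  jsonlite::write_json(
    list(user_id = profile$user_id, life_stage = profile$life_stage,
         revision = profile$revision, gestures = as.list(profile$gestures),
         sensor_config = profile$sensor_config,
         untrainable = profile$untrainable, created = profile$created),
    file.path(dir, sprintf("profile_r%d.json", profile$revision)),
    auto_unbox = TRUE, digits = NA)
}

#' @export
print.user_profile <- function(x, ...) {
  cat(sprintf("<user_profile> %s / %s (rev %d): %d gestures%s\n",
              x$user_id, x$life_stage, x$revision, length(x$gestures),
              if (x$untrainable) " [untrainable]" else ""))
  invisible(x)
}

#' Create a user profile for a life stage
#'
#' Registers a new (user, life stage) pair in the store. Class indices are
#' assigned by sorted gesture-name order, so they are reproducible across
#' machines. An empty gesture list yields a valid profile flagged
#' untrainable.
#'
#' @param root Registry root directory (created if absent).
#' @param user_id,life_stage Profile key; the pair must not already exist.
#' @param gestures Character vector of gesture names (unique).
#' @param sensor_config List with `n_channels` and `sampling_rate`.
#' @return The persisted `user_profile` (revision 1).
#' @export
create_profile <- function(root, user_id, life_stage, gestures,
                           sensor_config = list(n_channels = 4L,
                                                sampling_rate = 50)) {
  if (anyDuplicated(gestures)) stop("gesture names must be unique")
  dir <- stage_dir(root, user_id, life_stage)
  if (dir.exists(dir) && length(profile_revisions(dir)) > 0) {
    stop("profile conflict: (", user_id, ", ", life_stage,
         ") already exists")
  }
  dir.create(file.path(dir, "artifacts"), recursive = TRUE,
             showWarnings = FALSE)
  gs <- sort(as.character(gestures))
  profile <- structure(
    list(user_id = as.character(user_id),
         life_stage = as.character(life_stage), revision = 1L,
         gestures = stats::setNames(seq_along(gs) - 1L, gs),
         sensor_config = sensor_config,
         untrainable = length(gs) == 0,
         created = format(Sys.time(), tz = "UTC")),
    class = "user_profile"
  )
  write_profile_file(dir, profile)
  profile
}

#' Load the latest profile revision
#'
#' @param root Registry root.
#' @param user_id,life_stage Profile key.
#' @return The latest `user_profile` revision.
#' @export
get_profile <- function(root, user_id, life_stage) {
  dir <- stage_dir(root, user_id, life_stage)
  revs <- if (dir.exists(dir)) profile_revisions(dir) else integer(0)
  if (length(revs) == 0) {
    stop("profile not found: (", user_id, ", ", life_stage, ")")
  }
  read_profile_file(dir, max(revs))
}

#' Edit a profile's gesture bank
#'
#' Appends a new profile revision with the requested gestures added and/or
#' removed; class indices are recomputed from the new sorted name order.
#' Every stored artifact whose gesture map no longer matches the new bank is
#' marked stale so it can never be silently served again. An edit that
#' changes nothing returns the current revision untouched.
#'
#' @param root Registry root.
#' @param user_id,life_stage Profile key.
#' @param add Gesture names to add (must not already be present).
#' @param remove Gesture names to remove (must be present).
#' @return The new (or unchanged) `user_profile`.
#' @export
edit_gesture_bank <- function(root, user_id, life_stage,
                              add = character(0), remove = character(0)) {
  profile <- get_profile(root, user_id, life_stage)
  dir <- stage_dir(root, user_id, life_stage)
  if (length(add) == 0 && length(remove) == 0) return(profile)
  unknown <- setdiff(remove, names(profile$gestures))
  if (length(unknown) > 0) {
    stop("cannot remove unknown gesture(s): ", paste(unknown, collapse = ", "))
  }
  dup <- intersect(add, setdiff(names(profile$gestures), remove))
  if (length(dup) > 0) {
    stop("gesture(s) already present: ", paste(dup, collapse = ", "))
  }
  gs <- sort(union(setdiff(names(profile$gestures), remove), add))
  new <- profile
  new$revision <- profile$revision + 1L
  new$gestures <- stats::setNames(seq_along(gs) - 1L, gs)
  new$untrainable <- length(gs) == 0
  new$created <- format(Sys.time(), tz = "UTC")
  write_profile_file(dir, new)
  # invalidate artifacts whose class map no longer matches the bank
  for (v in artifact_versions(dir)) {
    af <- load_artifact(file.path(dir, "artifacts", sprintf("v%d.json", v)))
    if (!identical(af$gesture_map, new$gestures)) {
      marker <- file.path(dir, "artifacts", sprintf("v%d.stale", v))
      if (!file.exists(marker)) file.create(marker)
    }
  }
  new
}

artifact_versions <- function(dir) {
  fs <- list.files(file.path(dir, "artifacts"), pattern = "^v[0-9]+\\.json$")
  sort(as.integer(sub("^v([0-9]+)\\.json$", "\\1", fs)))
}

#' Store a trained artifact for a profile
#'
#' Appends the artifact (and its training report) under the next version
#' number. The artifact's gesture map must match the profile's current bank
#' exactly; a mismatch is an integrity error.
#'
#' @param root Registry root.
#' @param user_id,life_stage Profile key.
#' @param artifact A `model_artifact`.
#' @param report Optional `training_report` stored alongside.
#' @return The assigned version number.
#' @export
store_artifact <- function(root, user_id, life_stage, artifact,
                           report = NULL) {
  profile <- get_profile(root, user_id, life_stage)
  dir <- stage_dir(root, user_id, life_stage)
  if (!identical(artifact$gesture_map, profile$gestures)) {
    stop("integrity error: artifact gesture map does not match the ",
         "profile's gesture bank")
  }
  v <- max(c(0L, artifact_versions(dir))) + 1L
  save_artifact(artifact, file.path(dir, "artifacts", sprintf("v%d.json", v)))
  if (!is.null(report)) {
    jsonlite::write_json(
      unclass(report),
      file.path(dir, "artifacts", sprintf("v%d_report.json", v)),
      auto_unbox = TRUE, digits = NA)
  }
  v
}

#' Fetch the latest usable artifact
#'
#' Returns the highest-version stored artifact that has not been marked
#' stale by a gesture-bank edit.
#'
#' @param root Registry root.
#' @param user_id,life_stage Profile key.
#' @return A list with `artifact` and its `version`.
#' @export
latest_artifact <- function(root, user_id, life_stage) {
  profile <- get_profile(root, user_id, life_stage) # not-found check
  dir <- stage_dir(root, user_id, life_stage)
  vs <- artifact_versions(dir)
  usable <- vs[!file.exists(file.path(dir, "artifacts",
                                      sprintf("v%d.stale", vs)))]
  if (length(usable) == 0) {
    stop("no usable model for (", profile$user_id, ", ", profile$life_stage,
         "): ", if (length(vs) == 0) "none stored" else "all versions stale")
  }
  v <- max(usable)
  list(artifact = load_artifact(file.path(dir, "artifacts",
                                          sprintf("v%d.json", v))),
       version = v)
}

#' Append a prediction to the log
#'
#' @param root Registry root.
#' @param user_id,life_stage Profile key.
#' @param timestamp Prediction timestamp (ms since stream epoch).
#' @param label Predicted gesture label.
#' @param probabilities Named probability vector.
#' @param artifact_version Version of the artifact that produced the
#'   prediction; must exist in the store.
#' @return Invisibly, the log file path.
#' @export
log_prediction <- function(root, user_id, life_stage, timestamp, label,
                           probabilities, artifact_version) {
  dir <- stage_dir(root, user_id, life_stage)
  if (!(artifact_version %in% artifact_versions(dir))) {
    stop("integrity error: artifact version ", artifact_version,
         " does not exist for (", user_id, ", ", life_stage, ")")
  }
  line <- jsonlite::toJSON(
    list(ts_ms = timestamp, label = label,
         probabilities = as.list(probabilities),
         artifact_version = artifact_version),
    auto_unbox = TRUE, digits = NA)
  cat(line, "\n", sep = "", file = file.path(dir, "predictions.jsonl"),
      append = TRUE)
  invisible(file.path(dir, "predictions.jsonl"))
}

#' Query logged predictions in a time range
#'
#' @param root Registry root.
#' @param user_id,life_stage Profile key.
#' @param from,to Inclusive timestamp bounds in ms (defaults: all).
#' @return Data frame of matching entries in timestamp order.
#' @export
query_predictions <- function(root, user_id, life_stage,
                              from = -Inf, to = Inf) {
  path <- file.path(stage_dir(root, user_id, life_stage), "predictions.jsonl")
  empty <- data.frame(ts_ms = numeric(0), label = character(0),
                      artifact_version = integer(0),
                      stringsAsFactors = FALSE)
  if (!file.exists(path)) return(empty)
  rows <- lapply(readLines(path, warn = FALSE), jsonlite::fromJSON)
  df <- do.call(rbind, lapply(rows, function(r) {
    data.frame(ts_ms = r$ts_ms, label = r$label,
               artifact_version = r$artifact_version,
               stringsAsFactors = FALSE)
  }))
  if (is.null(df)) return(empty)
  df <- df[df$ts_ms >= from & df$ts_ms <= to, , drop = FALSE]
  df[order(df$ts_ms), , drop = FALSE]
}

#' Audit a registry for referential integrity
#'
#' Walks the whole store and checks that every artifact belongs to an
#' existing profile and matches some revision of its gesture bank (or is
#' marked stale), and that every logged prediction references a stored
#' artifact version.
#'
#' @param root Registry root.
#' @return A data frame of violations (zero rows when the store is
#'   consistent) with columns `user_id`, `life_stage`, `what`.
#' @export
audit_registry <- function(root) {
  bad <- list()
  note <- function(u, s, what) {
    bad[[length(bad) + 1]] <<- data.frame(user_id = u, life_stage = s,
                                          what = what,
                                          stringsAsFactors = FALSE)
  }
  for (u in list.dirs(root, recursive = FALSE, full.names = FALSE)) {
    for (s in list.dirs(file.path(root, u), recursive = FALSE,
                        full.names = FALSE)) {
      dir <- stage_dir(root, u, s)
      revs <- profile_revisions(dir)
      if (length(revs) == 0) {
        note(u, s, "stage directory without any profile revision")
        next
      }
      profiles <- lapply(revs, read_profile_file, dir = dir)
      maps <- lapply(profiles, `[[`, "gestures")
      vs <- artifact_versions(dir)
      for (v in vs) {
        af <- tryCatch(
          load_artifact(file.path(dir, "artifacts", sprintf("v%d.json", v))),
          error = function(e) NULL)
        if (is.null(af)) {
          note(u, s, sprintf("artifact v%d unreadable", v))
          next
        }
        matches <- any(vapply(maps, identical, logical(1), y = af$gesture_map))
        stale <- file.exists(file.path(dir, "artifacts",
                                       sprintf("v%d.stale", v)))
        if (!matches && !stale) {
          note(u, s, sprintf(
            "artifact v%d matches no profile revision and is not stale", v))
        }
      }
      log <- query_predictions(root, u, s)
      dangling <- setdiff(unique(log$artifact_version), vs)
      for (v in dangling) {
        note(u, s, sprintf("prediction log references missing artifact v%d", v))
      }
    }
  }
  if (length(bad) == 0) {
    data.frame(user_id = character(0), life_stage = character(0),
               what = character(0), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, bad)
  }
}
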