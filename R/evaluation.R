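# Personalized-versus-cross-user experiments on synthetic cohorts.
#
# Design rules that make the comparison fair and the degenerate identities
# exact: both arms consume byte-identical per-user window sets (each user's
# recordings are standardized with that user's own scaler, then windowed
# once); model architecture and training configuration are identical across
# arms; and the same training seed drives both arms, so a one-user cohort
# trains literally the same model twice and the accuracy gap is exactly
# zero.

#' Cohort specification for evaluation experiments
#'
#' @param n_users Number of synthetic users.
#' @param gestures_per_user Gestures assigned to each user, drawn at random
#'   from the shared bank (default 3).
#' @param reps_per_gesture Repetitions per assigned gesture (default 5);
#'   must be at least 2 so a validation split exists.
#' @param variability_level Inter-user variability scale passed to the
#'   phenotype sampler (default 1).
#' @param bank_size Size of the shared gesture bank (default 10).
#' @param seeds Integer vector of replication seeds (default `1:5`).
#' @param n_channels,sampling_rate,repetition_duration Signal geometry
#'   (defaults 4 channels, 50 Hz, 3 s).
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_users, gestures_per_user = 3L,
                        reps_per_gesture = 5L, variability_level = 1,
                        bank_size = 10L, seeds = 1:5, n_channels = 4L,
                        sampling_rate = 50, repetition_duration = 3) {
  if (gestures_per_user > bank_size) {
    stop("gestures_per_user cannot exceed the bank size")
  }
  if (reps_per_gesture < 2) {
    stop("reps_per_gesture must be >= 2 (validation split impossible)")
  }
  structure(
    list(n_users = as.integer(n_users),
         gestures_per_user = as.integer(gestures_per_user),
         reps_per_gesture = as.integer(reps_per_gesture),
         variability_level = variability_level,
         bank_size = as.integer(bank_size), seeds = as.integer(seeds),
         n_channels = as.integer(n_channels), sampling_rate = sampling_rate,
         repetition_duration = repetition_duration),
    class = "cohort_spec"
  )
}

# Generate one cohort replicate: bank, phenotypes, assignments, and each
# user's standardized window batch (windowed per repetition, so no window
# spans two repetitions). Each user's scaler is fitted on a calibration
# session — one pass over the full gesture bank — rather than on their
# assigned training gestures: calibration-based scaling is standard sEMG
# onboarding practice, and it keeps the standardization statistics
# independent of which gesture subset a user happens to train, so the
# absolute signal levels carry no information about the user's class
# assignment.
prepare_cohort <- function(spec, seed, wcfg = windowing_config()) {
  bank <- make_gesture_bank(spec$bank_size, spec$n_channels,
                            seed = derive_seed(seed, 1L))
  phen <- sample_phenotypes(spec$n_users, spec$variability_level,
                            seed = derive_seed(seed, 2L),
                            n_channels = spec$n_channels)
  assignments <- with_seed(derive_seed(seed, 3L), {
    stats::setNames(
      lapply(seq_len(spec$n_users), function(u) {
        sort(sample(names(bank), spec$gestures_per_user))
      }),
      names(phen))
  })
  config <- sim_config(n_channels = spec$n_channels,
                       sampling_rate = spec$sampling_rate,
                       repetition_duration = spec$repetition_duration,
                       variability_level = spec$variability_level,
                       rng_seed = derive_seed(seed, 4L))
  ds <- synthesize_dataset(bank, phen, spec$reps_per_gesture, config,
                           assignments)
  calib_config <- config
  calib_config$rng_seed <- derive_seed(seed, 5L)
  calib <- synthesize_dataset(bank, phen, 1L, calib_config)
  batches <- lapply(names(phen), function(uid) {
    recs <- Filter(function(r) r$user_id == uid, ds$recordings)
    scaler <- fit_scaler(Filter(function(r) r$user_id == uid,
                                calib$recordings))
    rep_batches <- lapply(recs, function(r) {
      segment_windows(apply_scaler(r, scaler), wcfg)
    })
    wb <- bind_batches(rep_batches)
    wb$user_id <- uid
    # repetition provenance of every window, for leakage-free splits:
    # overlapping windows from one repetition must never straddle the
    # train/validation boundary
    wb$group <- rep(seq_along(recs),
                    vapply(rep_batches, function(b) dim(b$windows)[1],
                           integer(1)))
    list(batch = wb, scaler = scaler)
  })
  names(batches) <- names(phen)
  list(bank = bank, phenotypes = phen, assignments = assignments,
       config = config, batches = batches)
}

# Accuracy and loss of an artifact on labeled windows.
score_windows <- function(artifact, windows, labels) {
  pr <- predict_window(artifact, windows)
  col <- match(labels, colnames(pr$probabilities))
  p_true <- ifelse(is.na(col), 1e-12, # true label outside the class space
                   pr$probabilities[cbind(seq_along(labels), col)])
  list(accuracy = mean(pr$label == labels),
       loss = -mean(log(pmax(p_true, 1e-12))))
}

# One stratified train/validation partition per user, fixed by the training
# seed. Held-out units are whole repetitions, not windows: overlapping
# windows from one repetition are near-duplicates, so a window-level split
# would leak training data into validation and pin both arms to a
# memorization ceiling. The same partition drives both arms, so
# personalized and cross-user accuracies are estimated on identical
# validation windows (a paired comparison) and the cross-user model never
# trains on any window of a validation repetition.
user_splits <- function(cohort, uids, train_cfg, train_seed) {
  out <- lapply(seq_along(uids), function(i) {
    b <- cohort$batches[[uids[i]]]
    with_seed(derive_seed(train_seed, 21L, i), {
      val <- integer(0)
      for (cl in sort(unique(b$batch$labels))) {
        reps <- sort(unique(b$batch$group[b$batch$labels == cl]))
        n_val <- min(max(1L, round(length(reps) *
                                     train_cfg$validation_fraction)),
                     length(reps) - 1L)
        held <- sample(reps, n_val)
        val <- c(val, which(b$batch$group %in% held))
      }
      list(train = setdiff(seq_along(b$batch$labels), val), val = sort(val))
    })
  })
  names(out) <- uids
  out
}

# Train the personalized arm for the first `n` users of a cohort.
train_personalized <- function(cohort, n, train_cfg, train_seed) {
  uids <- names(cohort$batches)[seq_len(n)]
  tcfg <- train_cfg
  tcfg$seed <- train_seed
  splits <- user_splits(cohort, uids, train_cfg, train_seed)
  out <- lapply(uids, function(uid) {
    b <- cohort$batches[[uid]]
    res <- train(b$batch, b$scaler, train_cfg = tcfg, user_id = uid,
                 split = splits[[uid]])
    list(report = res$report, artifact = res$artifact)
  })
  names(out) <- uids
  out
}

# Train both arms on the first `n_subset` users of a prepared cohort.
# Returns per-user personalized and cross-user validation metrics.
# `personalized` may carry pre-trained personalized-arm results (as from
# train_personalized) to avoid retraining across subset sizes.
run_arms <- function(cohort, n_subset, train_cfg, train_seed,
                     personalized = NULL) {
  uids <- names(cohort$batches)[seq_len(n_subset)]
  tcfg <- train_cfg
  tcfg$seed <- train_seed
  per_user <- if (is.null(personalized)) {
    train_personalized(cohort, n_subset, train_cfg, train_seed)
  } else {
    personalized[uids]
  }
  splits <- user_splits(cohort, uids, train_cfg, train_seed)
  pooled <- bind_batches(lapply(uids, function(u) cohort$batches[[u]]$batch))
  sizes <- vapply(uids, function(u) {
    dim(cohort$batches[[u]]$batch$windows)[1]
  }, integer(1))
  offsets <- cumsum(c(0L, sizes[-length(sizes)]))
  names(offsets) <- uids
  pooled_split <- list(
    train = unlist(lapply(uids, function(u) splits[[u]]$train + offsets[u])),
    val = unlist(lapply(uids, function(u) splits[[u]]$val + offsets[u]))
  )
  union_classes <- sort(unique(unlist(cohort$assignments[uids])))
  cross <- train(pooled, cohort$batches[[uids[1]]]$scaler,
                 train_cfg = tcfg, user_id = "cross",
                 class_levels = union_classes, split = pooled_split)
  cross_user_acc <- vapply(uids, function(u) {
    idx <- splits[[u]]$val + offsets[u]
    score_windows(cross$artifact,
                  pooled$windows[idx, , , drop = FALSE],
                  pooled$labels[idx])$accuracy
  }, numeric(1))
  data.frame(
    user_id = uids,
    personalized_accuracy = vapply(per_user, function(r)
      r$report$best_val_accuracy, numeric(1)),
    personalized_loss = vapply(per_user, function(r)
      r$report$best_val_loss, numeric(1)),
    cross_accuracy_overall = cross$report$best_val_accuracy,
    cross_loss_overall = cross$report$best_val_loss,
    cross_accuracy_user = cross_user_acc,
    stringsAsFactors = FALSE
  )
}

#' Personalized vs cross-user accuracy as a function of cohort size
#'
#' For each subset size `U` and each replication seed, trains `U`
#' personalized models and one cross-user model on the pooled windows of the
#' same `U` users (classes = union of their gesture sets), holding
#' architecture, training configuration and training seed identical between
#' arms. Reports the macro-averaged personalized validation accuracy, the
#' cross-user validation accuracy on the pooled split, and their gap in
#' percentage points.
#'
#' @param spec A `cohort_spec`; `spec$n_users` must cover
#'   `max(subset_sizes)`.
#' @param subset_sizes Integer vector of cohort sizes to scan (all >= 1).
#' @param train_cfg Training configuration shared by both arms (default:
#'   standard configuration capped at 30 epochs).
#' @return An `eval_result` with `per_seed` (one row per seed and size) and
#'   `summary` (seed-averaged, one row per size).
#' @export
run_group_size_scan <- function(spec, subset_sizes,
                                train_cfg = train_config(max_epochs = 30L)) {
  if (any(subset_sizes < 1)) stop("subset sizes must be >= 1")
  if (max(subset_sizes) > spec$n_users) {
    stop("subset sizes cannot exceed spec$n_users")
  }
  rows <- list()
  for (seed in spec$seeds) {
    cohort <- prepare_cohort(spec, seed)
    ts <- derive_seed(seed, 11L)
    # a user's personalized model does not depend on the subset size, so the
    # personalized arm is trained once per seed and reused across sizes
    pers <- train_personalized(cohort, max(subset_sizes), train_cfg, ts)
    for (U in sort(subset_sizes)) {
      arms <- run_arms(cohort, U, train_cfg, ts, personalized = pers)
      rows[[length(rows) + 1]] <- data.frame(
        seed = seed, subset_size = as.integer(U),
        personalized_accuracy = mean(arms$personalized_accuracy),
        cross_accuracy = arms$cross_accuracy_overall[1],
        gap_pp = 100 * (mean(arms$personalized_accuracy) -
                          arms$cross_accuracy_overall[1]),
        stringsAsFactors = FALSE
      )
    }
  }
  per_seed <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(sort(unique(per_seed$subset_size)),
                                   function(U) {
    s <- per_seed[per_seed$subset_size == U, ]
    data.frame(subset_size = U,
               personalized_accuracy = mean(s$personalized_accuracy),
               cross_accuracy = mean(s$cross_accuracy),
               gap_pp = mean(s$gap_pp))
  }))
  structure(list(kind = "scan", spec = spec, per_seed = per_seed,
                 summary = summary),
            class = "eval_result")
}

#' Reproduce the live seven-subject protocol on a synthetic cohort
#'
#' Each synthetic subject is assigned a random subset of gestures from the
#' shared bank and performs each assigned gesture a fixed number of times; a
#' personalized model is trained per subject and one cross-user model (same
#' architecture, training configuration and seed) on the combined data of
#' all subjects. Per-subject personalized and cross-user validation accuracy
#' and loss are reported, averaged over the replication seeds.
#'
#' @param spec A `cohort_spec` (default: 7 subjects, 3 of 10 gestures, 5
#'   repetitions — the live-protocol data budget).
#' @param train_cfg Training configuration shared by both arms.
#' @return An `eval_result` with per-seed per-subject rows and a per-subject
#'   seed-averaged summary.
#' @export
run_live_protocol <- function(spec = cohort_spec(n_users = 7L),
                              train_cfg = train_config(max_epochs = 30L)) {
  rows <- list()
  for (seed in spec$seeds) {
    cohort <- prepare_cohort(spec, seed)
    arms <- run_arms(cohort, spec$n_users, train_cfg, derive_seed(seed, 11L))
    arms$seed <- seed
    rows[[length(rows) + 1]] <- arms
  }
  per_seed <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(sort(unique(per_seed$user_id)),
                                   function(u) {
    s <- per_seed[per_seed$user_id == u, ]
    data.frame(user_id = u,
               personalized_accuracy = mean(s$personalized_accuracy),
               personalized_loss = mean(s$personalized_loss),
               cross_accuracy = mean(s$cross_accuracy_overall),
               cross_accuracy_user = mean(s$cross_accuracy_user, na.rm = TRUE),
               gap_pp = 100 * (mean(s$personalized_accuracy) -
                                 mean(s$cross_accuracy_overall)),
               stringsAsFactors = FALSE)
  }))
  structure(list(kind = "live", spec = spec, per_seed = per_seed,
                 summary = summary),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result> %s experiment, %d seeds\n", x$kind,
              length(x$spec$seeds)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Summarize an evaluation result
#'
#' Renders the seed-averaged summary table and, for a group-size scan, the
#' gap-versus-cohort-size curve. Deterministic: identical results yield
#' byte-identical files.
#'
#' @param result An `eval_result`.
#' @param out_dir Optional directory; when given, writes `summary.csv`,
#'   `per_seed.csv` and (for scans) `gap_curve.csv`.
#' @return A list with `table` (the summary data frame) and `curve`
#'   (`subset_size` vs `gap_pp`, scans only).
#' @export
summarize_eval <- function(result, out_dir = NULL) {
  stopifnot(inherits(result, "eval_result"))
  if (nrow(result$summary) == 0) stop("empty evaluation result")
  curve <- if (result$kind == "scan") {
    result$summary[, c("subset_size", "gap_pp")]
  } else NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_table <- function(df, name) {
      utils::write.csv(format(df, digits = 10, trim = TRUE),
                       file.path(out_dir, name), row.names = FALSE,
                       quote = FALSE)
    }
    write_table(result$summary, "summary.csv")
    write_table(result$per_seed, "per_seed.csv")
    if (!is.null(curve)) write_table(curve, "gap_curve.csv")
  }
  list(table = result$summary, curve = curve)
}
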