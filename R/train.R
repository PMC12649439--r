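# Training: Adam on multi-class cross-entropy in mini-batches of 32, a
# stratified validation split held fixed across epochs, and early stopping
# on validation loss with best-epoch weight restoration.

#' Training configuration
#'
#' @param learning_rate Adam learning rate (default 0.001).
#' @param batch_size Mini-batch size (default 32).
#' @param min_epochs Minimum number of epochs before early stopping may
#'   trigger (default 10).
#' @param max_epochs Hard epoch cap (default 200).
#' @param early_stop_patience Epochs without validation-loss improvement
#'   tolerated before stopping (default 5).
#' @param validation_fraction Fraction of windows held out per class for
#'   validation (default 0.2).
#' @param seed Integer seed for the split, shuffling and initialization.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.001, batch_size = 32L,
                         min_epochs = 10L, max_epochs = 200L,
                         early_stop_patience = 5L,
                         validation_fraction = 0.2, seed = 1L) {
  if (min_epochs > max_epochs) stop("min_epochs must be <= max_epochs")
  if (validation_fraction <= 0 || validation_fraction >= 1) {
    stop("validation_fraction must lie in (0, 1)")
  }
  structure(
    list(learning_rate = learning_rate, batch_size = as.integer(batch_size),
         min_epochs = as.integer(min_epochs),
         max_epochs = as.integer(max_epochs),
         early_stop_patience = as.integer(early_stop_patience),
         validation_fraction = validation_fraction, seed = as.integer(seed)),
    class = "train_config"
  )
}

# Number of trailing epochs since the running validation-loss minimum last
# (strictly) improved. The training loop stops at the first epoch e >=
# min_epochs where this reaches the patience.
epochs_without_improvement <- function(val_losses) {
  if (length(val_losses) == 0) return(0L)
  best_at <- which.min(val_losses) # earliest epoch attaining the minimum
  length(val_losses) - best_at
}

# Decide the stopping epoch for a validation-loss sequence; used both by the
# training loop and as a pure, testable statement of the rule.
stopping_point <- function(val_losses, patience, min_epochs, max_epochs) {
  for (e in seq_along(val_losses)) {
    if (e >= min_epochs &&
        epochs_without_improvement(val_losses[seq_len(e)]) >= patience) {
      return(list(stopped_epoch = e, stop_reason = "early_stop"))
    }
    if (e >= max_epochs) {
      return(list(stopped_epoch = e, stop_reason = "max_epochs"))
    }
  }
  list(stopped_epoch = length(val_losses), stop_reason = "max_epochs")
}

# Stratified train/validation indices: per class, at least one window held
# out; deterministic under seed.
stratified_split <- function(labels, validation_fraction, seed) {
  with_seed(derive_seed(seed, 404L), {
    val <- integer(0)
    for (cl in sort(unique(labels))) {
      idx <- which(labels == cl)
      if (length(idx) < 2) {
        stop("class '", cl, "' has fewer than 2 windows; cannot split")
      }
      n_val <- max(1L, round(length(idx) * validation_fraction))
      n_val <- min(n_val, length(idx) - 1L)
      val <- c(val, sample(idx, n_val))
    }
    list(train = setdiff(seq_along(labels), val), val = sort(val))
  })
}

#' Train a personalized gesture classifier
#'
#' Fits the two-conv / five-dense 1D-CNN on a standardized window batch.
#' Classes are the sorted unique gesture labels of the batch. Optimization is
#' Adam on multi-class cross-entropy in mini-batches; a stratified validation
#' split is held fixed across epochs; training stops at the first epoch
#' `e >= min_epochs` at which validation loss has not improved for
#' `early_stop_patience` consecutive epochs (else at `max_epochs`), and the
#' returned artifact carries the weights of the best-validation-loss epoch.
#'
#' @param batch A labeled, standardized `window_batch`; every class needs at
#'   least 2 windows.
#' @param scaler The `scaler_params` the windows were standardized with
#'   (persisted into the artifact for deployment).
#' @param model_cfg Optional `model_config`; defaults to the standard
#'   architecture sized from the batch.
#' @param train_cfg A `train_config`.
#' @param sampling_rate Sensor sampling rate recorded in the artifact
#'   (default 50 Hz).
#' @param user_id User id recorded in the artifact; defaults to the batch's.
#' @param class_levels Optional character vector fixing the class space
#'   (e.g. the union bank for a cross-user model); defaults to the labels
#'   present in `batch`. Every level must have windows in the batch.
#' @param split Optional pre-specified partition, a list with integer
#'   window indices `train` and `val`; defaults to an internal stratified
#'   split. The evaluation experiments pass the same per-user partition to
#'   both arms so their accuracies are estimated on identical windows.
#' @return A list with `artifact` (a `model_artifact`) and `report` (a
#'   `training_report` with per-epoch train/validation loss, validation
#'   accuracy, `stopped_epoch` and `stop_reason`).
#' @export
train <- function(batch, scaler, model_cfg = NULL,
                  train_cfg = train_config(), sampling_rate = 50,
                  user_id = NULL, class_levels = NULL, split = NULL) {
  stopifnot(inherits(batch, "window_batch"))
  if (is.null(batch$labels) || anyNA(batch$labels)) {
    stop("training requires a fully labeled window batch")
  }
  levels <- if (is.null(class_levels)) sort(unique(batch$labels))
            else sort(class_levels)
  missing_cl <- setdiff(levels, unique(batch$labels))
  if (length(missing_cl) > 0) {
    stop("class(es) absent from the training data: ",
         paste(missing_cl, collapse = ", "))
  }
  if (!all(batch$labels %in% levels)) {
    stop("batch contains labels outside the declared class space")
  }
  gesture_map <- stats::setNames(seq_along(levels) - 1L, levels)
  y <- gesture_map[batch$labels]
  d <- dim(batch$windows)
  if (is.null(model_cfg)) model_cfg <- model_config(d[2], length(levels), d[3])
  if (model_cfg$n_classes != length(levels)) {
    stop("model_cfg$n_classes (", model_cfg$n_classes,
         ") does not match the number of classes (", length(levels), ")")
  }
  sp <- if (is.null(split)) {
    stratified_split(batch$labels, train_cfg$validation_fraction,
                     train_cfg$seed)
  } else {
    if (!setequal(c(split$train, split$val), seq_along(batch$labels)) ||
        length(intersect(split$train, split$val)) > 0) {
      stop("split must partition the batch's window indices")
    }
    missing_tr <- setdiff(levels, unique(batch$labels[split$train]))
    if (length(missing_tr) > 0) {
      stop("class(es) absent from the training split: ",
           paste(missing_tr, collapse = ", "))
    }
    list(train = as.integer(split$train), val = sort(as.integer(split$val)))
  }
  Xtr <- batch$windows[sp$train, , , drop = FALSE]
  ytr <- y[sp$train]
  Xva <- batch$windows[sp$val, , , drop = FALSE]
  yva <- y[sp$val]

  model <- build_model(model_cfg, seed = train_cfg$seed)
  opt <- adam_init(model$params)
  tr_loss <- va_loss <- va_acc <- numeric(0)
  best <- list(loss = Inf, params = model$params, epoch = 0L)
  ntr <- length(ytr)
  stop_reason <- "max_epochs"
  stopped <- train_cfg$max_epochs
  for (epoch in seq_len(train_cfg$max_epochs)) {
    ord <- with_seed(derive_seed(train_cfg$seed, 505L, epoch), sample(ntr))
    epoch_loss <- 0
    nb <- 0L
    for (b0 in seq.int(1L, ntr, by = train_cfg$batch_size)) {
      idx <- ord[b0:min(b0 + train_cfg$batch_size - 1L, ntr)]
      lg <- cnn_loss_grads(model, Xtr[idx, , , drop = FALSE], ytr[idx])
      upd <- adam_step(model$params, lg$grads, opt,
                       lr = train_cfg$learning_rate)
      model$params <- upd$params
      opt <- upd$state
      epoch_loss <- epoch_loss + lg$loss
      nb <- nb + 1L
    }
    tr_loss[epoch] <- epoch_loss / nb
    ev <- evaluate_model(model, Xva, yva)
    va_loss[epoch] <- ev$loss
    va_acc[epoch] <- ev$accuracy
    if (ev$loss < best$loss) {
      best <- list(loss = ev$loss, params = model$params, epoch = epoch)
    }
    if (epoch >= train_cfg$min_epochs &&
        epochs_without_improvement(va_loss) >= train_cfg$early_stop_patience) {
      stopped <- epoch
      stop_reason <- "early_stop"
      break
    }
    if (epoch == train_cfg$max_epochs) stopped <- epoch
  }
  model$params <- best$params
  best_ev <- evaluate_model(model, Xva, yva)
  artifact <- model_artifact(
    weights = model$params, model_cfg = model_cfg, gesture_map = gesture_map,
    scaler = scaler,
    sensor_config = list(n_channels = d[2], sampling_rate = sampling_rate),
    user_id = if (is.null(user_id)) batch$user_id else user_id
  )
  report <- structure(
    list(train_loss = tr_loss, val_loss = va_loss, val_accuracy = va_acc,
         stopped_epoch = stopped, stop_reason = stop_reason,
         best_epoch = best$epoch, best_val_loss = best_ev$loss,
         best_val_accuracy = best_ev$accuracy, val_indices = sp$val),
    class = "training_report"
  )
  list(artifact = artifact, report = report)
}

#' @export
print.training_report <- function(x, ...) {
  cat(sprintf(
    "<training_report> stopped at epoch %d (%s); best epoch %d: val loss %.4f, val accuracy %.3f\n",
    x$stopped_epoch, x$stop_reason, x$best_epoch, x$best_val_loss,
    x$best_val_accuracy))
  invisible(x)
}

# Loss and window-level accuracy of `model` on (X, y); y 0-based.
evaluate_model <- function(model, X, y) {
  logits <- cnn_forward(model, X)
  P <- softmax_rows(logits)
  idx <- cbind(seq_along(y), y + 1L)
  pred <- max.col(P, ties.method = "first") - 1L
  list(loss = -mean(log(pmax(P[idx], 1e-12))), accuracy = mean(pred == y))
}

artifact_model <- function(artifact) {
  structure(list(cfg = artifact$model_cfg, params = artifact$weights),
            class = "cnn_model")
}

#' Classify a standardized window
#'
#' Pure function from a standardized window to a gesture label and a
#' softmax probability vector (sums to 1; argmax ties break to the lowest
#' class index).
#'
#' @param artifact A `model_artifact`.
#' @param window Numeric matrix `channels x window_len` (standardized with
#'   the artifact's scaler), or an array of several such windows
#'   (`n x channels x window_len`).
#' @return For one window, a list with `label` and `probabilities` (named by
#'   gesture); for an array, a list with vectors `label` and matrix
#'   `probabilities`.
#' @export
predict_window <- function(artifact, window) {
  stopifnot(inherits(artifact, "model_artifact"))
  cfg <- artifact$model_cfg
  single <- is.matrix(window)
  X <- if (single) array(window, dim = c(1, nrow(window), ncol(window)))
       else window
  d <- dim(X)
  if (length(d) != 3 || d[2] != cfg$n_channels || d[3] != cfg$window_len) {
    stop("window shape mismatch: expected ", cfg$n_channels, " x ",
         cfg$window_len, ", got ", paste(d[-1], collapse = " x "))
  }
  P <- softmax_rows(cnn_forward(artifact_model(artifact), X))
  levels <- names(sort(artifact$gesture_map))
  colnames(P) <- levels
  lab <- levels[max.col(P, ties.method = "first")]
  if (single) list(label = lab, probabilities = P[1, ])
  else list(label = lab, probabilities = P)
}

#' Majority label over a set of window predictions
#'
#' Repetition-level decision: the most frequent window label, ties broken
#' alphabetically. Complements the window-level accuracy reported by
#' training.
#'
#' @param labels Character vector of window-level predicted labels.
#' @return The majority label.
#' @export
majority_label <- function(labels) {
  tab <- table(labels)
  sort(names(tab)[tab == max(tab)])[1]
}
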