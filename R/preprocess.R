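# Preprocessing pipeline: z-score standardization with persisted per-channel
# parameters (fit on training data only, reused verbatim at inference), and
# sliding-window segmentation into fixed-length model inputs.

#' Windowing configuration
#'
#' @param window_len Window length in samples (default 32).
#' @param overlap_fraction Overlap between consecutive windows in `[0, 1)`
#'   (default 0.5, i.e. stride 16 for a 32-sample window).
#' @param label_rule How to label a window from per-sample labels:
#'   `"majority"` (ties broken by the center sample's label) or `"center"`.
#' @return An object of class `windowing_config` with derived `stride`.
#' @export
windowing_config <- function(window_len = 32L, overlap_fraction = 0.5,
                             label_rule = c("majority", "center")) {
  label_rule <- match.arg(label_rule)
  if (window_len < 1) stop("window_len must be >= 1")
  if (overlap_fraction < 0 || overlap_fraction >= 1) {
    stop("overlap_fraction must lie in [0, 1)")
  }
  stride <- max(1L, as.integer(round(window_len * (1 - overlap_fraction))))
  structure(
    list(window_len = as.integer(window_len),
         overlap_fraction = overlap_fraction,
         stride = stride, label_rule = label_rule),
    class = "windowing_config"
  )
}

# Pull a time x channels sample matrix out of a recording, matrix, or list
# of recordings (rbound).
as_sample_matrix <- function(x) {
  if (inherits(x, "semg_recording")) return(x$samples)
  if (is.matrix(x)) return(x)
  if (is.list(x)) {
    return(do.call(rbind, lapply(x, as_sample_matrix)))
  }
  stop("expected a recording, matrix, or list of recordings")
}

#' Fit per-channel standardization parameters
#'
#' Computes per-channel mean and population standard deviation over the
#' pooled training samples (Eq. `z = (x - mu) / sigma`). Channels with zero
#' spread are flagged `degenerate` and guarded with `epsilon` so the
#' transform maps them to zero instead of dividing by zero. The fitted
#' parameters are stored in the model artifact and reused verbatim at
#' inference so training and deployment see identically scaled data.
#'
#' @param x Training data: an `semg_recording`, a samples matrix, or a list
#'   of recordings (pooled).
#' @param epsilon Guard used in place of a zero standard deviation
#'   (default 1e-8 mV).
#' @return An object of class `scaler_params` with fields `mean`, `sd`,
#'   `epsilon` and logical `degenerate` per channel.
#' @export
fit_scaler <- function(x, epsilon = 1e-8) {
  m <- as_sample_matrix(x)
  if (nrow(m) < 2) stop("need at least 2 samples per channel to fit a scaler")
  mu <- unname(colMeans(m))
  # population (1/n) standard deviation: deployment consistency over
  # unbiasedness
  sig <- unname(sqrt(colMeans(sweep(m, 2, mu)^2)))
  structure(
    list(mean = mu, sd = sig, epsilon = epsilon, degenerate = sig == 0),
    class = "scaler_params"
  )
}

#' Apply (or invert) fitted standardization
#'
#' Pure elementwise map `z = (x - mu) / max(sigma, epsilon)` per channel;
#' never refits or mutates the parameters.
#'
#' @param x An `semg_recording` or samples matrix with matching channel
#'   count.
#' @param params A `scaler_params`.
#' @return Standardized object of the same type as `x`.
#' @export
apply_scaler <- function(x, params) {
  if (inherits(x, "semg_recording")) {
    x$samples <- apply_scaler(x$samples, params)
    return(x)
  }
  m <- as.matrix(x)
  if (ncol(m) != length(params$mean)) {
    stop("channel mismatch: data has ", ncol(m), " channels, scaler has ",
         length(params$mean))
  }
  sweep(sweep(m, 2, params$mean), 2, pmax(params$sd, params$epsilon), `/`)
}

#' @rdname apply_scaler
#' @export
inverse_scaler <- function(x, params) {
  if (inherits(x, "semg_recording")) {
    x$samples <- inverse_scaler(x$samples, params)
    return(x)
  }
  m <- as.matrix(x)
  if (ncol(m) != length(params$mean)) {
    stop("channel mismatch: data has ", ncol(m), " channels, scaler has ",
         length(params$mean))
  }
  sweep(sweep(m, 2, pmax(params$sd, params$epsilon), `*`), 2, params$mean, `+`)
}

#' Construct a window batch
#'
#' @param windows Numeric array `n_windows x channels x window_len`.
#' @param labels Character gesture labels, one per window (or `NULL`).
#' @param user_id Source user id.
#' @return An object of class `window_batch`.
#' @export
window_batch <- function(windows, labels = NULL, user_id = NA_character_) {
  stopifnot(length(dim(windows)) == 3)
  if (!is.null(labels) && length(labels) != dim(windows)[1]) {
    stop("labels length must equal the number of windows")
  }
  structure(list(windows = windows, labels = labels, user_id = user_id),
            class = "window_batch")
}

#' @export
print.window_batch <- function(x, ...) {
  d <- dim(x$windows)
  cat(sprintf("<window_batch> %d windows x %d channels x %d samples (user %s)\n",
              d[1], d[2], d[3], x$user_id))
  invisible(x)
}

#' Combine window batches into one
#'
#' @param ... `window_batch` objects with identical channel count and window
#'   length.
#' @return A single `window_batch`; `user_id` is kept only if shared.
#' @export
bind_batches <- function(...) {
  bs <- list(...)
  if (length(bs) == 1 && is.list(bs[[1]]) && !inherits(bs[[1]], "window_batch")) {
    bs <- bs[[1]]
  }
  d <- dim(bs[[1]]$windows)[2:3]
  n <- sum(vapply(bs, function(b) dim(b$windows)[1], integer(1)))
  w <- array(0, dim = c(n, d[1], d[2]))
  labs <- character(0)
  at <- 0
  for (b in bs) {
    k <- dim(b$windows)[1]
    if (!all(dim(b$windows)[2:3] == d)) stop("window geometries differ")
    if (k > 0) w[at + seq_len(k), , ] <- b$windows
    labs <- c(labs, if (is.null(b$labels)) rep(NA_character_, k) else b$labels)
    at <- at + k
  }
  uids <- unique(vapply(bs, function(b) b$user_id, character(1)))
  window_batch(w, labs, if (length(uids) == 1) uids else NA_character_)
}

#' Segment a recording into fixed-length windows
#'
#' Slides a `window_len`-sample window at the configured stride; a window
#' starting at 0-based index `s` is kept only when `s + window_len` fits
#' inside the recording, so the incomplete tail is dropped. Window labels
#' come from the recording's gesture id (broadcast) or from `sample_labels`
#' via the configured rule. A recording shorter than one window yields an
#' empty batch.
#'
#' @param rec An `semg_recording` (already standardized, if the windows feed
#'   a model).
#' @param cfg A `windowing_config`.
#' @param sample_labels Optional per-sample label vector overriding the
#'   recording label.
#' @return A `window_batch` with windows `n x channels x window_len`.
#' @export
segment_windows <- function(rec, cfg, sample_labels = NULL) {
  stopifnot(inherits(rec, "semg_recording"), inherits(cfg, "windowing_config"))
  m <- rec$samples
  n <- nrow(m); C <- ncol(m)
  wl <- cfg$window_len; st <- cfg$stride
  starts <- if (n >= wl) seq.int(1L, n - wl + 1L, by = st) else integer(0)
  w <- array(0, dim = c(length(starts), C, wl))
  labs <- NULL
  if (is.null(sample_labels) && !is.null(rec$gesture_id)) {
    labs <- rep(rec$gesture_id, length(starts))
  } else if (!is.null(sample_labels)) {
    if (length(sample_labels) != n) {
      stop("sample_labels length must equal the number of samples")
    }
    labs <- character(length(starts))
  }
  for (i in seq_along(starts)) {
    idx <- starts[i]:(starts[i] + wl - 1L)
    w[i, , ] <- t(m[idx, , drop = FALSE])
    if (!is.null(sample_labels)) {
      seg <- sample_labels[idx]
      center <- seg[ceiling(wl / 2)]
      if (cfg$label_rule == "center") {
        labs[i] <- center
      } else {
        tab <- table(seg)
        top <- names(tab)[tab == max(tab)]
        labs[i] <- if (length(top) == 1) top
                   else if (center %in% top) center else sort(top)[1]
      }
    }
  }
  window_batch(w, labs, rec$user_id)
}

#' Emulate envelope extraction from a raw sEMG signal
#'
#' Mirrors the analog envelope chain of an sEMG sensor front-end: full-wave
#' rectification, a first-order low-pass smoother (default cutoff 3.6 Hz),
#' then decimation to the target rate. Output samples are non-negative.
#'
#' @param raw An `semg_recording` sampled well above the cutoff.
#' @param lowpass_cutoff Smoother cutoff in Hz (default 3.6).
#' @param target_rate Output sampling rate in Hz (default 50).
#' @return An `semg_recording` at `target_rate`.
#' @export
envelope_from_raw <- function(raw, lowpass_cutoff = 3.6, target_rate = 50) {
  stopifnot(inherits(raw, "semg_recording"))
  if (raw$sampling_rate <= 2 * lowpass_cutoff) {
    stop("raw sampling rate must exceed twice the low-pass cutoff")
  }
  if (lowpass_cutoff > target_rate / 2) {
    stop("low-pass cutoff above the Nyquist frequency of the target rate")
  }
  rect <- abs(raw$samples)
  dt <- 1 / raw$sampling_rate
  rc <- 1 / (2 * pi * lowpass_cutoff)
  alpha <- dt / (rc + dt)
  smooth <- apply(rect, 2, function(ch) {
    if (length(ch) == 0) return(ch)
    as.numeric(stats::filter(alpha * ch, 1 - alpha, method = "recursive",
                             init = 0))
  })
  if (nrow(rect) <= 1) smooth <- matrix(smooth, nrow = nrow(rect))
  dec <- max(1L, round(raw$sampling_rate / target_rate))
  keep <- seq.int(1L, nrow(rect), by = dec)
  recording(smooth[keep, , drop = FALSE], raw$sampling_rate / dec,
            raw$user_id, gesture_id = raw$gesture_id)
}
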