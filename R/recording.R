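#' Construct an sEMG envelope recording
#'
#' A recording is the unit of training data: a time-by-channel matrix of
#' envelope samples (mV) for one user at a fixed sampling rate, optionally
#' carrying a gesture label and per-sample timestamps.
#'
#' @param samples Numeric matrix, time (rows) by channels (columns), in mV.
#' @param sampling_rate Sampling rate in Hz; must be positive.
#' @param user_id Character user identifier.
#' @param gesture_id Optional gesture label for the whole recording.
#' @param timestamps Optional numeric vector of per-sample times in seconds;
#'   when present its spacing must be consistent with `sampling_rate`.
#' @return An object of class `semg_recording`.
#' @export
recording <- function(samples, sampling_rate, user_id,
                      gesture_id = NULL, timestamps = NULL) {
  samples <- as.matrix(samples)
  if (nrow(samples) > 0 && !all(is.finite(samples))) {
    stop("recording samples must be finite")
  }
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1 ||
      sampling_rate <= 0) {
    stop("sampling_rate must be a single positive number")
  }
  if (!is.null(timestamps)) {
    if (length(timestamps) != nrow(samples)) {
      stop("timestamps length must equal the number of samples")
    }
    if (length(timestamps) > 1) {
      dt <- diff(timestamps)
      if (any(abs(dt - 1 / sampling_rate) > 0.5 / sampling_rate)) {
        stop("timestamp spacing inconsistent with sampling_rate")
      }
    }
  }
  if (is.null(colnames(samples)) && ncol(samples) > 0) {
    colnames(samples) <- paste0("ch", seq_len(ncol(samples)))
  }
  structure(
    list(user_id = as.character(user_id),
         sampling_rate = sampling_rate,
         samples = samples,
         gesture_id = if (is.null(gesture_id)) NULL else as.character(gesture_id),
         timestamps = timestamps),
    class = "semg_recording"
  )
}

#' @export
print.semg_recording <- function(x, ...) {
  cat(sprintf("<semg_recording> user '%s': %d samples x %d channels @ %g Hz",
              x$user_id, nrow(x$samples), ncol(x$samples), x$sampling_rate))
  if (!is.null(x$gesture_id)) cat(sprintf(", gesture '%s'", x$gesture_id))
  cat("\n")
  invisible(x)
}

#' @export
dim.semg_recording <- function(x) dim(x$samples)

n_channels <- function(rec) ncol(rec$samples)
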