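# Online inference over packet streams. A per-segment buffer holds the last
# window_len standardized samples; an emission fires exactly when
# samples_seen >= window_len and (samples_seen - window_len) %% stride == 0,
# which makes the k-th emission equal to batch prediction on the k-th
# sliding window of the same samples. A timestamp jump larger than twice the
# nominal sample period is treated as a stream gap: the buffer resets, so no
# window ever mixes pre- and post-gap samples.

#' Run streaming gesture inference over a packet stream
#'
#' Feeds packets through the artifact's stored scaler and model, emitting a
#' classification per stride. Emissions are elementwise identical to batch
#' prediction on the gap-delimited segments of the same stream; the
#' emission timestamp is the timestamp of the window's last sample.
#'
#' @param packets A `packet_stream` (rows ordered by `ts_ms`).
#' @param artifact A `model_artifact`; its scaler parameters standardize the
#'   stream, and its sensor configuration sets the nominal sample period for
#'   gap detection.
#' @param cfg A `windowing_config` (default: 32-sample windows, 50%
#'   overlap).
#' @param instrument When `TRUE`, per-emission buffer-update and inference
#'   durations are recorded and attached (see [latency_summary()]);
#'   instrumentation never changes the emissions.
#' @return A data frame with `ts_ms`, `label` and one `p_<gesture>`
#'   probability column per class, one row per emission.
#' @export
stream_infer <- function(packets, artifact, cfg = windowing_config(),
                         instrument = FALSE) {
  stopifnot(inherits(artifact, "model_artifact"),
            inherits(cfg, "windowing_config"))
  chcols <- grep("^ch[0-9]+$", names(packets), value = TRUE)
  C <- artifact$sensor_config$n_channels
  if (length(chcols) != C) {
    stop("channel mismatch: stream has ", length(chcols),
         " channels, artifact expects ", C)
  }
  wl <- cfg$window_len
  stride <- cfg$stride
  period_ms <- 1000 / artifact$sensor_config$sampling_rate
  levels <- names(sort(artifact$gesture_map))
  n <- nrow(packets)
  raw <- as.matrix(packets[, chcols, drop = FALSE])
  ts <- packets$ts_ms

  buffer <- matrix(0, C, wl)
  seen <- 0L
  out_ts <- numeric(0); out_lab <- character(0)
  out_p <- matrix(numeric(0), 0, length(levels))
  lat_buf <- numeric(0); lat_inf <- numeric(0)
  for (i in seq_len(n)) {
    if (i > 1 && ts[i] - ts[i - 1] > 2 * period_ms) {
      seen <- 0L # stream gap: reset, discard partial window
    }
    t0 <- if (instrument) proc.time()[3]
    z <- (raw[i, ] - artifact$scaler$mean) /
      pmax(artifact$scaler$sd, artifact$scaler$epsilon)
    buffer <- cbind(buffer[, -1, drop = FALSE], z)
    seen <- seen + 1L
    t1 <- if (instrument) proc.time()[3]
    if (seen >= wl && (seen - wl) %% stride == 0L) {
      pr <- predict_window(artifact, buffer)
      out_ts <- c(out_ts, ts[i])
      out_lab <- c(out_lab, pr$label)
      out_p <- rbind(out_p, pr$probabilities)
      if (instrument) {
        t2 <- proc.time()[3]
        lat_buf <- c(lat_buf, (t1 - t0) * 1000)
        lat_inf <- c(lat_inf, (t2 - t1) * 1000)
      }
    }
  }
  res <- data.frame(ts_ms = out_ts, label = out_lab,
                    stringsAsFactors = FALSE)
  for (j in seq_along(levels)) res[[paste0("p_", levels[j])]] <- out_p[, j]
  if (instrument) {
    attr(res, "latency") <- data.frame(buffer_ms = lat_buf,
                                       inference_ms = lat_inf)
  }
  res
}

#' Summarize per-emission latency instrumentation
#'
#' Aggregates the buffer-update and inference durations recorded by
#' `stream_infer(..., instrument = TRUE)` into mean and 95th-percentile
#' figures. Reported for monitoring only; absolute values depend on the
#' host.
#'
#' @param emissions Result of an instrumented [stream_infer()] call.
#' @return Data frame with one row per stage (`buffer`, `inference`,
#'   `total`) and columns `mean_ms`, `p95_ms`, `n`.
#' @export
latency_summary <- function(emissions) {
  lat <- attr(emissions, "latency")
  if (is.null(lat)) stop("emissions carry no latency instrumentation")
  tot <- lat$buffer_ms + lat$inference_ms
  data.frame(
    stage = c("buffer", "inference", "total"),
    mean_ms = c(mean(lat$buffer_ms), mean(lat$inference_ms), mean(tot)),
    p95_ms = c(stats::quantile(lat$buffer_ms, 0.95),
               stats::quantile(lat$inference_ms, 0.95),
               stats::quantile(tot, 0.95)),
    n = nrow(lat),
    stringsAsFactors = FALSE
  )
}

# Batch-mode reference for the streaming path: split the stream at gaps,
# window each segment, and predict every window. Used by tests to assert
# streaming/batch equivalence.
batch_infer <- function(packets, artifact, cfg = windowing_config()) {
  chcols <- grep("^ch[0-9]+$", names(packets), value = TRUE)
  period_ms <- 1000 / artifact$sensor_config$sampling_rate
  ts <- packets$ts_ms
  seg_id <- cumsum(c(0, diff(ts) > 2 * period_ms))
  levels <- names(sort(artifact$gesture_map))
  out <- NULL
  for (s in unique(seg_id)) {
    rows <- which(seg_id == s)
    m <- apply_scaler(as.matrix(packets[rows, chcols, drop = FALSE]),
                      artifact$scaler)
    rec <- recording(m, artifact$sensor_config$sampling_rate, "stream")
    wb <- segment_windows(rec, cfg)
    nw <- dim(wb$windows)[1]
    if (nw == 0) next
    # predict one window at a time: elementwise identical to the streaming
    # path (a pooled forward pass can differ in the last float bit because
    # BLAS may reassociate sums across batch shapes)
    preds <- lapply(seq_len(nw), function(i) {
      predict_window(artifact, wb$windows[i, , ])
    })
    starts <- seq.int(1L, by = cfg$stride, length.out = nw)
    df <- data.frame(ts_ms = ts[rows[starts + cfg$window_len - 1L]],
                     label = vapply(preds, `[[`, character(1), "label"),
                     stringsAsFactors = FALSE)
    pm <- do.call(rbind, lapply(preds, `[[`, "probabilities"))
    for (j in seq_along(levels)) {
      df[[paste0("p_", levels[j])]] <- pm[, j]
    }
    out <- rbind(out, df)
  }
  if (is.null(out)) {
    out <- data.frame(ts_ms = numeric(0), label = character(0),
                      stringsAsFactors = FALSE)
    for (lv in levels) out[[paste0("p_", lv)]] <- numeric(0)
  }
  out
}
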