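# Packet wire format: one JSON object per line with keys ts_ms (integer
# milliseconds since stream epoch), user_id and ch (array of per-channel
# envelope values in mV). Line framing keeps the stream loss-tolerant: a
# corrupted line damages only itself, mirroring datagram semantics.

#' Convert a recording into a packet stream
#'
#' Emits one packet per sample; sample `k` (0-based) carries timestamp
#' `round(1000 * k / sampling_rate)` ms, so a 50 Hz recording yields
#' consecutive timestamps 20 ms apart. [recording_from_packets()] inverts the
#' conversion exactly.
#'
#' @param rec An `semg_recording`.
#' @return A data frame with columns `ts_ms`, `user_id` and one `chK` column
#'   per channel, one row per packet, of class `packet_stream`.
#' @export
packets_from_recording <- function(rec) {
  stopifnot(inherits(rec, "semg_recording"))
  n <- nrow(rec$samples)
  C <- ncol(rec$samples)
  df <- data.frame(
    ts_ms = if (n > 0) round(1000 * (seq_len(n) - 1) / rec$sampling_rate) else integer(0),
    user_id = rep(rec$user_id, n),
    stringsAsFactors = FALSE
  )
  for (ch in seq_len(C)) df[[paste0("ch", ch)]] <- rec$samples[, ch]
  attr(df, "sampling_rate") <- rec$sampling_rate
  class(df) <- c("packet_stream", "data.frame")
  df
}

#' Reassemble a recording from a packet stream
#'
#' @param packets A `packet_stream` (or data frame with `ts_ms`, `user_id`
#'   and `chK` columns).
#' @param sampling_rate Sampling rate in Hz; defaults to the stream's
#'   attribute, or is inferred from the median timestamp spacing.
#' @return An `semg_recording`.
#' @export
recording_from_packets <- function(packets, sampling_rate = NULL) {
  chcols <- grep("^ch[0-9]+$", names(packets), value = TRUE)
  if (is.null(sampling_rate)) sampling_rate <- attr(packets, "sampling_rate")
  if (is.null(sampling_rate)) {
    if (nrow(packets) < 2) stop("cannot infer sampling_rate from < 2 packets")
    sampling_rate <- 1000 / stats::median(diff(packets$ts_ms))
  }
  uid <- if (nrow(packets) > 0) packets$user_id[1] else "unknown"
  recording(as.matrix(packets[, chcols, drop = FALSE]), sampling_rate, uid)
}

#' Write a packet stream as JSON lines
#'
#' @param packets A `packet_stream`.
#' @param path Destination file path.
#' @return `path`, invisibly.
#' @export
write_packet_stream <- function(packets, path) {
  chcols <- grep("^ch[0-9]+$", names(packets), value = TRUE)
  lines <- vapply(seq_len(nrow(packets)), function(i) {
    jsonlite::toJSON(
      list(ts_ms = packets$ts_ms[i], user_id = packets$user_id[i],
           ch = as.numeric(packets[i, chcols])),
      auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a packet stream, tolerating loss and corruption
#'
#' Parses a JSON-lines packet file the way a datagram receiver would: lines
#' that are not valid JSON, lack the required fields, carry the wrong channel
#' count or run backwards in time are dropped and counted, never fatal. A
#' warning is raised when more than half the lines are dropped.
#'
#' @param path Source file path.
#' @param expected_channels Required channel count per packet.
#' @return A `packet_stream` data frame of the surviving packets, with
#'   attribute `dropped` (count of discarded lines).
#' @export
read_packet_stream <- function(path, expected_channels) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  dropped <- 0L
  ts <- numeric(0); uid <- character(0)
  chmat <- matrix(numeric(0), nrow = 0, ncol = expected_channels)
  last_ts <- -Inf
  for (ln in lines) {
    p <- tryCatch(jsonlite::fromJSON(ln), error = function(e) NULL)
    ok <- !is.null(p) && is.list(p) &&
      all(c("ts_ms", "user_id", "ch") %in% names(p)) &&
      is.numeric(p$ts_ms) && length(p$ts_ms) == 1 && is.finite(p$ts_ms) &&
      is.numeric(p$ch) && length(p$ch) == expected_channels &&
      all(is.finite(p$ch)) && p$ts_ms >= last_ts
    if (!ok) { dropped <- dropped + 1L; next }
    ts <- c(ts, p$ts_ms)
    uid <- c(uid, as.character(p$user_id))
    chmat <- rbind(chmat, p$ch)
    last_ts <- p$ts_ms
  }
  if (length(lines) > 0 && dropped > length(lines) / 2) {
    warning(sprintf("dropped %d of %d packet lines (> 50%%)",
                    dropped, length(lines)))
  }
  df <- data.frame(ts_ms = ts, user_id = uid, stringsAsFactors = FALSE)
  for (ch in seq_len(expected_channels)) {
    df[[paste0("ch", ch)]] <- if (nrow(chmat) > 0) chmat[, ch] else numeric(0)
  }
  attr(df, "dropped") <- dropped
  class(df) <- c("packet_stream", "data.frame")
  df
}
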