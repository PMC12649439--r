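# Recording file format: CSV with header "time_s,ch1..chN,label". Values are
# written with 17 significant digits so a read-back reproduces the samples to
# within double-precision round-off. Parsing is line-wise so malformed input
# can be reported with its line number.

#' Write a recording to CSV
#'
#' Columns are `time_s`, one `chK` column per channel, and `label` (the
#' recording's gesture id, empty when unlabeled). The user id and sampling
#' rate are carried in `#`-prefixed header comments so the file is
#' self-describing.
#'
#' @param rec An `semg_recording`.
#' @param path Destination file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "semg_recording"))
  n <- nrow(rec$samples)
  C <- ncol(rec$samples)
  t_s <- if (!is.null(rec$timestamps)) rec$timestamps
         else (seq_len(n) - 1) / rec$sampling_rate
  label <- if (is.null(rec$gesture_id)) "" else rec$gesture_id
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# user_id: %s", rec$user_id),
    sprintf("# sampling_rate: %.17g", rec$sampling_rate),
    paste(c("time_s", paste0("ch", seq_len(C)), "label"), collapse = ",")
  ), con)
  if (n > 0) {
    body <- apply(cbind(sprintf("%.17g", t_s),
                        matrix(sprintf("%.17g", rec$samples), n, C),
                        rep(label, n)),
                  1, paste, collapse = ",")
    writeLines(body, con)
  }
  invisible(path)
}

#' Read a recording from CSV
#'
#' Inverse of [write_recording()]: reproduces samples to within 1e-9 relative
#' error and user id, sampling rate and label exactly. Malformed input (bad
#' header, ragged rows, non-numeric cells) raises a parse error naming the
#' offending line.
#'
#' @param path Source file path.
#' @return An `semg_recording`.
#' @export
read_recording <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta <- grep("^#", lines, value = TRUE)
  uid <- sub("^# user_id:\\s*", "", grep("^# user_id:", meta, value = TRUE)[1])
  rate <- as.numeric(sub("^# sampling_rate:\\s*", "",
                         grep("^# sampling_rate:", meta, value = TRUE)[1]))
  if (is.na(uid) || is.na(rate)) stop("parse error: missing user_id/sampling_rate header comments")
  body_idx <- which(!grepl("^#", lines))
  if (length(body_idx) == 0) stop("parse error: missing column header line")
  header <- strsplit(lines[body_idx[1]], ",", fixed = TRUE)[[1]]
  C <- sum(grepl("^ch[0-9]+$", header))
  if (header[1] != "time_s" || header[length(header)] != "label" ||
      C != length(header) - 2) {
    stop("parse error at line ", body_idx[1], ": expected header time_s,ch1..chN,label")
  }
  rows <- body_idx[-1]
  n <- length(rows)
  samples <- matrix(0, n, C)
  t_s <- numeric(n)
  label <- character(n)
  for (i in seq_len(n)) {
    ln <- rows[i]
    cells <- strsplit(lines[ln], ",", fixed = TRUE)[[1]]
    # a trailing empty label cell is dropped by strsplit; restore it
    if (length(cells) == C + 1) cells <- c(cells, "")
    if (length(cells) != C + 2) {
      stop("parse error at line ", ln, ": expected ", C + 2, " cells, found ",
           length(cells))
    }
    vals <- suppressWarnings(as.numeric(cells[seq_len(C + 1)]))
    if (any(is.na(vals))) {
      stop("parse error at line ", ln, ": non-numeric cell")
    }
    t_s[i] <- vals[1]
    samples[i, ] <- vals[-1]
    label[i] <- cells[C + 2]
  }
  gid <- unique(label[label != ""])
  recording(samples, rate, uid,
            gesture_id = if (length(gid) == 1) gid else NULL,
            timestamps = if (n > 0) t_s else NULL)
}
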