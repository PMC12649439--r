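# Vibrotactile encoding for a ten-motor arm sleeve. A symbol is a short
# spatiotemporal pattern of ERM coin-motor activations; a message is the
# concatenation of its symbols' patterns separated by a fixed silent gap.
# Maps are fully config-driven and injective by construction, and encode()
# has an exact inverse for round-trip verification.

#' Construct a motor event
#'
#' @param motor_index Motor position on the sleeve, 0-based, below
#'   `n_motors`.
#' @param start Onset in ms from pattern start (>= 0).
#' @param duration Vibration duration in ms (> 0).
#' @param intensity Drive level in (0, 1] (default 1).
#' @param n_motors Sleeve size used for validation (default 10).
#' @return A one-row data frame with columns `motor_index`, `start`,
#'   `duration`, `intensity`.
#' @export
motor_event <- function(motor_index, start, duration, intensity = 1,
                        n_motors = 10L) {
  if (motor_index < 0 || motor_index >= n_motors) {
    stop("motor_index must lie in [0, ", n_motors, ")")
  }
  if (duration <= 0) stop("duration must be > 0")
  if (start < 0) stop("start must be >= 0")
  if (intensity <= 0 || intensity > 1) stop("intensity must lie in (0, 1]")
  data.frame(motor_index = as.integer(motor_index), start = start,
             duration = duration, intensity = intensity)
}

#' Construct a haptic pattern
#'
#' @param events Data frame of motor events (possibly zero rows).
#' @param total_duration Pattern duration in ms; defaults to the latest
#'   event end. Must cover every event, and events on one motor must not
#'   overlap.
#' @param n_motors Sleeve size (default 10).
#' @return An object of class `haptic_pattern`.
#' @export
haptic_pattern <- function(events, total_duration = NULL, n_motors = 10L) {
  if (is.null(events) || nrow(events) == 0) {
    events <- data.frame(motor_index = integer(0), start = numeric(0),
                         duration = numeric(0), intensity = numeric(0))
    if (is.null(total_duration)) total_duration <- 0
  } else {
    if (any(events$motor_index < 0) || any(events$motor_index >= n_motors)) {
      stop("motor_index out of range for a ", n_motors, "-motor sleeve")
    }
    if (any(events$duration <= 0)) stop("event durations must be > 0")
    ends <- events$start + events$duration
    if (is.null(total_duration)) total_duration <- max(ends)
    if (total_duration < max(ends) - 1e-9) {
      stop("total_duration shorter than the last event")
    }
    for (m in unique(events$motor_index)) {
      e <- events[events$motor_index == m, ]
      e <- e[order(e$start), ]
      if (nrow(e) > 1 &&
          any(e$start[-1] < (e$start + e$duration)[-nrow(e)] - 1e-9)) {
        stop("overlapping events on motor ", m)
      }
    }
  }
  ord <- order(events$start, events$motor_index)
  structure(list(events = events[ord, , drop = FALSE],
                 total_duration = total_duration,
                 n_motors = as.integer(n_motors)),
            class = "haptic_pattern")
}

#' @export
print.haptic_pattern <- function(x, ...) {
  cat(sprintf("<haptic_pattern> %d events over %g ms on %d motors\n",
              nrow(x$events), x$total_duration, x$n_motors))
  invisible(x)
}

pattern_signature <- function(p) {
  if (nrow(p$events) == 0) return("empty")
  paste(sprintf("%d@%.3f+%.3fx%.3f", p$events$motor_index, p$events$start,
                p$events$duration, p$events$intensity),
        collapse = ";")
}

#' Construct an encoding map
#'
#' @param patterns Named list of `haptic_pattern`s, one per symbol; no two
#'   symbols may share an identical pattern and the empty pattern is not
#'   encodable.
#' @param gap_ms Silent gap inserted between consecutive symbols
#'   (default 100).
#' @param n_motors Sleeve size (default 10).
#' @return An object of class `encoding_map`.
#' @export
encoding_map <- function(patterns, gap_ms = 100, n_motors = 10L) {
  if (length(patterns) == 0) stop("encoding map needs at least one symbol")
  if (is.null(names(patterns)) || any(!nzchar(names(patterns)))) {
    stop("patterns must be named by their symbols")
  }
  sigs <- vapply(patterns, pattern_signature, character(1))
  if (any(sigs == "empty")) stop("symbols must have non-empty patterns")
  if (anyDuplicated(sigs)) {
    dup <- names(patterns)[duplicated(sigs) | duplicated(sigs, fromLast = TRUE)]
    stop("map is not injective: symbols ", paste(dup, collapse = ", "),
         " share a pattern")
  }
  bad <- vapply(patterns, function(p) p$n_motors > n_motors, logical(1))
  if (any(bad)) stop("pattern exceeds the sleeve's motor count")
  structure(list(patterns = patterns, gap_ms = gap_ms,
                 n_motors = as.integer(n_motors)),
            class = "encoding_map")
}

#' @export
print.encoding_map <- function(x, ...) {
  cat(sprintf("<encoding_map> %d symbols, %g ms gap, %d motors\n",
              length(x$patterns), x$gap_ms, x$n_motors))
  invisible(x)
}

#' Default letter map
#'
#' Maps A-Z onto the ten-motor sleeve by position/pulse-count coding: the
#' motor index encodes the letter's position within its group of ten, and
#' the number of short pulses (one, two or three) encodes the group. Every
#' symbol occupies a 300 ms slot.
#'
#' @param n_motors Sleeve size (default 10).
#' @param symbol_ms Symbol slot duration in ms (default 300).
#' @param gap_ms Inter-symbol gap in ms (default 100).
#' @return An `encoding_map` over `LETTERS`.
#' @export
default_letter_map <- function(n_motors = 10L, symbol_ms = 300,
                               gap_ms = 100) {
  pats <- lapply(seq_along(LETTERS) - 1L, function(i) {
    motor <- i %% n_motors
    pulses <- i %/% n_motors + 1L
    slot <- symbol_ms / pulses
    ev <- do.call(rbind, lapply(seq_len(pulses), function(p) {
      motor_event(motor, start = (p - 1) * slot, duration = 0.7 * slot,
                  n_motors = n_motors)
    }))
    haptic_pattern(ev, total_duration = symbol_ms, n_motors = n_motors)
  })
  names(pats) <- LETTERS
  encoding_map(pats, gap_ms = gap_ms, n_motors = n_motors)
}

#' Encode a message as a haptic pattern
#'
#' Concatenates the per-symbol patterns in message order, separated by the
#' map's inter-symbol gap; total duration is the sum of symbol durations
#' plus `(length - 1) * gap`.
#'
#' @param message Character string (or vector of symbols) over the map's
#'   alphabet.
#' @param map An `encoding_map`.
#' @return A `haptic_pattern`.
#' @export
haptic_encode <- function(message, map) {
  stopifnot(inherits(map, "encoding_map"))
  symbols <- if (length(message) == 1) strsplit(message, "")[[1]] else message
  if (length(symbols) == 0) return(haptic_pattern(NULL, 0, map$n_motors))
  unknown <- setdiff(symbols, names(map$patterns))
  if (length(unknown) > 0) {
    stop("symbol(s) not in the encoding map: ",
         paste(unique(unknown), collapse = ", "))
  }
  offset <- 0
  evs <- list()
  for (s in symbols) {
    p <- map$patterns[[s]]
    e <- p$events
    e$start <- e$start + offset
    evs[[length(evs) + 1]] <- e
    offset <- offset + p$total_duration + map$gap_ms
  }
  haptic_pattern(do.call(rbind, evs),
                 total_duration = offset - map$gap_ms,
                 n_motors = map$n_motors)
}

#' Decode a haptic pattern back into symbols
#'
#' Exact inverse of [haptic_encode()] under the same map: walks the pattern,
#' matching one symbol at a time at the current offset. A pattern that
#' cannot be segmented into the map's symbols raises a decode error naming
#' the failing offset.
#'
#' @param pattern A `haptic_pattern` produced by [haptic_encode()].
#' @param map The same `encoding_map`.
#' @return Character vector of decoded symbols (zero-length for the empty
#'   pattern).
#' @export
haptic_decode <- function(pattern, map) {
  stopifnot(inherits(pattern, "haptic_pattern"), inherits(map, "encoding_map"))
  ev <- pattern$events[order(pattern$events$start,
                             pattern$events$motor_index), , drop = FALSE]
  out <- character(0)
  offset <- 0
  row <- 1
  tol <- 1e-6
  while (row <= nrow(ev)) {
    matched <- NULL
    for (s in names(map$patterns)) {
      pe <- map$patterns[[s]]$events
      k <- nrow(pe)
      if (row + k - 1 > nrow(ev)) next
      cand <- ev[row:(row + k - 1), , drop = FALSE]
      if (all(cand$motor_index == pe$motor_index) &&
          all(abs(cand$start - (pe$start + offset)) < tol) &&
          all(abs(cand$duration - pe$duration) < tol) &&
          all(abs(cand$intensity - pe$intensity) < tol)) {
        matched <- s
        row <- row + k
        offset <- offset + map$patterns[[s]]$total_duration + map$gap_ms
        break
      }
    }
    if (is.null(matched)) {
      stop("decode error: no symbol matches at offset ", offset, " ms")
    }
    out <- c(out, matched)
  }
  out
}

#' Build an encoding map for a gesture bank
#'
#' Assigns each gesture a distinct sleeve pattern from a single-burst style
#' space (motor position x burst duration level), deterministically: sorted
#' gesture names take patterns in enumeration order. Requesting more
#' gestures than the style space holds raises a capacity error.
#'
#' @param gestures Character vector of gesture names (>= 1, unique).
#' @param n_motors Sleeve size (default 10).
#' @param duration_levels Available burst durations in ms
#'   (default `c(150, 300, 450)`), giving a capacity of
#'   `n_motors * length(duration_levels)` patterns.
#' @param gap_ms Inter-symbol gap (default 100).
#' @return An `encoding_map` keyed by gesture name.
#' @export
map_from_gesture_bank <- function(gestures, n_motors = 10L,
                                  duration_levels = c(150, 300, 450),
                                  gap_ms = 100) {
  if (length(gestures) < 1) stop("need at least one gesture")
  if (anyDuplicated(gestures)) stop("gesture names must be unique")
  capacity <- n_motors * length(duration_levels)
  if (length(gestures) > capacity) {
    stop("capacity error: ", length(gestures), " gestures exceed the ",
         capacity, "-pattern space of this style")
  }
  gs <- sort(as.character(gestures))
  pats <- lapply(seq_along(gs) - 1L, function(i) {
    motor <- i %% n_motors
    dur <- duration_levels[i %/% n_motors + 1L]
    haptic_pattern(motor_event(motor, 0, dur, n_motors = n_motors),
                   n_motors = n_motors)
  })
  names(pats) <- gs
  encoding_map(pats, gap_ms = gap_ms, n_motors = n_motors)
}

#' Write / read an encoding map as JSON
#'
#' @param map An `encoding_map`.
#' @param path File path.
#' @return `write_encoding_map()` returns `path` invisibly;
#'   `read_encoding_map()` returns an `encoding_map`.
#' @export
write_encoding_map <- function(map, path) {
  payload <- list(
    gap_ms = map$gap_ms, n_motors = map$n_motors,
    symbols = lapply(map$patterns, function(p) {
      list(total_duration = p$total_duration,
           events = p$events)
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_encoding_map
#' @export
read_encoding_map <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  pats <- lapply(payload$symbols, function(s) {
    haptic_pattern(as.data.frame(s$events),
                   total_duration = s$total_duration,
                   n_motors = as.integer(payload$n_motors))
  })
  encoding_map(pats, gap_ms = payload$gap_ms,
               n_motors = as.integer(payload$n_motors))
}

#' Write a haptic pattern as JSON
#'
#' @param pattern A `haptic_pattern`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_haptic_pattern <- function(pattern, path) {
  jsonlite::write_json(
    list(total_duration = pattern$total_duration,
         n_motors = pattern$n_motors, events = pattern$events),
    path, auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(path)
}
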