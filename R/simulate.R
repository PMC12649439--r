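# Synthetic multi-channel sEMG envelope generator.
#
# Stands in for hardware acquisition and human subjects: gestures are
# per-channel activation envelopes (trapezoid or gaussian-burst profiles on a
# low baseline, peaks within the 0-10 mV range of a typical envelope-output
# sEMG sensor), and inter-user variability is a parametric phenotype
# (per-channel amplitude gains, onset timing jitter, a row-stochastic
# channel-mixing matrix emulating electrode shift/crosstalk, additive
# envelope noise and slow baseline drift), all scaled by a single
# variability level.

#' Envelope amplifier gain for a potentiometer setting
#'
#' Gain of the envelope-mode sEMG amplifier as a function of the gain
#' potentiometer resistance: `G = 200 * R / 1 kOhm`. The simulator uses it to
#' translate a configured resistance into an amplitude multiplier.
#'
#' @param R_kohm Potentiometer resistance in kilo-ohms; must be non-negative.
#' @return The dimensionless gain `200 * R_kohm`.
#' @examples
#' sensor_gain(1)   # 200
#' sensor_gain(2.5) # 500
#' @export
sensor_gain <- function(R_kohm) {
  if (!is.numeric(R_kohm) || any(!is.finite(R_kohm)) || any(R_kohm < 0)) {
    stop("R_kohm must be a non-negative finite resistance in kOhm")
  }
  200 * R_kohm
}

#' Simulation configuration
#'
#' @param n_channels Number of sEMG channels (default 4).
#' @param sampling_rate Envelope sampling rate in Hz (default 50).
#' @param repetition_duration Duration of one gesture repetition in seconds
#'   (default 3, a typical held-gesture collection protocol; 150 samples at
#'   50 Hz, i.e. eight 32-sample windows at stride 16).
#' @param variability_level Non-negative scale applied to all phenotype
#'   dispersions; 0 forces every user phenotype identical (default 1).
#' @param rng_seed Integer seed controlling all randomness downstream.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_channels = 4L, sampling_rate = 50,
                       repetition_duration = 3, variability_level = 1,
                       rng_seed = 1L) {
  if (n_channels < 1) stop("n_channels must be >= 1")
  if (sampling_rate <= 0) stop("sampling_rate must be > 0")
  if (repetition_duration <= 0) stop("repetition_duration must be > 0")
  if (variability_level < 0) stop("variability_level must be >= 0")
  structure(
    list(n_channels = as.integer(n_channels),
         sampling_rate = sampling_rate,
         repetition_duration = repetition_duration,
         variability_level = variability_level,
         rng_seed = as.integer(rng_seed)),
    class = "sim_config"
  )
}

#' Construct a gesture template
#'
#' A gesture is described per channel by an activation profile: where in the
#' repetition the channel turns on (`onset_fraction`), for how long
#' (`duration_fraction`), how strongly (`peak_amplitude`, mV) and with what
#' shape (`"trapezoid"` or `"gaussian"` burst). Channels whose peak equals
#' the baseline stay flat.
#'
#' @param gesture_id Gesture label.
#' @param profiles Data frame with one row per channel and columns
#'   `onset_fraction`, `duration_fraction`, `peak_amplitude`, `shape`.
#' @param baseline_amplitude Resting envelope level in mV.
#' @return An object of class `gesture_template`.
#' @export
gesture_template <- function(gesture_id, profiles, baseline_amplitude = 0.3) {
  need <- c("onset_fraction", "duration_fraction", "peak_amplitude", "shape")
  if (!all(need %in% names(profiles))) {
    stop("profiles must have columns ", paste(need, collapse = ", "))
  }
  if (any(profiles$peak_amplitude < 0) || any(profiles$peak_amplitude > 10)) {
    stop("peak amplitudes must lie in [0, 10] mV")
  }
  if (any(profiles$onset_fraction < 0) || any(profiles$onset_fraction >= 1)) {
    stop("onset_fraction must lie in [0, 1)")
  }
  if (any(profiles$duration_fraction <= 0) ||
      any(profiles$onset_fraction + profiles$duration_fraction > 1 + 1e-12)) {
    stop("onset_fraction + duration_fraction must be <= 1")
  }
  if (!any(profiles$peak_amplitude > baseline_amplitude)) {
    stop("at least one channel must rise above baseline")
  }
  if (!all(profiles$shape %in% c("trapezoid", "gaussian"))) {
    stop("shape must be 'trapezoid' or 'gaussian'")
  }
  structure(
    list(gesture_id = as.character(gesture_id),
         profiles = as.data.frame(profiles),
         baseline_amplitude = baseline_amplitude),
    class = "gesture_template"
  )
}

# Render one template as an n_samples x n_channels envelope matrix (mV).
# `onset_shift` (fraction of the repetition) models timing jitter.
render_template <- function(template, n_samples, onset_shift = 0) {
  p <- template$profiles
  C <- nrow(p)
  out <- matrix(template$baseline_amplitude, nrow = n_samples, ncol = C)
  if (n_samples == 0) return(out)
  tt <- (seq_len(n_samples) - 0.5) / n_samples # fraction of repetition
  for (ch in seq_len(C)) {
    peak <- p$peak_amplitude[ch]
    if (peak <= template$baseline_amplitude) next
    on <- min(max(p$onset_fraction[ch] + onset_shift, 0),
              1 - p$duration_fraction[ch])
    dur <- p$duration_fraction[ch]
    rel <- (tt - on) / dur
    if (p$shape[ch] == "trapezoid") {
      # rise/fall occupy 5% of the active phase each (~0.14 s for a held
      # 3 s gesture, the settling time of a 3.6 Hz envelope low-pass)
      ramp <- 0.05
      f <- pmin(pmax(rel / ramp, 0), 1) * pmin(pmax((1 - rel) / ramp, 0), 1)
    } else {
      f <- exp(-0.5 * ((rel - 0.5) / 0.2)^2)
      f[rel < 0 | rel > 1] <- 0
    }
    out[, ch] <- template$baseline_amplitude +
      (peak - template$baseline_amplitude) * f
  }
  out
}

#' Sample a bank of distinct gesture templates
#'
#' Gestures are coded spatially: each template activates a distinct subset
#' of one to three channels (amplitude is not a coding dimension — it is
#' unreliable across users and repetitions), so the bank is pairwise
#' distinct by construction; `min_separation` (mean absolute envelope
#' difference in mV) is verified as a guard. Subsets are chosen greedily so
#' every channel is active in a near-equal share of gestures. A repetition
#' records a *held* gesture: active channels switch on within the first
#' tenth of the recording and stay active until near its end, so every
#' analysis window overlaps genuine activation.
#'
#' @param n_gestures Number of gestures (>= 1).
#' @param n_channels Number of channels (default 4).
#' @param seed Integer seed; fixed seed gives an identical bank.
#' @param min_separation Minimum mean absolute envelope difference between
#'   any two templates, in mV (default 0.8 — comfortably above the 0.3 mV
#'   envelope noise floor, so the bank's gestures are mutually
#'   distinguishable from any single window and a pooled model's larger
#'   class space carries no intrinsic handicap).
#' @return A list of `gesture_template` objects of class `gesture_bank`,
#'   named `G01`, `G02`, ...
#' @export
make_gesture_bank <- function(n_gestures, n_channels = 4L, seed = 1L,
                              min_separation = 0.8) {
  if (n_gestures < 1) stop("n_gestures must be >= 1")
  with_seed(derive_seed(seed, 101L), {
    # candidate activation sets: all channel subsets of size 1..3
    sizes <- seq_len(min(3L, n_channels))
    all_sets <- unlist(lapply(sizes, function(k) {
      utils::combn(n_channels, k, simplify = FALSE)
    }), recursive = FALSE)
    if (n_gestures > length(all_sets)) {
      stop("a ", n_channels, "-channel montage supports at most ",
           length(all_sets), " spatially coded gestures")
    }
    # build the bank from whole orbits of the one-slot montage rotation: a
    # cyclic orbit is internally balanced (every channel active in an
    # equal share of its sets) and closed under rotation, so the gesture
    # code stays inside the bank's vocabulary when a sleeve is worn
    # rotated instead of producing unseen patterns
    shift1 <- function(s) sort((s %% n_channels) + 1)
    key <- function(s) paste(s, collapse = ",")
    remaining <- all_sets
    orbits <- list()
    while (length(remaining) > 0) {
      o <- list(remaining[[1]])
      nxt <- shift1(remaining[[1]])
      while (key(nxt) != key(o[[1]])) {
        o[[length(o) + 1]] <- nxt
        nxt <- shift1(nxt)
      }
      orbits[[length(orbits) + 1]] <- o
      keys <- vapply(o, key, character(1))
      remaining <- Filter(function(s) !(key(s) %in% keys), remaining)
    }
    orbits <- sample(orbits)
    chosen <- list()
    leftover <- list()
    for (o in orbits) { # whole orbits that fit, in seeded order
      if (length(o) <= n_gestures - length(chosen)) {
        chosen <- c(chosen, o)
      } else {
        leftover <- c(leftover, list(o))
      }
    }
    for (o in leftover) { # top up with partial orbits only if unavoidable
      if (length(chosen) >= n_gestures) break
      take <- min(length(o), n_gestures - length(chosen))
      chosen <- c(chosen, sample(o)[seq_len(take)])
    }
    chosen <- chosen[seq_len(n_gestures)]
    bank <- vector("list", n_gestures)
    rendered <- vector("list", n_gestures)
    n_probe <- 100L
    for (g in seq_len(n_gestures)) {
      prof <- data.frame(
        onset_fraction = rep(0, n_channels),
        duration_fraction = rep(0.6, n_channels),
        peak_amplitude = rep(0, n_channels),
        shape = rep("trapezoid", n_channels),
        stringsAsFactors = FALSE
      )
      for (ch in chosen[[g]]) {
        on <- stats::runif(1, 0, 0.1)
        prof$onset_fraction[ch] <- on
        prof$duration_fraction[ch] <- stats::runif(1, 0.85, 1 - on)
        # gestures are coded spatially — by which muscles activate, not
        # how strongly: amplitude is unreliable across users (gain and
        # effort variability), so it is not a coding dimension
        prof$peak_amplitude[ch] <- 6
        # held gestures plateau; bursts (gaussian) would leave the first
        # and last windows of a repetition near baseline and ambiguous
        prof$shape[ch] <- "trapezoid"
      }
      bank[[g]] <- gesture_template(sprintf("G%02d", g), prof,
                                    baseline_amplitude = 0.3)
      rendered[[g]] <- render_template(bank[[g]], n_probe)
      for (h in seq_len(g - 1)) {
        if (mean(abs(rendered[[g]] - rendered[[h]])) < min_separation) {
          stop("bank separation fell below ", min_separation,
               " mV; distinct activation sets should prevent this")
        }
      }
    }
    names(bank) <- vapply(bank, function(t) t$gesture_id, character(1))
    structure(bank, class = "gesture_bank")
  })
}

#' @export
print.gesture_bank <- function(x, ...) {
  cat(sprintf("<gesture_bank> %d gestures: %s\n", length(x),
              paste(names(x), collapse = ", ")))
  invisible(x)
}

#' Construct a user phenotype
#'
#' The per-user physiology of the simulator: per-channel amplitude gains,
#' onset timing jitter (s), a row-stochastic channel-mixing matrix whose
#' off-diagonal mass models electrode shift and crosstalk between adjacent
#' muscles, additive envelope noise (mV) and slow baseline drift (mV).
#'
#' @param user_id User label.
#' @param gains Positive per-channel amplitude multipliers.
#' @param timing_jitter_sd Standard deviation of repetition-to-repetition
#'   onset wobble in seconds (a within-user trait).
#' @param channel_mixing Square row-stochastic matrix (rows sum to 1).
#' @param noise_sd Envelope noise standard deviation in mV (>= 0).
#' @param drift_amplitude Peak slow-drift amplitude in mV (>= 0).
#' @param timing_offset Systematic onset shift in seconds applied to every
#'   repetition of this user (a between-user trait; default 0).
#' @return An object of class `user_phenotype`.
#' @export
user_phenotype <- function(user_id, gains, timing_jitter_sd, channel_mixing,
                           noise_sd, drift_amplitude = 0,
                           timing_offset = 0) {
  channel_mixing <- as.matrix(channel_mixing)
  C <- length(gains)
  if (any(gains <= 0)) stop("gains must be positive")
  if (nrow(channel_mixing) != C || ncol(channel_mixing) != C) {
    stop("channel_mixing must be ", C, " x ", C)
  }
  if (any(channel_mixing < 0)) stop("channel_mixing entries must be >= 0")
  if (any(abs(rowSums(channel_mixing) - 1) > 1e-9)) {
    stop("channel_mixing rows must sum to 1")
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (timing_jitter_sd < 0) stop("timing_jitter_sd must be >= 0")
  structure(
    list(user_id = as.character(user_id), gains = as.numeric(gains),
         timing_jitter_sd = timing_jitter_sd, channel_mixing = channel_mixing,
         noise_sd = noise_sd, drift_amplitude = drift_amplitude,
         timing_offset = timing_offset),
    class = "user_phenotype"
  )
}

#' Sample a cohort of user phenotypes
#'
#' Draws `n_users` phenotypes whose dispersion around the nominal physiology
#' scales with `variability_level`: log-normal channel gains (sd
#' `0.5 * level`), a systematic per-user onset shift (sd `0.12 * level` s),
#' and channel mixing composed of mild crosstalk leakage into the adjacent
#' channel (`0.02-0.1 * level`) and — with probability `0.5 * level`
#' (capped at 0.8) — a montage rotation by one slot, the classic
#' wearable-sleeve placement failure in which every electrode sits over the
#' neighbouring muscle. Repetition-to-repetition onset wobble (0.02 s),
#' the envelope noise floor and the slow-drift amplitude are fixed
#' constants shared by every user: the first is a within-user
#' physiological property and the other two are sensor-electronics
#' properties, so the level dial moves only how much users differ from one
#' another. Because mixing acts after the gains, the combination is a
#' user-systematic distortion that per-channel standardization cannot undo
#' — the mechanism that degrades a shared cross-user model. At level 0
#' every user gets unit gains, the identity mixing matrix and zero
#' systematic shift — i.e. identical phenotypes.
#'
#' @param n_users Number of users (>= 1).
#' @param variability_level Non-negative dispersion scale.
#' @param seed Integer seed.
#' @param n_channels Number of channels (default 4).
#' @param base_noise_sd Common envelope noise floor in mV (default 0.3).
#' @return A list of `user_phenotype` objects named `U01`, `U02`, ...
#' @export
sample_phenotypes <- function(n_users, variability_level, seed = 1L,
                              n_channels = 4L, base_noise_sd = 0.3) {
  if (n_users < 1) stop("n_users must be >= 1")
  if (variability_level < 0) stop("variability_level must be >= 0")
  v <- variability_level
  with_seed(derive_seed(seed, 202L), {
    out <- vector("list", n_users)
    for (u in seq_len(n_users)) {
      gains <- exp(stats::rnorm(n_channels, 0, 0.5 * v))
      # onset timing: a systematic per-user shift (between-user trait that
      # scales with the level) plus a small fixed repetition wobble (a
      # within-user physiological constant, deliberately NOT scaled — the
      # level dial controls only how much users differ from one another)
      offset <- stats::rnorm(1, 0, 0.12 * v)
      jitter <- 0.02
      # channel mixing = montage rotation x local crosstalk blur. A sleeve
      # worn rotated by one slot shifts every electrode onto the adjacent
      # muscle — the classic wearable-sEMG placement failure — and is the
      # user-systematic distortion that makes different users' gestures
      # genuinely confusable in pooled training. On top of it, mild
      # leakage into the neighbouring channel models ordinary crosstalk.
      leak <- pmin(v * stats::runif(n_channels, 0.02, 0.1), 0.3)
      M <- diag(1 - leak, n_channels)
      if (n_channels > 1) {
        for (ch in seq_len(n_channels)) {
          nb <- if (stats::runif(1) < 0.5) ch %% n_channels + 1
                else (ch - 2) %% n_channels + 1
          w <- stats::runif(n_channels) * 0.3
          w[ch] <- 0
          w[nb] <- w[nb] + 0.7
          M[ch, -ch] <- leak[ch] * (w[-ch] / sum(w))
        }
        if (stats::runif(1) < min(0.5 * v, 0.8)) {
          rot <- if (stats::runif(1) < 0.5) 1L else -1L
          P <- diag(n_channels)[((seq_len(n_channels) - 1 + rot) %%
                                   n_channels) + 1, , drop = FALSE]
          M <- P %*% M
        }
      } else {
        M <- matrix(1, 1, 1)
      }
      M <- M / rowSums(M)
      # noise floor and drift are sensor-electronics properties, common to
      # every unit: per-user values would let a classifier identify users
      # by within-window variance instead of muscle activation patterns
      noise <- base_noise_sd
      drift <- if (base_noise_sd > 0) 0.1 else 0
      out[[u]] <- user_phenotype(sprintf("U%02d", u), gains, jitter, M,
                                 noise, drift, timing_offset = offset)
    }
    names(out) <- vapply(out, function(p) p$user_id, character(1))
    out
  })
}

#' Synthesize one gesture repetition for one user
#'
#' Renders the template's activation profiles, scales the repetition by a
#' log-normal effort/contact factor (sd 0.25), applies the phenotype's
#' per-channel gains, onset timing and channel mixing, then adds slow
#' sinusoidal baseline drift and Gaussian envelope noise and clips at zero
#' (an envelope is a rectified magnitude, so samples are non-negative).
#'
#' @param template A `gesture_template`.
#' @param phenotype A `user_phenotype` with matching channel count.
#' @param config A `sim_config`.
#' @param seed Integer seed for this repetition's jitter, drift phase and
#'   noise.
#' @return A labeled `semg_recording` of
#'   `round(repetition_duration * sampling_rate)` samples.
#' @export
synthesize_repetition <- function(template, phenotype, config, seed = 1L) {
  C <- nrow(template$profiles)
  if (length(phenotype$gains) != C || config$n_channels != C) {
    stop("channel counts of template (", C, "), phenotype (",
         length(phenotype$gains), ") and config (", config$n_channels,
         ") must match")
  }
  n <- round(config$repetition_duration * config$sampling_rate)
  with_seed(seed, {
    wobble <- if (phenotype$timing_jitter_sd > 0) {
      stats::rnorm(1, 0, phenotype$timing_jitter_sd)
    } else 0
    shift <- (phenotype$timing_offset + wobble) / config$repetition_duration
    x <- render_template(template, n, onset_shift = shift)
    # repetition-level effort: activation above baseline scales by a
    # log-normal factor — a muscle does not contract with identical
    # strength every time, so absolute envelope amplitude is unreliable
    # and classification must rest on the spatial activation pattern.
    # Skipped for the exact identity phenotype (zero jitter and noise) so
    # a noiseless rendering stays reproducible.
    if (phenotype$timing_jitter_sd > 0 || phenotype$noise_sd > 0) {
      effort <- exp(stats::rnorm(1, 0, 0.2))
      x <- template$baseline_amplitude +
        (x - template$baseline_amplitude) * effort
    }
    x <- sweep(x, 2, phenotype$gains, `*`)
    x <- x %*% t(phenotype$channel_mixing)
    if (phenotype$drift_amplitude > 0 && n > 0) {
      tsec <- (seq_len(n) - 1) / config$sampling_rate
      phase <- stats::runif(1, 0, 2 * pi)
      x <- x + phenotype$drift_amplitude * sin(2 * pi * 0.25 * tsec + phase)
    }
    if (phenotype$noise_sd > 0 && n > 0) {
      x <- x + matrix(stats::rnorm(n * C, 0, phenotype$noise_sd), n, C)
    }
    x <- pmax(x, 0)
    recording(x, config$sampling_rate, phenotype$user_id,
              gesture_id = template$gesture_id)
  })
}

#' Synthesize a labeled multi-user dataset
#'
#' Generates `reps_per_gesture` repetitions of each assigned gesture for each
#' user. Every (user, gesture, repetition) triple draws from its own random
#' substream derived from `config$rng_seed`, so the dataset is a pure
#' function of (bank, phenotypes, config) and identical across reruns.
#'
#' @param bank A `gesture_bank` (non-empty).
#' @param phenotypes List of `user_phenotype` objects.
#' @param reps_per_gesture Repetitions per gesture per user (>= 1).
#' @param config A `sim_config`; `config$rng_seed` seeds all substreams.
#' @param assignments Optional named list mapping each user id to the gesture
#'   ids that user performs; defaults to the full bank for every user.
#' @return An object of class `semg_dataset`: a list with `recordings` (each
#'   a labeled `semg_recording`) and `provenance` (config, phenotypes,
#'   assignments).
#' @export
synthesize_dataset <- function(bank, phenotypes, reps_per_gesture, config,
                               assignments = NULL) {
  if (length(bank) < 1) stop("gesture bank must be non-empty")
  if (reps_per_gesture < 1) stop("reps_per_gesture must be >= 1")
  if (is.null(assignments)) {
    assignments <- stats::setNames(
      rep(list(names(bank)), length(phenotypes)),
      vapply(phenotypes, function(p) p$user_id, character(1))
    )
  }
  recs <- list()
  for (u in seq_along(phenotypes)) {
    ph <- phenotypes[[u]]
    gids <- assignments[[ph$user_id]]
    if (is.null(gids)) stop("no gesture assignment for user ", ph$user_id)
    if (!all(gids %in% names(bank))) {
      stop("assignment for user ", ph$user_id, " includes gestures not in bank")
    }
    for (g in seq_along(gids)) {
      tmpl <- bank[[gids[g]]]
      gi <- match(gids[g], names(bank))
      for (r in seq_len(reps_per_gesture)) {
        s <- derive_seed(config$rng_seed, 7L, u, gi, r)
        recs[[length(recs) + 1]] <- synthesize_repetition(tmpl, ph, config, s)
      }
    }
  }
  structure(
    list(recordings = recs,
         provenance = list(config = config, phenotypes = phenotypes,
                           assignments = assignments)),
    class = "semg_dataset"
  )
}

#' @export
print.semg_dataset <- function(x, ...) {
  users <- unique(vapply(x$recordings, function(r) r$user_id, character(1)))
  gests <- unique(vapply(x$recordings, function(r) r$gesture_id, character(1)))
  cat(sprintf("<semg_dataset> %d recordings, %d users, %d gestures\n",
              length(x$recordings), length(users), length(gests)))
  invisible(x)
}
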