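# EMG-to-keyboard control: hysteresis activation detection on each
# normalized channel, cocontraction recognition, and mapping to
# press/release events with degree-of-freedom (DoF) switching.

#' Game control configuration
#'
#' Parameters of the EMG-to-keyboard mapper. Activation uses hysteresis:
#' a channel switches on when its normalized envelope reaches
#' `on_threshold` and off when it falls below `off_threshold`, which
#' prevents chatter around the activation bar. A contraction is "quick"
#' when it lasts at most `quick_max_ms`; a cocontraction is a quick
#' contraction on both channels with onsets at most
#' `cocontraction_sync_ms` apart, and by default it switches to the next
#' DoF instead of emitting key events.
#'
#' @param on_threshold Activation threshold, fraction of MVC (default
#'   0.15, the separation bar).
#' @param off_threshold Release threshold, fraction of MVC (default
#'   0.10); must be below `on_threshold`.
#' @param quick_max_ms Duration ceiling for a quick contraction, ms.
#' @param cocontraction_sync_ms Maximum onset separation for a
#'   cocontraction, ms.
#' @param n_dofs Number of degrees of freedom cycled by cocontraction.
#' @param keymap List with one character vector of length 2 per DoF:
#'   `c(channel-1 key, channel-2 key)`.
#' @param cocontraction_mode `"switch"` (cocontraction cycles the DoF,
#'   the racing/dexterity games) or `"chord"` (simultaneous quick
#'   contractions simply press both keys, the rhythm game).
#' @return An object of class `control_config`.
#' @export
control_config <- function(on_threshold = 0.15,
                           off_threshold = 0.10,
                           quick_max_ms = 300,
                           cocontraction_sync_ms = 100,
                           n_dofs = 2L,
                           keymap = list(c("LEFT", "RIGHT"), c("UP", "DOWN")),
                           cocontraction_mode = c("switch", "chord")) {
  cocontraction_mode <- match.arg(cocontraction_mode)
  n_dofs <- as.integer(n_dofs)
  stopifnot(
    off_threshold < on_threshold, off_threshold > 0,
    quick_max_ms > 0, cocontraction_sync_ms >= 0, n_dofs >= 1L
  )
  if (length(keymap) != n_dofs)
    stop("keymap must have one (ch1, ch2) key pair per DoF (config error)")
  if (!all(vapply(keymap, function(k) is.character(k) && length(k) == 2L, logical(1))))
    stop("each keymap entry must be a character vector of length 2")
  structure(
    list(
      on_threshold = on_threshold, off_threshold = off_threshold,
      quick_max_ms = quick_max_ms, cocontraction_sync_ms = cocontraction_sync_ms,
      n_dofs = n_dofs, keymap = keymap, cocontraction_mode = cocontraction_mode
    ),
    class = "control_config"
  )
}

#' Detect activation intervals on a normalized channel
#'
#' Hysteresis state machine: an interval opens at the first sample whose
#' value reaches `on_threshold` and closes at the first subsequent
#' sample whose value drops below `off_threshold` (the offset sample
#' itself is inactive). An interval still open at the end of the stream
#' closes one past the last sample. Intervals are classified `quick`
#' when their duration `(offset - onset) / rate` is at most
#' `quick_max_ms`, else `sustained`.
#'
#' @param stream A `normalized_trace`.
#' @param cfg A `control_config`.
#' @return Data frame with columns `channel_id`, `onset`, `offset`
#'   (sample indices, `onset < offset`), `duration_ms`, `kind`
#'   (`"quick"` or `"sustained"`). Zero rows when nothing crosses the
#'   threshold.
#' @export
detect_activations <- function(stream, cfg = control_config()) {
  stopifnot(inherits(stream, "normalized_trace"))
  v <- stream$values
  rate <- stream$sample_rate_hz
  onsets <- integer(0)
  offsets <- integer(0)
  open <- FALSE
  cur <- NA_integer_
  for (i in seq_along(v)) {
    if (!open && v[i] >= cfg$on_threshold) {
      open <- TRUE
      cur <- i
    } else if (open && v[i] < cfg$off_threshold) {
      onsets <- c(onsets, cur)
      offsets <- c(offsets, i)
      open <- FALSE
    }
  }
  if (open) {
    onsets <- c(onsets, cur)
    offsets <- c(offsets, length(v) + 1L)
  }
  dur_ms <- (offsets - onsets) / rate * 1000
  data.frame(
    channel_id = rep(stream$channel_id, length(onsets)),
    onset = onsets, offset = offsets, duration_ms = dur_ms,
    kind = ifelse(dur_ms <= cfg$quick_max_ms, "quick", "sustained")
  )
}

#' Detect cocontractions from per-channel activation intervals
#'
#' A cocontraction is a quick contraction on each channel with onsets at
#' most `cocontraction_sync_ms` apart. Intervals are matched greedily in
#' onset order and each interval participates in at most one
#' cocontraction; matched intervals emit no press/release downstream.
#'
#' @param intervals_ch1,intervals_ch2 Data frames from
#'   [detect_activations()], sorted by onset.
#' @param cfg A `control_config`.
#' @param sample_rate_hz Sampling rate used to convert the sync window
#'   to samples.
#' @return List with `times` (sample index of each cocontraction, the
#'   later of the two onsets) and `used_ch1`, `used_ch2` (row indices of
#'   the participating intervals).
#' @export
detect_cocontractions <- function(intervals_ch1, intervals_ch2,
                                  cfg = control_config(), sample_rate_hz = 100) {
  sync_samples <- cfg$cocontraction_sync_ms / 1000 * sample_rate_hz
  q1 <- which(intervals_ch1$kind == "quick")
  q2 <- which(intervals_ch2$kind == "quick")
  times <- integer(0)
  used1 <- integer(0)
  used2 <- integer(0)
  taken2 <- rep(FALSE, length(q2))
  for (i in q1) {
    gap <- abs(intervals_ch2$onset[q2] - intervals_ch1$onset[i])
    cand <- which(!taken2 & gap <= sync_samples)
    if (length(cand) > 0L) {
      j <- cand[which.min(gap[cand])]
      taken2[j] <- TRUE
      times <- c(times, max(intervals_ch1$onset[i], intervals_ch2$onset[q2[j]]))
      used1 <- c(used1, i)
      used2 <- c(used2, q2[j])
    }
  }
  ord <- order(times)
  list(times = times[ord], used_ch1 = used1[ord], used_ch2 = used2[ord])
}

#' Map a two-channel recording to keyboard control events
#'
#' The full input pipeline of the games: both channels are normalized
#' and passed through the hysteresis detector; cocontractions become
#' `dof_switch` events that cycle the active DoF forward (modulo
#' `n_dofs`); every remaining interval becomes a `press` at its onset
#' and a `release` at its offset of the key that the active DoF assigns
#' to its channel. The key of a press is fixed by the DoF active at
#' onset time, and its release always uses the same key even if the DoF
#' switches while the key is held. In `"chord"` mode no cocontractions
#' are resolved and simultaneous quick contractions press both keys.
#'
#' @param rec A `two_channel_recording`.
#' @param calib A `calibration_profile`.
#' @param cfg A `control_config`.
#' @return Data frame of class `control_events`, sorted by time (sample
#'   index; ties: dof_switch first): columns `time`, `type`
#'   (`press`/`release`/`dof_switch`), `key` (NA for dof_switch),
#'   `channel_id` (NA for dof_switch), `dof_active_after`.
#' @export
map_to_keys <- function(rec, calib, cfg = control_config()) {
  stopifnot(inherits(rec, "two_channel_recording"))
  rate <- rec$ch1$sample_rate_hz
  iv1 <- detect_activations(normalize_trace(rec$ch1, calib), cfg)
  iv2 <- detect_activations(normalize_trace(rec$ch2, calib), cfg)
  if (cfg$cocontraction_mode == "switch") {
    coco <- detect_cocontractions(iv1, iv2, cfg, sample_rate_hz = rate)
  } else {
    coco <- list(times = integer(0), used_ch1 = integer(0), used_ch2 = integer(0))
  }
  keep1 <- setdiff(seq_len(nrow(iv1)), coco$used_ch1)
  keep2 <- setdiff(seq_len(nrow(iv2)), coco$used_ch2)

  # Event queue: kind 0 = dof_switch, 1 = onset, 2 = offset. Onsets and
  # switches are ordered by time with switches first on ties, so a
  # cocontraction recognized at time t applies to presses from t on.
  ev <- rbind(
    if (length(coco$times)) data.frame(time = coco$times, kind = 0L, channel = NA_integer_, row = NA_integer_),
    if (length(keep1)) data.frame(time = iv1$onset[keep1], kind = 1L, channel = 1L, row = keep1),
    if (length(keep2)) data.frame(time = iv2$onset[keep2], kind = 1L, channel = 2L, row = keep2),
    if (length(keep1)) data.frame(time = iv1$offset[keep1], kind = 2L, channel = 1L, row = keep1),
    if (length(keep2)) data.frame(time = iv2$offset[keep2], kind = 2L, channel = 2L, row = keep2)
  )
  out <- data.frame(
    time = integer(0), type = character(0), key = character(0),
    channel_id = integer(0), dof_active_after = integer(0)
  )
  if (!is.null(ev) && nrow(ev) > 0L) {
    ev <- ev[order(ev$time, ev$kind), , drop = FALSE]
    dof <- 0L
    press_key <- list(`1` = NA_character_, `2` = NA_character_)
    rows <- vector("list", nrow(ev))
    for (k in seq_len(nrow(ev))) {
      e <- ev[k, ]
      if (e$kind == 0L) {
        dof <- (dof + 1L) %% cfg$n_dofs
        rows[[k]] <- data.frame(
          time = e$time, type = "dof_switch", key = NA_character_,
          channel_id = NA_integer_, dof_active_after = dof
        )
      } else if (e$kind == 1L) {
        key <- cfg$keymap[[dof + 1L]][e$channel]
        press_key[[as.character(e$channel)]] <- key
        rows[[k]] <- data.frame(
          time = e$time, type = "press", key = key,
          channel_id = e$channel, dof_active_after = dof
        )
      } else {
        key <- press_key[[as.character(e$channel)]]
        rows[[k]] <- data.frame(
          time = e$time, type = "release", key = key,
          channel_id = e$channel, dof_active_after = dof
        )
      }
    }
    out <- do.call(rbind, rows)
  }
  class(out) <- c("control_events", class(out))
  out
}

#' Write control events as JSON lines
#'
#' One JSON object per line with `time_s`, `type`, `key`, `dof` — the
#' replay log a game shim would consume.
#'
#' @param events A `control_events` data frame from [map_to_keys()].
#' @param sample_rate_hz Sampling rate used to convert sample indices to
#'   seconds.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(events, sample_rate_hz, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(events))) {
    rec <- list(
      time_s = (events$time[i] - 1L) / sample_rate_hz,
      type = events$type[i],
      key = events$key[i],
      dof = events$dof_active_after[i]
    )
    if (is.na(rec$key)) rec$key <- NULL
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}
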