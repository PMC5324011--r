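# The four controllability assessments: MVC calibration, precision
# control, electrode separation, and endurance (sine tracking).

#' Assessment protocol configuration
#'
#' All protocol constants of the controllability battery in one place.
#' Defaults reproduce the published protocol: a 1.3 s MVC hold of which
#' the last 1.0 s is evaluated, averaged over 3 trials; 3 precision
#' trials of 10 goal levels each (30 marks per electrode) drawn from
#' 10-90% MVC and held 300 ms; a 15% MVC activation threshold for the
#' separation assessment; a 1/4 Hz reference sine peaking at 60% MVC for
#' endurance, scored in 30 s windows with the best score taken over a
#' period of at least 200 s.
#'
#' @param mvc_hold_s MVC contraction hold, seconds.
#' @param mvc_eval_last_s Final portion of each MVC trial used for the
#'   activation baseline, seconds.
#' @param mvc_n_trials Number of MVC trials averaged per channel.
#' @param n_trials Precision trials per electrode.
#' @param levels_per_trial Goal levels per precision trial.
#' @param level_min,level_max Goal range, fraction of MVC.
#' @param hold_ms Hold duration per goal mark, milliseconds.
#' @param separation_threshold Opposing-electrode activation threshold,
#'   fraction of MVC.
#' @param sine_freq_hz Reference sine frequency, Hz.
#' @param sine_amp_mvc Reference sine peak amplitude, fraction of MVC.
#' @param r2_window_s Endurance scoring window, seconds.
#' @param min_period_s Minimum period spanned by the best-score
#'   aggregate, seconds.
#' @param min_session_s Minimum endurance session duration, seconds.
#' @param schedule_seed Integer seed fixing the goal schedule. The
#'   randomization happens once and the same schedule is reused for
#'   every participant and session.
#' @return An object of class `assessment_config` (a validated list).
#' @export
assessment_config <- function(mvc_hold_s = 1.3,
                              mvc_eval_last_s = 1.0,
                              mvc_n_trials = 3L,
                              n_trials = 3L,
                              levels_per_trial = 10L,
                              level_min = 0.10,
                              level_max = 0.90,
                              hold_ms = 300,
                              separation_threshold = 0.15,
                              sine_freq_hz = 0.25,
                              sine_amp_mvc = 0.60,
                              r2_window_s = 30,
                              min_period_s = 200,
                              min_session_s = 300,
                              schedule_seed = 20150113L) {
  cfg <- list(
    mvc_hold_s = mvc_hold_s, mvc_eval_last_s = mvc_eval_last_s,
    mvc_n_trials = as.integer(mvc_n_trials),
    n_trials = as.integer(n_trials), levels_per_trial = as.integer(levels_per_trial),
    level_min = level_min, level_max = level_max, hold_ms = hold_ms,
    separation_threshold = separation_threshold,
    sine_freq_hz = sine_freq_hz, sine_amp_mvc = sine_amp_mvc,
    r2_window_s = r2_window_s, min_period_s = min_period_s,
    min_session_s = min_session_s, schedule_seed = as.integer(schedule_seed)
  )
  stopifnot(
    cfg$mvc_hold_s >= cfg$mvc_eval_last_s, cfg$mvc_eval_last_s > 0,
    cfg$mvc_n_trials >= 1L, cfg$n_trials >= 1L, cfg$levels_per_trial >= 1L,
    0 < cfg$level_min, cfg$level_min < cfg$level_max, cfg$level_max < 1,
    cfg$hold_ms > 0, 0 < cfg$separation_threshold, cfg$separation_threshold < 1,
    cfg$sine_freq_hz > 0, cfg$sine_amp_mvc > 0,
    cfg$r2_window_s > 0, cfg$min_period_s >= cfg$r2_window_s
  )
  class(cfg) <- "assessment_config"
  cfg
}

last_second_mean <- function(samples, rate, eval_last_s) {
  n_eval <- round(eval_last_s * rate)
  n <- length(samples)
  if (n < n_eval) stop("trial shorter than the evaluation window (input error)")
  mean(samples[(n - n_eval + 1L):n])
}

#' Calibrate MVC from maximal-contraction trials
#'
#' Each trial is a short recording during which the participant holds a
#' maximal contraction of one muscle. Per channel, the MVC is the mean,
#' over that channel's trials, of the mean envelope over the final
#' `mvc_eval_last_s` of the trial (only the last second of the 1.3 s
#' hold enters the activation baseline).
#'
#' Trials may carry a `target_channel` attribute (1 or 2) naming the
#' contracted muscle; then only those trials calibrate that channel.
#' Without the attribute every trial is evaluated for both channels,
#' which is correct when each trial contains a maximal contraction of
#' both muscles in turn or when channels are calibrated from separate
#' trial lists.
#'
#' @param trials List of `two_channel_recording` objects.
#' @param cfg An `assessment_config`.
#' @return A `calibration_profile` with `threshold_fraction` taken from
#'   `cfg$separation_threshold`.
#' @export
calibrate_mvc <- function(trials, cfg = assessment_config()) {
  stopifnot(is.list(trials), length(trials) >= 1L)
  tgt <- vapply(trials, function(tr) {
    a <- attr(tr, "target_channel")
    if (is.null(a)) NA_integer_ else as.integer(a)
  }, integer(1))
  per_channel <- function(ch_id) {
    idx <- if (all(is.na(tgt))) seq_along(trials) else which(tgt == ch_id)
    if (length(idx) != cfg$mvc_n_trials)
      stop(sprintf(
        "channel %d: expected %d MVC trials, got %d (input error)",
        ch_id, cfg$mvc_n_trials, length(idx)
      ))
    vals <- vapply(idx, function(i) {
      tr <- trials[[i]]
      ch <- if (ch_id == 1L) tr$ch1 else tr$ch2
      if (length(ch$samples) < round(cfg$mvc_hold_s * ch$sample_rate_hz))
        stop("MVC trial shorter than the required hold (input error)")
      last_second_mean(ch$samples, ch$sample_rate_hz, cfg$mvc_eval_last_s)
    }, numeric(1))
    mean(vals)
  }
  mvc1 <- per_channel(1L)
  mvc2 <- per_channel(2L)
  if (mvc1 <= 0 || mvc2 <= 0)
    stop("calibrated MVC is not positive; check electrode contact (calibration error)")
  calibration_profile(mvc1, mvc2, threshold_fraction = cfg$separation_threshold)
}

#' Generate the randomized goal schedule for the precision assessment
#'
#' Draws, for each electrode, `n_trials` blocks of `levels_per_trial`
#' goal activation levels uniformly from `[level_min, level_max]`
#' (10-90% MVC by default, 30 marks per electrode). The draw is fixed by
#' `cfg$schedule_seed`: the randomization happens once and the identical
#' schedule is used for every participant and session.
#'
#' @param cfg An `assessment_config`.
#' @return An object of class `goal_schedule`: list with `seed` and
#'   `marks`, a data frame with columns `channel_id`, `trial`, `mark`
#'   (index within channel), `level` (fraction of MVC), `hold_ms`.
#' @export
generate_goal_schedule <- function(cfg = assessment_config()) {
  n_per_ch <- cfg$n_trials * cfg$levels_per_trial
  levels <- with_seed(cfg$schedule_seed, stats::runif(2L * n_per_ch, cfg$level_min, cfg$level_max))
  marks <- data.frame(
    channel_id = rep(c(1L, 2L), each = n_per_ch),
    trial = rep(rep(seq_len(cfg$n_trials), each = cfg$levels_per_trial), times = 2L),
    mark = rep(seq_len(n_per_ch), times = 2L),
    level = levels,
    hold_ms = cfg$hold_ms
  )
  structure(list(seed = cfg$schedule_seed, marks = marks), class = "goal_schedule")
}

#' Classify a goal level into its intensity band
#'
#' The goal range 10-90% MVC is partitioned into three equidistant
#' intensity sections of width 80/3 percent MVC each. Bands are
#' half-open on the left with ties going to the upper band; the top band
#' is closed at 0.90.
#'
#' @param level Goal level(s), fraction of MVC in `[level_min, level_max]`.
#' @param cfg An `assessment_config` (supplies the range).
#' @return Factor with levels `low`, `middle`, `high`.
#' @examples
#' bin_intensity(c(0.10, 0.50, 0.90))  # low middle high
#' @export
bin_intensity <- function(level, cfg = assessment_config()) {
  if (any(level < cfg$level_min - 1e-12 | level > cfg$level_max + 1e-12))
    stop("goal level outside the configured range (input error)")
  width <- (cfg$level_max - cfg$level_min) / 3
  idx <- pmin(3L, 1L + as.integer(floor((level - cfg$level_min) / width + 1e-12)))
  factor(c("low", "middle", "high")[idx], levels = c("low", "middle", "high"))
}

check_mark_windows <- function(windows, schedule, n_samples) {
  need <- c("channel_id", "mark", "start", "end")
  if (!is.data.frame(windows) || !all(need %in% names(windows)))
    stop("mark_windows must be a data frame with columns channel_id, mark, start, end")
  if (nrow(windows) != nrow(schedule$marks))
    stop("one hold window per goal mark is required (input error)")
  if (any(windows$start < 1L) || any(windows$end > n_samples) ||
      any(windows$end < windows$start))
    stop("mark window outside the recording (input error)")
  key_w <- paste(windows$channel_id, windows$mark)
  key_m <- paste(schedule$marks$channel_id, schedule$marks$mark)
  if (!setequal(key_w, key_m) || anyDuplicated(key_w))
    stop("mark_windows must cover every scheduled mark exactly once")
  windows[match(key_m, key_w), , drop = FALSE]
}

#' Score the precision control assessment
#'
#' For every goal mark, the achieved level is the mean normalized
#' activation of the mark's channel over its 300 ms hold window; the
#' outcome is the absolute deviation from the goal, expressed in percent
#' of MVC, tagged with the mark's intensity band.
#'
#' @param rec The assessment `two_channel_recording`.
#' @param schedule The `goal_schedule` used.
#' @param calib The participant's `calibration_profile`.
#' @param mark_windows Data frame with one row per mark: `channel_id`,
#'   `mark`, `start`, `end` (1-based inclusive sample indices of the
#'   hold window). Supplied by the session runner or simulator.
#' @param cfg An `assessment_config`.
#' @return Data frame of class `precision_outcome`: one row per mark
#'   with `channel_id`, `trial`, `mark`, `goal_level`, `achieved_level`,
#'   `deviation_pct`, `intensity_band`.
#' @export
score_precision <- function(rec, schedule, calib, mark_windows,
                            cfg = assessment_config()) {
  stopifnot(inherits(rec, "two_channel_recording"), inherits(schedule, "goal_schedule"))
  w <- check_mark_windows(mark_windows, schedule, recording_length(rec))
  norm <- list(
    `1` = normalize_trace(rec$ch1, calib)$values,
    `2` = normalize_trace(rec$ch2, calib)$values
  )
  achieved <- vapply(seq_len(nrow(w)), function(i) {
    v <- norm[[as.character(w$channel_id[i])]]
    mean(v[w$start[i]:w$end[i]])
  }, numeric(1))
  out <- data.frame(
    channel_id = schedule$marks$channel_id,
    trial = schedule$marks$trial,
    mark = schedule$marks$mark,
    goal_level = schedule$marks$level,
    achieved_level = achieved,
    deviation_pct = abs(achieved - schedule$marks$level) * 100,
    intensity_band = bin_intensity(schedule$marks$level, cfg)
  )
  class(out) <- c("precision_outcome", class(out))
  out
}

#' Score the electrode separation assessment
#'
#' A subsection of the precision assessment: during each mark's hold
#' window, the opposing electrode is checked against the activation
#' threshold (15% of its MVC by default). A mark counts as cocontracted
#' if any opposing-channel sample within the window reaches the
#' threshold. The subject-level outcome is the percentage of marks with
#' opposing activation, overall and per intensity band.
#'
#' @inheritParams score_precision
#' @return List of class `separation_outcome`: `per_mark` (data frame
#'   with `channel_id`, `mark`, `goal_level`, `intensity_band`,
#'   `opposing_active`), `percent_active` (overall, 0-100), and
#'   `percent_by_band` (named vector over low/middle/high).
#' @export
score_separation <- function(rec, schedule, calib, mark_windows,
                             cfg = assessment_config()) {
  stopifnot(inherits(rec, "two_channel_recording"), inherits(schedule, "goal_schedule"))
  w <- check_mark_windows(mark_windows, schedule, recording_length(rec))
  norm <- list(
    `1` = normalize_trace(rec$ch1, calib)$values,
    `2` = normalize_trace(rec$ch2, calib)$values
  )
  thr <- calib$threshold_fraction
  active <- vapply(seq_len(nrow(w)), function(i) {
    opp <- if (w$channel_id[i] == 1L) "2" else "1"
    any(norm[[opp]][w$start[i]:w$end[i]] >= thr)
  }, logical(1))
  per_mark <- data.frame(
    channel_id = schedule$marks$channel_id,
    mark = schedule$marks$mark,
    goal_level = schedule$marks$level,
    intensity_band = bin_intensity(schedule$marks$level, cfg),
    opposing_active = active
  )
  by_band <- tapply(per_mark$opposing_active, per_mark$intensity_band, mean) * 100
  structure(
    list(
      per_mark = per_mark,
      percent_active = 100 * mean(active),
      percent_by_band = by_band
    ),
    class = "separation_outcome"
  )
}

#' Reference sine for the endurance assessment
#'
#' The target the participant retraces with the bipolar composite: a
#' 1/4 Hz sine whose peaks correspond to 60% MVC. Positive half-waves
#' require channel 1 (flexor) activation, negative half-waves channel 2.
#'
#' @param duration_s Duration in seconds (> 0).
#' @param cfg An `assessment_config` (frequency and amplitude).
#' @param sample_rate_hz Sampling rate, Hz.
#' @return A `bipolar_composite` with values
#'   `sine_amp_mvc * sin(2 * pi * sine_freq_hz * t)` at
#'   `t = 0, 1/rate, 2/rate, ...`.
#' @export
reference_sine <- function(duration_s, cfg = assessment_config(), sample_rate_hz = 100) {
  if (!is.finite(duration_s) || duration_s <= 0) stop("duration_s must be > 0")
  n <- round(duration_s * sample_rate_hz)
  t <- (seq_len(n) - 1L) / sample_rate_hz
  structure(
    list(
      values = cfg$sine_amp_mvc * sin(2 * pi * cfg$sine_freq_hz * t),
      sample_rate_hz = sample_rate_hz
    ),
    class = "bipolar_composite"
  )
}

window_r2 <- function(x, s) {
  # Coefficient of determination of the composite against the reference,
  # floored at 0. Not squared Pearson correlation: an antiphase tracker
  # must score 0, not 1.
  ss_ref <- sum((s - mean(s))^2)
  if (ss_ref == 0) return(NA_real_)
  max(0, 1 - sum((x - s)^2) / ss_ref)
}

#' Score the endurance (sine tracking) assessment
#'
#' Compares the recording's bipolar composite to the reference sine in
#' consecutive non-overlapping 30 s windows; each window is scored with
#' the coefficient of determination against the reference, floored at 0.
#' The headline score `best_r2` is the maximum, over all contiguous runs
#' of windows spanning at least `min_period_s` (200 s, i.e. 7 windows of
#' 30 s), of the mean window score.
#'
#' @param rec The endurance `two_channel_recording` (tracking starts at
#'   the first sample, in phase with [reference_sine()]).
#' @param calib The participant's `calibration_profile`.
#' @param cfg An `assessment_config`.
#' @return List of class `endurance_outcome`: `window_r2` (one score per
#'   complete 30 s window, each in \[0, 1\]), `best_r2` (NA with a
#'   warning when the recording is shorter than `min_period_s`),
#'   `duration_s`.
#' @export
score_endurance <- function(rec, calib, cfg = assessment_config()) {
  stopifnot(inherits(rec, "two_channel_recording"))
  rate <- rec$ch1$sample_rate_hz
  x <- composite_bipolar(rec, calib)$values
  n <- length(x)
  wlen <- round(cfg$r2_window_s * rate)
  if (n < wlen) stop("recording shorter than one scoring window (input error)")
  s <- reference_sine(n / rate, cfg, sample_rate_hz = rate)$values
  n_win <- n %/% wlen
  r2 <- vapply(seq_len(n_win), function(k) {
    idx <- ((k - 1L) * wlen + 1L):(k * wlen)
    window_r2(x[idx], s[idx])
  }, numeric(1))
  need <- ceiling(cfg$min_period_s / cfg$r2_window_s)
  duration_s <- n / rate
  if (n_win < need) {
    warning("recording shorter than the minimum scoring period; best_r2 not computed")
    best <- NA_real_
  } else {
    best <- -Inf
    for (len in need:n_win) {
      for (start in seq_len(n_win - len + 1L)) {
        best <- max(best, mean(r2[start:(start + len - 1L)]))
      }
    }
  }
  structure(
    list(window_r2 = r2, best_r2 = best, duration_s = duration_s),
    class = "endurance_outcome"
  )
}

#' Serialize a goal schedule to JSON
#' @param schedule A `goal_schedule`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_schedule_json <- function(schedule, path) {
  jsonlite::write_json(
    list(seed = schedule$seed, marks = schedule$marks),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read a goal schedule from JSON
#' @param path Path written by [write_schedule_json()].
#' @return A `goal_schedule`.
#' @export
read_schedule_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  marks <- as.data.frame(obj$marks)
  marks$channel_id <- as.integer(marks$channel_id)
  marks$trial <- as.integer(marks$trial)
  marks$mark <- as.integer(marks$mark)
  structure(list(seed = as.integer(obj$seed), marks = marks), class = "goal_schedule")
}
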