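# Synthetic two-channel envelope generator: simulated participants with
# noise, bias, response lag, opposing-channel leak (cocontraction
# tendency), fatigue, and between-session learning. Stands in for human
# subjects so the whole battery is testable without hardware.

#' Synthetic participant model
#'
#' Parameters of one simulated participant. All activation-scale
#' parameters are fractions of MVC; the volt scale enters only through
#' `mvc_true`, mirroring the arbitrary amplification of real hardware.
#'
#' @param mvc_true Length-2 numeric, true per-channel MVC in volts.
#' @param idle_offset Resting envelope level (common noise floor),
#'   fraction of MVC. Default 0.02: small but nonzero idle activation.
#' @param noise_sd SD of Gaussian envelope noise, fraction of MVC.
#' @param bias Systematic over/undershoot of goal levels, fraction of
#'   MVC (signed).
#' @param lag_s Response lag in seconds: first-order time constant for
#'   step-like tasks (MVC ramps, goal approach), pure reaction delay for
#'   sine tracking.
#' @param leak Fraction of intended activation appearing on the opposing
#'   channel (cocontraction tendency), in `[0, 1)`.
#' @param fatigue_rate Per-second multiplicative growth of `noise_sd`
#'   during the endurance task (sd at time t is
#'   `noise_sd * (1 + fatigue_rate)^t`).
#' @param learning_factor Multiplier applied to `noise_sd`, `|bias|`,
#'   and `leak` per session step; values below 1 model skill
#'   improvement across sessions.
#' @param seed Integer seed making this subject's recordings
#'   reproducible.
#' @return An object of class `subject_model`.
#' @export
subject_model <- function(mvc_true = c(2.0, 1.8),
                          idle_offset = 0.02,
                          noise_sd = 0.04,
                          bias = 0.02,
                          lag_s = 0.2,
                          leak = 0.15,
                          fatigue_rate = 0.001,
                          learning_factor = 0.75,
                          seed = 1L) {
  stopifnot(
    length(mvc_true) == 2L, all(mvc_true > 0),
    idle_offset >= 0, noise_sd >= 0, leak >= 0, leak < 1,
    lag_s >= 0, fatigue_rate >= 0, learning_factor > 0
  )
  structure(
    list(
      mvc_true = as.numeric(mvc_true), idle_offset = idle_offset,
      noise_sd = noise_sd, bias = bias, lag_s = lag_s, leak = leak,
      fatigue_rate = fatigue_rate, learning_factor = learning_factor,
      seed = as.integer(seed)
    ),
    class = "subject_model"
  )
}

#' Apply between-session learning to a subject
#'
#' Scales `noise_sd`, `|bias|` (sign preserved), and `leak` by
#' `learning_factor^n_steps`. The true MVC is left unchanged.
#'
#' @param subject A `subject_model`.
#' @param n_steps Number of session steps since the first measurement.
#' @return The adjusted `subject_model`.
#' @export
apply_learning <- function(subject, n_steps) {
  f <- subject$learning_factor^n_steps
  subject$noise_sd <- subject$noise_sd * f
  subject$bias <- subject$bias * f
  subject$leak <- subject$leak * f
  subject
}

# First-order low-pass of an intended activation profile; alpha from the
# time constant. lag_s = 0 is the identity. init is the response state
# just before the first sample (sessions start from rest).
first_order_response <- function(x, lag_s, rate, init = x[1]) {
  if (lag_s <= 0) return(x)
  alpha <- 1 - exp(-1 / (rate * lag_s))
  as.numeric(stats::filter(alpha * x, 1 - alpha, method = "recursive", init = init))
}

clip0 <- function(x) pmax(x, 0)

#' Simulate MVC calibration trials
#'
#' Generates `mvc_n_trials` recordings per channel. In each trial the
#' target muscle ramps toward its true MVC with first-order lag during a
#' 0.7 s lead-in and holds for `mvc_hold_s`; the opposing channel sits
#' at `idle_offset + leak * activation`. Gaussian envelope noise (SD
#' `noise_sd`) is added to both channels and negative excursions are
#' clipped at zero. Each recording carries a `target_channel` attribute
#' so [calibrate_mvc()] groups trials correctly.
#'
#' @param subject A `subject_model`.
#' @param cfg An `assessment_config`.
#' @param sample_rate_hz Sampling rate, Hz.
#' @param lead_in_s Ramp-up time before the scored hold, seconds.
#' @param seed Seed for this simulation (default: the subject's).
#' @return List of `2 * mvc_n_trials` `two_channel_recording` objects.
#' @export
simulate_mvc_trials <- function(subject, cfg = assessment_config(),
                                sample_rate_hz = 100, lead_in_s = 0.7,
                                seed = subject$seed) {
  with_seed(seed, {
    n <- round((lead_in_s + cfg$mvc_hold_s) * sample_rate_hz)
    trials <- vector("list", 2L * cfg$mvc_n_trials)
    k <- 0L
    for (ch in 1:2) {
      for (tr in seq_len(cfg$mvc_n_trials)) {
        intended <- rep(1.0, n)
        resp <- first_order_response(intended, subject$lag_s, sample_rate_hz,
                                     init = subject$idle_offset)
        active <- clip0(resp + stats::rnorm(n, 0, subject$noise_sd))
        opposing <- clip0(subject$idle_offset + subject$leak * resp +
                            stats::rnorm(n, 0, subject$noise_sd))
        opp <- if (ch == 1L) 2L else 1L
        volts <- list()
        volts[[ch]] <- active * subject$mvc_true[ch]
        volts[[opp]] <- opposing * subject$mvc_true[opp]
        rec <- two_channel_recording(
          envelope_trace(volts[[1]], 1L, sample_rate_hz),
          envelope_trace(volts[[2]], 2L, sample_rate_hz)
        )
        attr(rec, "target_channel") <- ch
        k <- k + 1L
        trials[[k]] <- rec
      }
    }
    trials
  })
}

#' Simulate a precision/separation assessment session
#'
#' Plays the goal schedule: for each mark, the target channel rises from
#' idle toward `goal + bias` with first-order lag over a 1 s approach,
#' holds for `hold_ms` (the returned hold window), and relaxes back to
#' idle during the next inter-mark gap. The opposing channel carries
#' `idle_offset + leak * activation`; Gaussian envelope noise is added
#' to both channels and clipped at zero. Channel 1's marks are performed
#' first, then channel 2's, separated by idle gaps of
#' `inter_mark_gap_s`.
#'
#' @param subject A `subject_model`.
#' @param schedule A `goal_schedule`.
#' @param cfg An `assessment_config`.
#' @param sample_rate_hz Sampling rate, Hz.
#' @param inter_mark_gap_s Idle gap between marks, seconds.
#' @param approach_s Rise time allotted before each hold, seconds.
#' @param seed Seed for this simulation (default: the subject's).
#' @return List with `recording` (a `two_channel_recording`) and
#'   `mark_windows` (data frame `channel_id`, `mark`, `start`, `end`),
#'   ready for [score_precision()] and [score_separation()].
#' @export
simulate_goal_session <- function(subject, schedule, cfg = assessment_config(),
                                  sample_rate_hz = 100, inter_mark_gap_s = 2,
                                  approach_s = 1, seed = subject$seed) {
  with_seed(seed, {
    marks <- schedule$marks
    gap_n <- round(inter_mark_gap_s * sample_rate_hz)
    appr_n <- round(approach_s * sample_rate_hz)
    hold_n <- round(cfg$hold_ms / 1000 * sample_rate_hz)
    per_mark_n <- gap_n + appr_n + hold_n
    n <- per_mark_n * nrow(marks) + gap_n
    intended <- list(rep(subject$idle_offset, n), rep(subject$idle_offset, n))
    win <- data.frame(
      channel_id = marks$channel_id, mark = marks$mark,
      start = NA_integer_, end = NA_integer_
    )
    pos <- 0L
    for (i in seq_len(nrow(marks))) {
      ch <- marks$channel_id[i]
      target <- clip0(marks$level[i] + subject$bias)
      a0 <- pos + gap_n + 1L
      h0 <- pos + gap_n + appr_n + 1L
      h1 <- pos + per_mark_n
      intended[[ch]][a0:h1] <- target
      win$start[i] <- h0
      win$end[i] <- h1
      pos <- pos + per_mark_n
    }
    resp <- lapply(intended, first_order_response, lag_s = subject$lag_s,
                   rate = sample_rate_hz)
    own1 <- resp[[1]] - subject$idle_offset
    own2 <- resp[[2]] - subject$idle_offset
    fr1 <- clip0(resp[[1]] + subject$leak * own2 + stats::rnorm(n, 0, subject$noise_sd))
    fr2 <- clip0(resp[[2]] + subject$leak * own1 + stats::rnorm(n, 0, subject$noise_sd))
    rec <- two_channel_recording(
      envelope_trace(fr1 * subject$mvc_true[1], 1L, sample_rate_hz),
      envelope_trace(fr2 * subject$mvc_true[2], 2L, sample_rate_hz)
    )
    list(recording = rec, mark_windows = win)
  })
}

#' Simulate an endurance (sine tracking) session
#'
#' The subject retraces the reference sine with the bipolar composite.
#' The intended composite is the reference delayed by `lag_s` (reaction
#' delay), plus `bias`, plus Gaussian noise whose SD grows by
#' `fatigue_rate` per second (multiplicatively). Positive intent drives
#' channel 1, negative intent channel 2; each channel additionally
#' carries the idle offset and the leak of the opposing drive.
#'
#' @param subject A `subject_model`.
#' @param duration_s Session duration, seconds (> 0).
#' @param cfg An `assessment_config`.
#' @param sample_rate_hz Sampling rate, Hz.
#' @param seed Seed for this simulation (default: the subject's).
#' @return A `two_channel_recording` starting in phase with
#'   [reference_sine()].
#' @export
simulate_tracking <- function(subject, duration_s, cfg = assessment_config(),
                              sample_rate_hz = 100, seed = subject$seed) {
  stopifnot(duration_s > 0)
  with_seed(seed, {
    n <- round(duration_s * sample_rate_hz)
    s <- reference_sine(duration_s, cfg, sample_rate_hz)$values
    delay <- round(subject$lag_s * sample_rate_hz)
    lagged <- if (delay > 0) c(rep(0, min(delay, n)), s[seq_len(max(n - delay, 0))]) else s
    t <- (seq_len(n) - 1L) / sample_rate_hz
    sd_t <- subject$noise_sd * (1 + subject$fatigue_rate)^t
    u <- lagged + subject$bias + stats::rnorm(n, 0, 1) * sd_t
    drive1 <- clip0(u)
    drive2 <- clip0(-u)
    fr1 <- clip0(drive1 + subject$idle_offset + subject$leak * drive2)
    fr2 <- clip0(drive2 + subject$idle_offset + subject$leak * drive1)
    two_channel_recording(
      envelope_trace(fr1 * subject$mvc_true[1], 1L, sample_rate_hz),
      envelope_trace(fr2 * subject$mvc_true[2], 2L, sample_rate_hz)
    )
  })
}

#' Cohort specification for a simulated study
#'
#' Describes the simulated cohort: number of participants, the ordered
#' measurement sessions, and uniform sampling ranges for every
#' [subject_model()] parameter. Defaults emulate a small group of naive
#' able-bodied participants measured before gaming, directly after, and
#' at a follow-up.
#'
#' @param n_subjects Number of participants (default 11).
#' @param sessions Ordered session labels.
#' @param ranges Named list of length-2 numeric ranges for
#'   `mvc_true` (volts, shared by both channels), `idle_offset`,
#'   `noise_sd`, `bias`, `lag_s`, `leak`, `fatigue_rate`,
#'   `learning_factor`. Entries may be overridden individually.
#' @param master_seed Integer seed fixing the whole cohort.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 11L,
                        sessions = c("Pregaming", "Postgaming", "FollowUp"),
                        ranges = list(),
                        master_seed = 1L) {
  defaults <- list(
    mvc_true = c(1.5, 3.0),
    idle_offset = c(0.01, 0.03),
    noise_sd = c(0.02, 0.06),
    bias = c(-0.05, 0.05),
    lag_s = c(0.10, 0.30),
    leak = c(0.05, 0.30),
    fatigue_rate = c(0.0005, 0.002),
    learning_factor = c(0.60, 0.85)
  )
  unknown <- setdiff(names(ranges), names(defaults))
  if (length(unknown)) stop("unknown range name(s): ", paste(unknown, collapse = ", "))
  defaults[names(ranges)] <- ranges
  stopifnot(n_subjects >= 1L, !anyDuplicated(sessions))
  structure(
    list(
      n_subjects = as.integer(n_subjects), sessions = sessions,
      ranges = defaults, master_seed = as.integer(master_seed)
    ),
    class = "cohort_spec"
  )
}

draw_subject <- function(ranges, seed) {
  r <- function(nm) stats::runif(1, ranges[[nm]][1], ranges[[nm]][2])
  subject_model(
    mvc_true = c(r("mvc_true"), r("mvc_true")),
    idle_offset = r("idle_offset"),
    noise_sd = r("noise_sd"),
    bias = r("bias"),
    lag_s = r("lag_s"),
    leak = r("leak"),
    fatigue_rate = r("fatigue_rate"),
    learning_factor = r("learning_factor"),
    seed = seed
  )
}

#' Simulate a full cohort through the assessment battery
#'
#' Draws `n_subjects` participants from the cohort ranges, applies the
#' learning factor across sessions, runs the requested assessments for
#' every subject and session, and returns the long outcome table the
#' statistical pipeline consumes. Fully deterministic given
#' `master_seed`.
#'
#' @param spec A `cohort_spec`.
#' @param cfg An `assessment_config`.
#' @param assessments Character subset of
#'   `c("precision", "separation", "endurance")` to run.
#' @param endurance_duration_s Duration of each simulated endurance
#'   session, seconds (default `cfg$min_session_s`).
#' @return An `assessment_report`: data frame with columns `subject`,
#'   `session` (ordered factor), `outcome` (`precision_deviation`,
#'   `separation_active`, `endurance_r2`), `band` (`low`/`middle`/
#'   `high`, or `all` for endurance), `value` (mean deviation in %MVC,
#'   percent opposing activation, or best r²). The drawn subjects are
#'   attached as attribute `subjects`.
#' @export
simulate_cohort <- function(spec = cohort_spec(), cfg = assessment_config(),
                            assessments = c("precision", "separation", "endurance"),
                            endurance_duration_s = cfg$min_session_s) {
  assessments <- match.arg(assessments, several.ok = TRUE)
  schedule <- generate_goal_schedule(cfg)
  n_sess <- length(spec$sessions)
  setup <- with_seed(spec$master_seed, {
    seeds <- matrix(
      sample.int(.Machine$integer.max - 1L, spec$n_subjects * n_sess * 3L),
      nrow = spec$n_subjects
    )
    subjects <- lapply(seq_len(spec$n_subjects), function(i)
      draw_subject(spec$ranges, seed = seeds[i, 1]))
    list(seeds = seeds, subjects = subjects)
  })
  rows <- list()
  add_row <- function(subj, sess, outcome, band, value) {
    rows[[length(rows) + 1L]] <<- data.frame(
      subject = subj, session = sess, outcome = outcome,
      band = band, value = as.numeric(value)
    )
  }
  for (i in seq_len(spec$n_subjects)) {
    for (k in seq_len(n_sess)) {
      subj <- apply_learning(setup$subjects[[i]], k - 1L)
      sess <- spec$sessions[k]
      seed_base <- setup$seeds[i, (k - 1L) * 3L + 1L]
      trials <- simulate_mvc_trials(subj, cfg, seed = seed_base)
      calib <- calibrate_mvc(trials, cfg)
      if (any(c("precision", "separation") %in% assessments)) {
        gs <- simulate_goal_session(subj, schedule, cfg,
                                    seed = setup$seeds[i, (k - 1L) * 3L + 2L])
        if ("precision" %in% assessments) {
          prec <- score_precision(gs$recording, schedule, calib, gs$mark_windows, cfg)
          dev_by_band <- tapply(prec$deviation_pct, prec$intensity_band, mean)
          for (b in names(dev_by_band))
            add_row(i, sess, "precision_deviation", b, dev_by_band[[b]])
        }
        if ("separation" %in% assessments) {
          sep <- score_separation(gs$recording, schedule, calib, gs$mark_windows, cfg)
          for (b in names(sep$percent_by_band))
            add_row(i, sess, "separation_active", b, sep$percent_by_band[[b]])
        }
      }
      if ("endurance" %in% assessments) {
        rec <- simulate_tracking(subj, endurance_duration_s, cfg,
                                 seed = setup$seeds[i, (k - 1L) * 3L + 3L])
        end <- score_endurance(rec, calib, cfg)
        add_row(i, sess, "endurance_r2", "all", end$best_r2)
      }
    }
  }
  report <- do.call(rbind, rows)
  report$session <- factor(report$session, levels = spec$sessions, ordered = TRUE)
  attr(report, "subjects") <- setup$subjects
  class(report) <- c("assessment_report", class(report))
  report
}
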