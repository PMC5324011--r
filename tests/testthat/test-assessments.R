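cfg <- assessment_config()

test_that("MVC calibration averages the last-second mean over trials", {
  const_trial <- function(level_v) {
    rec <- make_recording(rep(level_v, 130), rep(level_v, 130))
    rec
  }
  # constant trials recover the constant
  trials <- lapply(c(2, 2, 2), const_trial)
  cal <- calibrate_mvc(trials, cfg)
  expect_equal(cal$mvc_ch1, 2.0)
  expect_equal(cal$mvc_ch2, 2.0)
  expect_equal(cal$threshold_fraction, 0.15)

  # last-second means 1, 2, 3 V -> MVC 2 V
  trials <- lapply(c(1, 2, 3), const_trial)
  expect_equal(calibrate_mvc(trials, cfg)$mvc_ch1, 2.0)

  # linear ramp 0 -> 1.3 V over 1.3 s at 100 Hz: mean of the final 100
  # samples computed directly as the oracle
  ramp <- (1:130) / 100
  expect_equal(
    calibrate_mvc(lapply(1:3, function(i) make_recording(ramp, ramp)), cfg)$mvc_ch1,
    mean(ramp[31:130])
  )
  expect_equal(mean(ramp[31:130]), 0.805)

  # trial shorter than the hold is rejected
  short <- make_recording(rep(1, 50), rep(1, 50))
  expect_error(calibrate_mvc(list(short, short, short), cfg), "shorter")
})

test_that("MVC trials tagged with a target channel calibrate per channel", {
  mk <- function(active_ch, level) {
    v <- list(rep(0.02, 130), rep(0.02, 130))
    v[[active_ch]] <- rep(level, 130)
    rec <- make_recording(v[[1]], v[[2]])
    attr(rec, "target_channel") <- active_ch
    rec
  }
  trials <- c(lapply(c(1.9, 2.0, 2.1), mk, active_ch = 1),
              lapply(c(1.4, 1.5, 1.6), mk, active_ch = 2))
  cal <- calibrate_mvc(trials, cfg)
  expect_equal(cal$mvc_ch1, 2.0)
  expect_equal(cal$mvc_ch2, 1.5)
  expect_error(calibrate_mvc(trials[1:4], cfg), "expected 3 MVC trials")
})

test_that("goal schedule has 30 in-range marks per electrode and is seed-deterministic", {
  sch <- generate_goal_schedule(cfg)
  for (ch in 1:2) {
    m <- sch$marks[sch$marks$channel_id == ch, ]
    expect_equal(nrow(m), 30L)
    expect_equal(sort(unique(m$trial)), 1:3)
    expect_true(all(m$level >= 0.10 & m$level <= 0.90))
    expect_true(all(m$hold_ms == 300))
  }
  expect_identical(generate_goal_schedule(cfg), sch)
  other <- generate_goal_schedule(assessment_config(schedule_seed = 999L))
  expect_false(identical(other$marks$level, sch$marks$level))
})

test_that("goal schedule JSON round-trips", {
  sch <- generate_goal_schedule(cfg)
  path <- withr::local_tempfile(fileext = ".json")
  write_schedule_json(sch, path)
  back <- read_schedule_json(path)
  expect_equal(back$seed, sch$seed)
  expect_equal(back$marks, sch$marks)
})

test_that("intensity bands partition 10-90% MVC into three equal sections", {
  expect_equal(as.character(bin_intensity(c(0.10, 0.50, 0.90))), c("low", "middle", "high"))
  # boundary between low and middle sits at 0.10 + 0.8/3 = 0.3667
  expect_equal(as.character(bin_intensity(c(0.36, 0.37))), c("low", "middle"))
  # ties at a boundary go to the upper band
  expect_equal(as.character(bin_intensity(0.10 + 0.8 / 3)), "middle")
  expect_equal(as.character(bin_intensity(0.10 + 1.6 / 3)), "high")
  expect_error(bin_intensity(0.05), "outside")

  # every in-range level maps to exactly one band; widths are equal
  lv <- seq(0.10, 0.90, by = 0.005)
  b <- bin_intensity(lv)
  expect_true(all(!is.na(b)))
  counts <- table(cut(lv, breaks = c(0.10, 0.10 + 0.8 / 3, 0.10 + 1.6 / 3, 0.90),
                      include.lowest = TRUE, right = FALSE))
  expect_equal(as.integer(table(b)), as.integer(counts), tolerance = 1)
})

test_that("precision scoring is the window-mean deviation in percent MVC", {
  cfg2 <- assessment_config(n_trials = 1L, levels_per_trial = 2L)
  sch <- generate_goal_schedule(cfg2)
  sch$marks$level <- rep(c(0.50, 0.30), 2)
  n <- 200
  hold <- 30  # 300 ms at 100 Hz
  win <- data.frame(
    channel_id = sch$marks$channel_id, mark = sch$marks$mark,
    start = c(1, 61, 1, 61), end = c(hold, 60 + hold, hold, 60 + hold)
  )
  v1 <- numeric(n)
  v1[1:hold] <- 0.45                      # goal 0.50 -> 5 %MVC deviation
  v1[61:(60 + hold)] <- rep(c(0.2, 0.4), hold / 2)  # mean 0.30 -> 0 deviation
  v2 <- numeric(n)
  v2[1:hold] <- 0.50                      # exact -> 0
  v2[61:(60 + hold)] <- 0.35              # goal 0.30 -> 5 %MVC
  out <- score_precision(make_recording(v1, v2), sch, unit_calib(), win, cfg2)
  expect_equal(out$deviation_pct, c(5, 0, 0, 5))
  expect_equal(out$achieved_level, c(0.45, 0.30, 0.50, 0.35))
  expect_equal(as.character(out$intensity_band), c("middle", "low", "middle", "low"))

  # deviation is zero iff the window mean equals the goal, and strictly
  # monotone in |window mean - goal|
  for (delta in c(0.01, 0.05, 0.2)) {
    v1[1:hold] <- 0.50 + delta
    out2 <- score_precision(make_recording(v1, v2), sch, unit_calib(), win, cfg2)
    expect_equal(out2$deviation_pct[1], delta * 100)
  }
  expect_error(
    score_precision(make_recording(v1, v2), sch, unit_calib(),
                    transform(win, end = end + 1000), cfg2),
    "outside"
  )
})

test_that("separation flags any-sample threshold crossing of the opposing electrode", {
  cfg2 <- assessment_config(n_trials = 1L, levels_per_trial = 3L)
  sch <- generate_goal_schedule(cfg2)
  win <- data.frame(
    channel_id = sch$marks$channel_id, mark = sch$marks$mark,
    start = rep(c(1, 41, 81), 2), end = rep(c(30, 70, 110), 2)
  )
  v1 <- numeric(200)
  v2 <- numeric(200)
  v1[1:110] <- 0.5
  v2[50] <- 0.16   # single opposing sample over 15% inside ch1 mark 2
  out <- score_separation(make_recording(v1, v2), sch, unit_calib(), win, cfg2)
  ch1_active <- out$per_mark$opposing_active[out$per_mark$channel_id == 1]
  expect_equal(ch1_active, c(FALSE, TRUE, FALSE))
  # ch2 marks see ch1 at 0.5 >= 0.15 throughout
  expect_true(all(out$per_mark$opposing_active[out$per_mark$channel_id == 2]))
  expect_equal(out$percent_active, 100 * 4 / 6)

  # all-quiet opposing channel scores 0%
  quiet <- score_separation(make_recording(v1, numeric(200)), sch, unit_calib(), win, cfg2)
  expect_equal(quiet$percent_active, 50)  # ch2 marks still see ch1 active
  none <- score_separation(make_recording(numeric(200), numeric(200)), sch,
                           unit_calib(), win, cfg2)
  expect_equal(none$percent_active, 0)

  # 3 of 30 marks active on each electrode -> 10% overall
  cfg30 <- assessment_config()
  sch30 <- generate_goal_schedule(cfg30)
  w30 <- data.frame(
    channel_id = sch30$marks$channel_id, mark = sch30$marks$mark,
    start = seq(1, by = 40, length.out = 60), end = seq(30, by = 40, length.out = 60)
  )
  v1b <- numeric(40 * 60 + 10)
  v2b <- numeric(40 * 60 + 10)
  v2b[w30$start[1:3]] <- 0.2    # opposing spikes in 3 ch1 windows
  v1b[w30$start[31:33]] <- 0.2  # opposing spikes in 3 ch2 windows
  outb <- score_separation(make_recording(v1b, v2b), sch30,
                           unit_calib(), w30, cfg30)
  expect_equal(sum(outb$per_mark$opposing_active), 6L)
  expect_equal(outb$percent_active, 10.0)
})

test_that("adding opposing activation never decreases percent_active", {
  set.seed(3)
  cfg2 <- assessment_config(n_trials = 1L, levels_per_trial = 5L)
  sch <- generate_goal_schedule(cfg2)
  win <- data.frame(
    channel_id = sch$marks$channel_id, mark = sch$marks$mark,
    start = rep(seq(1, by = 40, length.out = 5), 2),
    end = rep(seq(30, by = 40, length.out = 5), 2)
  )
  v1 <- runif(300, 0, 0.3)
  v2 <- runif(300, 0, 0.2)
  base <- score_separation(make_recording(v1, v2), sch, unit_calib(), win, cfg2)
  more <- score_separation(make_recording(v1, pmin(v2 + 0.1, 1)), sch,
                           unit_calib(), win, cfg2)
  expect_gte(more$percent_active, base$percent_active)
  expect_true(base$percent_active >= 0 && base$percent_active <= 100)
})

test_that("reference sine has quarter-hertz period and 60% MVC peaks", {
  s <- reference_sine(16, cfg, sample_rate_hz = 100)
  expect_equal(s$values[1], 0)
  expect_equal(s$values[101], 0.6)   # t = 1.0 s, first positive peak
  expect_equal(max(s$values), 0.6, tolerance = 1e-6)
  # period from consecutive upward zero crossings
  up <- which(diff(sign(s$values + 1e-15)) > 0)
  expect_equal(diff(up) / 100, rep(4.0, length(up) - 1), tolerance = 0.01)
})

test_that("endurance scoring: perfect tracking gives 1 in every window", {
  for (dur in c(210, 330)) {
    for (rate in c(100, 50)) {
      s <- reference_sine(dur, cfg, rate)$values
      mvc <- c(2.3, 1.7)
      rec <- make_recording(pmax(s, 0) * mvc[1], pmax(-s, 0) * mvc[2], rate)
      out <- score_endurance(rec, calibration_profile(mvc[1], mvc[2]), cfg)
      expect_equal(out$window_r2, rep(1, floor(dur / 30)))
      expect_equal(out$best_r2, 1)
    }
  }
})

test_that("endurance scoring floors antiphase tracking at zero", {
  s <- reference_sine(240, cfg, 100)$values
  x <- -s  # shifted by half a period
  rec <- make_recording(pmax(x, 0), pmax(-x, 0), 100)
  out <- score_endurance(rec, unit_calib(), cfg)
  expect_equal(out$window_r2, rep(0, 8))
  expect_equal(out$best_r2, 0)
})

test_that("endurance score decreases with tracking noise", {
  score_at <- function(sigma, seed) {
    set.seed(seed)
    s <- reference_sine(210, cfg, 100)$values
    x <- s + rnorm(length(s), 0, sigma)
    out <- score_endurance(make_recording(pmax(x, 0), pmax(-x, 0), 100), unit_calib(), cfg)
    out$best_r2
  }
  means <- sapply(c(0.05, 0.15, 0.30), function(sg)
    mean(sapply(1:5, function(sd_) score_at(sg, 400 + sd_))))
  expect_true(all(diff(means) < 0))
  expect_true(all(means > 0 & means < 1))
})

test_that("endurance scoring enforces duration preconditions", {
  s <- reference_sine(100, cfg, 100)$values
  rec <- make_recording(pmax(s, 0), pmax(-s, 0), 100)
  expect_warning(out <- score_endurance(rec, unit_calib(), cfg), "minimum scoring period")
  expect_equal(length(out$window_r2), 3L)
  expect_true(is.na(out$best_r2))
  tiny <- make_recording(rep(0.1, 50), rep(0.1, 50), 100)
  expect_error(score_endurance(tiny, unit_calib(), cfg), "shorter than one scoring window")
})
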