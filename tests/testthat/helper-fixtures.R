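# Shared fixtures and independent brute-force oracles. Oracles use
# plain loops and first principles only, never the package's internals.

make_recording <- function(v1, v2, rate = 100) {
  two_channel_recording(
    envelope_trace(v1, channel_id = 1L, sample_rate_hz = rate),
    envelope_trace(v2, channel_id = 2L, sample_rate_hz = rate)
  )
}

unit_calib <- function(threshold = 0.15) calibration_profile(1, 1, threshold)

# Brute-force separation scorer: explicit loops over marks and samples.
bf_separation <- function(rec, schedule, calib, windows, threshold) {
  marks <- schedule$marks
  active <- logical(nrow(marks))
  for (i in seq_len(nrow(marks))) {
    w <- windows[windows$channel_id == marks$channel_id[i] &
                   windows$mark == marks$mark[i], ]
    opp_trace <- if (marks$channel_id[i] == 1L) rec$ch2 else rec$ch1
    opp_mvc <- if (marks$channel_id[i] == 1L) calib$mvc_ch2 else calib$mvc_ch1
    hit <- FALSE
    for (t in w$start:w$end) {
      if (opp_trace$samples[t] / opp_mvc >= threshold) hit <- TRUE
    }
    active[i] <- hit
  }
  list(active = active, percent = 100 * sum(active) / length(active))
}

# Brute-force endurance scorer: explicit per-window loops for the
# coefficient of determination and explicit enumeration of window runs.
bf_endurance <- function(rec, calib, cfg) {
  rate <- rec$ch1$sample_rate_hz
  n <- length(rec$ch1$samples)
  x <- numeric(n)
  s <- numeric(n)
  for (t in seq_len(n)) {
    x[t] <- rec$ch1$samples[t] / calib$mvc_ch1 - rec$ch2$samples[t] / calib$mvc_ch2
    s[t] <- cfg$sine_amp_mvc * sin(2 * pi * cfg$sine_freq_hz * (t - 1) / rate)
  }
  wlen <- round(cfg$r2_window_s * rate)
  n_win <- floor(n / wlen)
  r2 <- numeric(n_win)
  for (k in seq_len(n_win)) {
    idx <- ((k - 1) * wlen + 1):(k * wlen)
    sbar <- 0
    for (t in idx) sbar <- sbar + s[t] / wlen
    num <- 0
    den <- 0
    for (t in idx) {
      num <- num + (x[t] - s[t])^2
      den <- den + (s[t] - sbar)^2
    }
    r2[k] <- max(0, 1 - num / den)
  }
  need <- ceiling(cfg$min_period_s / cfg$r2_window_s)
  best <- -Inf
  if (n_win >= need) {
    for (len in need:n_win) {
      for (start in 1:(n_win - len + 1)) {
        m <- 0
        for (k in start:(start + len - 1)) m <- m + r2[k] / len
        if (m > best) best <- m
      }
    }
  } else {
    best <- NA_real_
  }
  list(window_r2 = r2, best_r2 = best)
}

# Exact two-sided signed-rank p-value by full enumeration of the 2^n
# sign assignments (requires no zero differences and no tied |d|).
enum_signrank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  stopifnot(n <= 14, !anyDuplicated(abs(d)))
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.numeric(signs %*% r)
  mu <- n * (n + 1) / 4
  p <- if (v_obs > mu) 2 * mean(v_all >= v_obs) else 2 * mean(v_all <= v_obs)
  list(statistic = v_obs, p_value = min(1, p))
}

# Deterministic scripted two-channel stream builder: `spans` is a data
# frame with channel (1/2), start, end (samples), level (fraction MVC).
scripted_recording <- function(n, spans, rate = 100) {
  v1 <- numeric(n)
  v2 <- numeric(n)
  for (i in seq_len(nrow(spans))) {
    idx <- spans$start[i]:spans$end[i]
    if (spans$channel[i] == 1) v1[idx] <- spans$level[i] else v2[idx] <- spans$level[i]
  }
  make_recording(v1, v2, rate)
}
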