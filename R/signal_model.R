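# Core time-series containers for two-channel RMS envelope recordings,
# MVC normalization, and the signed bipolar composite used by the
# endurance tracking task.

#' Single-channel RMS envelope trace
#'
#' The basic container for one electrode channel's non-negative RMS
#' envelope stream, sampled uniformly (the hardware delivers the envelope
#' at 100 Hz after embedded filtering and rectification; raw EMG never
#' enters this package).
#'
#' @param samples Numeric vector of envelope amplitudes in volts
#'   (arbitrary hardware scale). All values must be finite and >= 0.
#' @param channel_id Integer channel label: `1` (flexor) or `2` (extensor).
#' @param sample_rate_hz Sampling rate in Hz (default 100).
#' @return An object of class `envelope_trace`: a list with elements
#'   `samples`, `channel_id`, `sample_rate_hz`.
#' @examples
#' tr <- envelope_trace(c(0, 0.2, 0.4), channel_id = 1)
#' length(tr$samples)
#' @export
envelope_trace <- function(samples, channel_id, sample_rate_hz = 100) {
  samples <- as.numeric(samples)
  if (length(samples) < 1L) stop("envelope trace must contain at least one sample")
  if (any(!is.finite(samples))) stop("envelope samples must be finite")
  if (any(samples < 0)) stop("envelope samples must be non-negative")
  channel_id <- as.integer(channel_id)
  if (!channel_id %in% c(1L, 2L)) stop("channel_id must be 1 (flexor) or 2 (extensor)")
  if (!is.finite(sample_rate_hz) || sample_rate_hz <= 0) stop("sample_rate_hz must be > 0")
  structure(
    list(samples = samples, channel_id = channel_id, sample_rate_hz = sample_rate_hz),
    class = "envelope_trace"
  )
}

#' Aligned two-channel recording
#'
#' Bundles the flexor (channel 1) and extensor (channel 2) envelope
#' traces. Both traces must have identical lengths and sample rates;
#' time is implicit in the sample index.
#'
#' @param ch1 `envelope_trace` with `channel_id == 1`.
#' @param ch2 `envelope_trace` with `channel_id == 2`.
#' @return An object of class `two_channel_recording`.
#' @export
two_channel_recording <- function(ch1, ch2) {
  stopifnot(inherits(ch1, "envelope_trace"), inherits(ch2, "envelope_trace"))
  if (ch1$channel_id != 1L || ch2$channel_id != 2L)
    stop("recording requires channel ids 1 (ch1) and 2 (ch2)")
  if (length(ch1$samples) != length(ch2$samples))
    stop("channel traces must have equal lengths")
  if (ch1$sample_rate_hz != ch2$sample_rate_hz)
    stop("channel traces must share one sample rate")
  structure(list(ch1 = ch1, ch2 = ch2), class = "two_channel_recording")
}

#' @export
print.two_channel_recording <- function(x, ...) {
  n <- length(x$ch1$samples)
  cat(sprintf(
    "two_channel_recording: %d samples @ %g Hz (%.2f s)\n",
    n, x$ch1$sample_rate_hz, n / x$ch1$sample_rate_hz
  ))
  invisible(x)
}

#' Recording length in samples
#' @param rec A `two_channel_recording`.
#' @return Integer number of samples per channel.
#' @export
recording_length <- function(rec) length(rec$ch1$samples)

#' Recording duration in seconds
#' @param rec A `two_channel_recording`.
#' @return Duration in seconds.
#' @export
recording_duration <- function(rec) length(rec$ch1$samples) / rec$ch1$sample_rate_hz

#' Per-channel MVC calibration profile
#'
#' Holds the maximum voluntary contraction (MVC) amplitude for each
#' channel, in volts, plus the activation-threshold fraction used by the
#' separation assessment and the game controller. All scores in the
#' battery are expressed relative to these MVC values, which makes the
#' arbitrary hardware volt scale irrelevant downstream.
#'
#' @param mvc_ch1,mvc_ch2 MVC amplitude per channel, volts, strictly > 0.
#' @param threshold_fraction Activation threshold as a fraction of MVC,
#'   in (0, 1). Default 0.15: an electrode is "active" at 15% MVC.
#' @return An object of class `calibration_profile`.
#' @export
calibration_profile <- function(mvc_ch1, mvc_ch2, threshold_fraction = 0.15) {
  if (!is.finite(mvc_ch1) || mvc_ch1 <= 0 || !is.finite(mvc_ch2) || mvc_ch2 <= 0)
    stop("MVC values must be strictly positive (calibration error)")
  if (!is.finite(threshold_fraction) || threshold_fraction <= 0 || threshold_fraction >= 1)
    stop("threshold_fraction must lie in (0, 1)")
  structure(
    list(mvc_ch1 = mvc_ch1, mvc_ch2 = mvc_ch2, threshold_fraction = threshold_fraction),
    class = "calibration_profile"
  )
}

mvc_for_channel <- function(calib, channel_id) {
  if (channel_id == 1L) calib$mvc_ch1 else calib$mvc_ch2
}

#' Normalize an envelope trace to fractions of MVC
#'
#' Divides every sample by the channel's MVC from the calibration
#' profile. Values above 1 are allowed, not clipped: the MVC measurement
#' is provisional and later contractions may exceed it.
#'
#' @param trace An `envelope_trace`.
#' @param calib A `calibration_profile`.
#' @return An object of class `normalized_trace`: list with `values`
#'   (dimensionless fractions of MVC), `channel_id`, `sample_rate_hz`.
#' @examples
#' tr <- envelope_trace(c(0.3, 0.6, 0.9), channel_id = 1)
#' calib <- calibration_profile(1.2, 1.0)
#' normalize_trace(tr, calib)$values  # 0.25 0.50 0.75
#' @export
normalize_trace <- function(trace, calib) {
  stopifnot(inherits(trace, "envelope_trace"), inherits(calib, "calibration_profile"))
  mvc <- mvc_for_channel(calib, trace$channel_id)
  if (!is.finite(mvc) || mvc <= 0) stop("MVC for this channel is not positive (calibration error)")
  structure(
    list(
      values = trace$samples / mvc,
      channel_id = trace$channel_id,
      sample_rate_hz = trace$sample_rate_hz
    ),
    class = "normalized_trace"
  )
}

#' Signed bipolar composite of a two-channel recording
#'
#' The endurance tracking signal: at every instant, normalized channel 1
#' minus normalized channel 2. A positive value corresponds to activation
#' of the first (flexor) electrode, a negative value to the second
#' (extensor); simultaneous equal activation cancels to zero.
#'
#' @param rec A `two_channel_recording`.
#' @param calib A `calibration_profile`.
#' @return An object of class `bipolar_composite`: list with `values`
#'   (signed fractions of MVC) and `sample_rate_hz`.
#' @export
composite_bipolar <- function(rec, calib) {
  stopifnot(inherits(rec, "two_channel_recording"))
  n1 <- normalize_trace(rec$ch1, calib)
  n2 <- normalize_trace(rec$ch2, calib)
  structure(
    list(values = n1$values - n2$values, sample_rate_hz = rec$ch1$sample_rate_hz),
    class = "bipolar_composite"
  )
}

#' Read a two-channel recording from CSV
#'
#' Expects a header `time_s,ch1,ch2` with a strictly increasing, uniform
#' time column; uniformity is validated to a relative tolerance of 1e-6
#' of the sampling interval. The sample rate is inferred from the time
#' column.
#'
#' @param path Path to the CSV file.
#' @param swap_channels If `TRUE`, relabel the columns so that the file's
#'   `ch2` becomes channel 1 (flexor). Electrode placement convention is
#'   otherwise fixed: column `ch1` = flexor = positive composite pole.
#' @return A `two_channel_recording`.
#' @export
read_recording_csv <- function(path, swap_channels = FALSE) {
  df <- utils::read.csv(path, colClasses = "numeric")
  need <- c("time_s", "ch1", "ch2")
  if (!all(need %in% names(df)))
    stop("recording CSV must have columns time_s, ch1, ch2")
  t <- df$time_s
  if (length(t) < 2L) stop("recording must contain at least two samples")
  dt <- diff(t)
  if (any(dt <= 0)) stop("time_s must be strictly increasing")
  dt0 <- (t[length(t)] - t[1]) / (length(t) - 1L)
  if (any(abs(dt - dt0) > 1e-6 * dt0))
    stop("time_s is not uniform to relative tolerance 1e-6")
  rate <- 1 / dt0
  a <- if (swap_channels) df$ch2 else df$ch1
  b <- if (swap_channels) df$ch1 else df$ch2
  two_channel_recording(
    envelope_trace(a, channel_id = 1L, sample_rate_hz = rate),
    envelope_trace(b, channel_id = 2L, sample_rate_hz = rate)
  )
}

#' Write a two-channel recording to CSV
#'
#' Inverse of [read_recording_csv()]: writes `time_s,ch1,ch2` with time
#' starting at 0.
#'
#' @param rec A `two_channel_recording`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_recording_csv <- function(rec, path) {
  n <- recording_length(rec)
  df <- data.frame(
    time_s = (seq_len(n) - 1L) / rec$ch1$sample_rate_hz,
    ch1 = rec$ch1$samples,
    ch2 = rec$ch2$samples
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Evaluate expr under a fixed RNG seed without disturbing the caller's
# RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
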