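#' Channel-quality screening thresholds
#'
#' Screening flags a channel as artifact when (1) the relative power of its
#' low-frequency components (0-12 Hz) exceeds `max_lowfreq_rel_power`, or
#' (2) the relative power of the power-line components (line frequency and
#' its first four harmonics) exceeds `max_powerline_rel_power`, or (3) its
#' mean power (squared RMS) falls outside `rms_power_bounds`. The default
#' thresholds are calibration knobs, not physiological constants.
#'
#' @param max_lowfreq_rel_power Fraction of total power allowed in 0-12 Hz.
#' @param max_powerline_rel_power Fraction allowed at line harmonics.
#' @param rms_power_bounds Two-element vector `(low, high)` in mV^2.
#' @export
quality_thresholds <- function(max_lowfreq_rel_power = 0.25,
                               max_powerline_rel_power = 0.50,
                               rms_power_bounds = c(1e-4, 25)) {
  stopifnot(max_lowfreq_rel_power > 0, max_powerline_rel_power > 0,
            length(rms_power_bounds) == 2L, all(rms_power_bounds > 0),
            rms_power_bounds[1] < rms_power_bounds[2])
  structure(list(max_lowfreq_rel_power = max_lowfreq_rel_power,
                 max_powerline_rel_power = max_powerline_rel_power,
                 rms_power_bounds = rms_power_bounds),
            class = "quality_thresholds")
}

# One-sided periodogram power of x in [f_lo, f_hi] (inclusive), and total.
periodogram_band_power <- function(x, fs, f_lo, f_hi) {
  n <- length(x)
  p <- Mod(stats::fft(x))^2 / n
  freq <- (seq_len(n) - 1L) * fs / n
  half <- freq <= fs / 2
  sum(p[half & freq >= f_lo & freq <= f_hi])
}

#' Screen channels for measurement artifacts
#'
#' Computes, per channel over the whole recording, the three screening
#' features (low-frequency relative power, power-line relative power, mean
#' power) from the periodogram and flags channels violating any threshold.
#'
#' @param recording An [emg_recording()], raw (unfiltered) signals.
#' @param thresholds A [quality_thresholds()].
#' @param line_freq Power-line fundamental in Hz (default 50).
#' @return An object of class `channel_quality` with elements `flags`
#'   (`"good"`/`"artifact"` per channel), `features` (channels x 3 matrix:
#'   `lowfreq_rel`, `line_rel`, `power_mv2`) and `bad` (integer indices).
#' @export
screen_channels <- function(recording, thresholds = quality_thresholds(),
                            line_freq = 50) {
  stopifnot(inherits(recording, "emg_recording"))
  x <- recording$signals; fs <- recording$fs
  if (ncol(x) < fs)
    stop("screen_channels: need at least 1 s of signal", call. = FALSE)
  n_ch <- nrow(x)
  feats <- matrix(NA_real_, n_ch, 3,
                  dimnames = list(NULL, c("lowfreq_rel", "line_rel", "power_mv2")))
  harmonics <- line_freq * 1:5      # fundamental + first four harmonics
  harmonics <- harmonics[harmonics < fs / 2]
  for (ch in seq_len(n_ch)) {
    s <- x[ch, ]
    total <- periodogram_band_power(s, fs, 0, fs / 2)
    if (total <= 0) {
      feats[ch, ] <- c(0, 0, 0)
      next
    }
    lf <- periodogram_band_power(s, fs, 0, 12)
    lp <- sum(vapply(harmonics, function(h)
      periodogram_band_power(s, fs, h - 1, h + 1), numeric(1)))
    feats[ch, ] <- c(lf / total, lp / total, mean(s^2))
  }
  bad <- feats[, 1] > thresholds$max_lowfreq_rel_power |
         feats[, 2] > thresholds$max_powerline_rel_power |
         feats[, 3] < thresholds$rms_power_bounds[1] |
         feats[, 3] > thresholds$rms_power_bounds[2]
  structure(list(flags = ifelse(bad, "artifact", "good"),
                 features = feats, bad = which(bad)),
            class = "channel_quality")
}

#' @export
print.channel_quality <- function(x, ...) {
  cat(sprintf("Channel quality: %d/%d channels flagged as artifact\n",
              length(x$bad), length(x$flags)))
  if (length(x$bad)) cat("  bad channels:", paste(x$bad, collapse = ", "), "\n")
  invisible(x)
}

#' Zero-phase Butterworth band-pass filter
#'
#' Designs a Butterworth band-pass of the stated order and applies it
#' forward-backward (zero phase) to every channel. The design order refers
#' to the one-pass filter; the forward-backward application squares its
#' magnitude response.
#'
#' @param signals Channels x samples numeric matrix (a plain vector is
#'   treated as one channel).
#' @param fs Sampling rate in Hz.
#' @param band Two-element vector `(low, high)` in Hz, default `c(15, 350)`.
#' @param order Design order of the Butterworth filter, default 4.
#' @return Filtered matrix (or vector) of the same shape.
#' @export
bandpass <- function(signals, fs, band = c(15, 350), order = 4) {
  vec <- !is.matrix(signals)
  if (vec) signals <- matrix(signals, nrow = 1L)
  if (band[1] <= 0 || band[2] <= band[1] || band[2] >= fs / 2)
    stop("bandpass: band must satisfy 0 < low < high < fs/2", call. = FALSE)
  bf <- signal::butter(order, band * 2 / fs, type = "pass")
  out <- t(apply(signals, 1L, function(s) signal::filtfilt(bf, s)))
  if (vec) out[1L, ] else out
}

#' Adaptive power-line interference canceller
#'
#' Suppresses the power-line fundamental and its first `n_harmonics - 1`
#' harmonics with an adaptive transversal filter: for each harmonic a
#' sine/cosine reference pair is synthesized, weights are adapted by the
#' least-mean-squares (LMS) rule, and the estimated interference is
#' subtracted sample by sample. Like the zero-phase band-pass, the
#' canceller works offline and runs in two passes: an adaptation pass over
#' the whole signal with a decaying (stochastic-approximation) step, then a
#' processing pass from the converged weights with the small tracking step,
#' so it behaves as a set of very narrow notches at the harmonics and
#' leaves EMG energy outside the notches essentially intact.
#'
#' @param signals Channels x samples matrix (or vector, one channel).
#' @param fs Sampling rate, Hz.
#' @param line_freq Fundamental, Hz (default 50).
#' @param n_harmonics Number of harmonics cancelled including the
#'   fundamental (default 6).
#' @param step Tracking LMS adaptation rate mu of the processing pass
#'   (default 1e-5 with unit-amplitude references).
#' @param step_initial Initial adaptation rate of the adaptation pass
#'   (default 4e-3); it decays as `1 / (1 + t / anneal_s)`.
#' @param anneal_s Time scale of the adaptation-pass step decay, s.
#' @return Filtered matrix (or vector) of the same shape.
#' @export
suppress_powerline <- function(signals, fs, line_freq = 50, n_harmonics = 6,
                               step = 1e-5, step_initial = 4e-3,
                               anneal_s = 0.5) {
  vec <- !is.matrix(signals)
  if (vec) signals <- matrix(signals, nrow = 1L)
  if (step <= 0) stop("suppress_powerline: step must be positive", call. = FALSE)
  if (n_harmonics * line_freq >= fs / 2)
    stop("suppress_powerline: harmonics exceed the Nyquist frequency", call. = FALSE)
  out <- matrix(NA_real_, nrow(signals), ncol(signals))
  for (ch in seq_len(nrow(signals))) {
    res <- lms_cancel(signals[ch, ], fs, line_freq, as.integer(n_harmonics),
                      step, max(step, step_initial), anneal_s)
    if (!all(is.finite(res)) ||
        (stats::sd(signals[ch, ]) > 0 &&
         mean(res^2) > 100 * mean(signals[ch, ]^2)))
      stop("suppress_powerline: adaptation diverged (reduce step)", call. = FALSE)
    out[ch, ] <- res
  }
  if (vec) out[1L, ] else out
}

#' Standard preprocessing chain
#'
#' Screens channels on the raw signals, band-pass filters 15-350 Hz
#' (zero-phase Butterworth, 4th order) and cancels the first six power-line
#' harmonics adaptively, in that order. Screening intentionally uses the
#' line fundamental plus four harmonics while suppression uses six.
#'
#' @param recording An [emg_recording()].
#' @param thresholds [quality_thresholds()] for screening.
#' @param band,order Band-pass parameters.
#' @param line_freq,n_harmonics,step Line-canceller parameters.
#' @param suppress_line Set `FALSE` to skip the adaptive canceller (useful
#'   when the simulator emitted no interference).
#' @return List with `recording` (filtered) and `quality`
#'   (the [screen_channels()] report of the raw input).
#' @export
preprocess_recording <- function(recording, thresholds = quality_thresholds(),
                                 band = c(15, 350), order = 4,
                                 line_freq = 50, n_harmonics = 6,
                                 step = 1e-5, suppress_line = TRUE) {
  quality <- screen_channels(recording, thresholds, line_freq = line_freq)
  sig <- bandpass(recording$signals, recording$fs, band = band, order = order)
  if (suppress_line)
    sig <- suppress_powerline(sig, recording$fs, line_freq = line_freq,
                              n_harmonics = n_harmonics, step = step)
  recording$signals <- sig
  list(recording = recording, quality = quality)
}
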