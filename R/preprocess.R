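#' Preprocessing configuration
#'
#' Standard surface-EMG conditioning: a Butterworth band-pass over the sEMG
#' band, a narrow notch at the mains frequency, and baseline removal by mean
#' subtraction. Defaults follow community practice at 1000 Hz sampling:
#' 4th-order 20--450 Hz band-pass, Q = 30 notch at 50 Hz, applied zero-phase
#' (forward-backward) so feature timing is preserved.
#'
#' @param band_low,band_high band-pass edges in Hz.
#' @param filter_order Butterworth order of the band-pass.
#' @param notch_freq mains frequency to suppress, Hz.
#' @param notch_q quality factor of the notch (centre / -3 dB width).
#' @param zero_phase if `TRUE`, filters run forward-backward (no group delay).
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(band_low = 20, band_high = 450,
                              filter_order = 4, notch_freq = 50,
                              notch_q = 30, zero_phase = TRUE) {
  cfg <- list(band_low = band_low, band_high = band_high,
              filter_order = as.integer(filter_order),
              notch_freq = notch_freq, notch_q = notch_q,
              zero_phase = isTRUE(zero_phase))
  class(cfg) <- "preprocess_config"
  cfg
}

check_band <- function(f, fs, what) {
  if (!is.finite(f) || f <= 0 || f >= fs / 2)
    stop("invalid config: ", what, " must lie in (0, fs/2)", call. = FALSE)
}

## Reflective padding (3x filter order at each end) before forward-backward
## application suppresses startup transients on short trials.
apply_zero_phase <- function(filt, x, pad) {
  n <- length(x)
  pad <- min(pad, n - 1L)
  xp <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  y <- signal::filtfilt(filt, xp)
  y[(pad + 1):(pad + n)]
}

#' Band-pass filter an EMG sample vector
#'
#' @param samples numeric vector.
#' @param fs sampling rate, Hz.
#' @param config a [preprocess_config()].
#' @return Filtered vector of the same length.
#' @export
bandpass_filter <- function(samples, fs, config = preprocess_config()) {
  check_band(config$band_low, fs, "band_low")
  check_band(config$band_high, fs, "band_high")
  if (config$band_low >= config$band_high)
    stop("invalid config: band_low must be below band_high", call. = FALSE)
  stopifnot(length(samples) > 3 * config$filter_order, all(is.finite(samples)))
  bf <- signal::butter(config$filter_order,
                       c(config$band_low, config$band_high) / (fs / 2),
                       type = "pass")
  if (config$zero_phase) {
    apply_zero_phase(bf, samples, 3L * config$filter_order * 4L)
  } else {
    as.numeric(signal::filter(bf, samples))
  }
}

## RBJ audio-cookbook biquad notch: unit gain away from notch_freq,
## zero at the notch, -3 dB width = notch_freq / Q.
design_notch <- function(notch_freq, q, fs) {
  w0 <- 2 * pi * notch_freq / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  signal::Arma(b = b / a[1], a = a / a[1])
}

#' Notch filter for powerline interference
#'
#' Second-order IIR notch (biquad) at `notch_freq`; with the default Q = 30
#' the -3 dB width at 50 Hz is under 2 Hz, so neighbouring EMG content is
#' essentially untouched while the mains tone is suppressed by tens of dB.
#'
#' @inheritParams bandpass_filter
#' @return Filtered vector of the same length.
#' @export
notch_filter <- function(samples, fs, config = preprocess_config()) {
  check_band(config$notch_freq, fs, "notch_freq")
  stopifnot(length(samples) > 12, all(is.finite(samples)))
  nf <- design_notch(config$notch_freq, config$notch_q, fs)
  if (config$zero_phase) {
    apply_zero_phase(nf, samples, 3L * 2L * 4L * 10L)
  } else {
    as.numeric(signal::filter(nf, samples))
  }
}

#' Remove baseline by mean subtraction
#'
#' @param samples non-empty numeric vector.
#' @return The vector centred to exactly zero mean.
#' @export
remove_baseline <- function(samples) {
  if (length(samples) == 0) stop("empty input", call. = FALSE)
  samples - mean(samples)
}

#' Preprocess a full EMG record
#'
#' Applies band-pass, then notch, then mean subtraction (last, so the output
#' mean is exactly zero). Keys and label windows are carried through.
#'
#' @param record an `emg_record`.
#' @param config a [preprocess_config()].
#' @return The record with conditioned `samples`.
#' @export
preprocess_record <- function(record, config = preprocess_config()) {
  x <- bandpass_filter(record$samples, record$fs, config)
  x <- notch_filter(x, record$fs, config)
  record$samples <- remove_baseline(x)
  record
}
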