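#' Windowing and feature-extraction configuration
#'
#' Defaults reflect common surface-EMG fatigue practice at 1000 Hz sampling:
#' 1 s analysis windows at 50% overlap; Welch spectra from 256-sample Hann
#' segments (frequency resolution ~3.9 Hz); short-time spectra from
#' 256-sample frames hopped by 64 samples; sample entropy with m = 2 and
#' r = 0.2 x window SD; rescaled-range Hurst over >= 8 log-spaced scales
#' from 16 samples to a quarter of the window.
#'
#' @param window_len analysis window length in samples.
#' @param overlap fraction of overlap between consecutive windows, in [0, 1).
#' @param welch_segment,welch_overlap Welch segment length and overlap, samples.
#' @param stft_window,stft_hop short-time frame length and hop, samples.
#' @param sampen_m sample-entropy template length.
#' @param sampen_r_factor sample-entropy tolerance as a fraction of window SD.
#' @param hurst_min_scale,hurst_n_scales smallest block size and number of
#'   log-spaced block sizes for rescaled-range analysis.
#' @return An object of class `window_config`.
#' @export
window_config <- function(window_len = 1000, overlap = 0.5,
                          welch_segment = 256, welch_overlap = 128,
                          stft_window = 256, stft_hop = 64,
                          sampen_m = 2, sampen_r_factor = 0.2,
                          hurst_min_scale = 16, hurst_n_scales = 8) {
  stopifnot(overlap >= 0, overlap < 1, welch_segment <= window_len,
            sampen_m >= 1)
  structure(list(window_len = as.integer(window_len), overlap = overlap,
                 welch_segment = as.integer(welch_segment),
                 welch_overlap = as.integer(welch_overlap),
                 stft_window = as.integer(stft_window),
                 stft_hop = as.integer(stft_hop),
                 sampen_m = as.integer(sampen_m),
                 sampen_r_factor = sampen_r_factor,
                 hurst_min_scale = as.integer(hurst_min_scale),
                 hurst_n_scales = as.integer(hurst_n_scales)),
            class = "window_config")
}

#' Time-domain features of one window
#'
#' Mean absolute value, population variance and root-mean-square:
#' `MAV = mean(|x|)`, `VAR = mean((x - mean(x))^2)`, `RMS = sqrt(mean(x^2))`.
#'
#' @param window non-empty numeric vector.
#' @return Named numeric vector `c(MAV, VAR, RMS)`.
#' @export
time_domain_features <- function(window) {
  if (length(window) == 0) stop("empty window", call. = FALSE)
  c(MAV = mean(abs(window)),
    VAR = mean((window - mean(window))^2),
    RMS = sqrt(mean(window^2)))
}

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))

## One-sided Hann periodogram of a single segment, density-normalised so that
## sum(P) * df equals the segment's (detrended) power.
segment_psd <- function(x, fs, win) {
  n <- length(x)
  x <- x - mean(x)
  X <- stats::fft(x * win)
  half <- n %/% 2 + 1L
  P <- Mod(X[seq_len(half)])^2 / (fs * sum(win^2))
  if (n %% 2 == 0) {
    P[2:(half - 1L)] <- 2 * P[2:(half - 1L)]
  } else {
    P[2:half] <- 2 * P[2:half]
  }
  P
}

#' Welch power spectral density of a window
#'
#' Hann-tapered, mean-detrended segments averaged with the configured overlap.
#' The density is normalised so `sum(powers) * df` approximates the window's
#' variance (one-sided convention).
#'
#' @param window numeric vector, at least one Welch segment long.
#' @param fs sampling rate, Hz.
#' @param config a [window_config()].
#' @return A list of class `emg_spectrum` with `freqs` (Hz) and `powers`.
#' @export
power_spectrum <- function(window, fs, config = window_config()) {
  seg <- config$welch_segment
  if (length(window) < seg) stop("window shorter than Welch segment", call. = FALSE)
  hop <- seg - config$welch_overlap
  win <- hann_window(seg)
  starts <- seq(1L, length(window) - seg + 1L, by = hop)
  P <- Reduce(`+`, lapply(starts, function(s)
    segment_psd(window[s:(s + seg - 1L)], fs, win))) / length(starts)
  structure(list(freqs = (seq_len(seg %/% 2 + 1L) - 1) * fs / seg, powers = P),
            class = "emg_spectrum")
}

#' Mean frequency of a spectrum
#'
#' Power-weighted average frequency, `sum(f * P) / sum(P)`.
#'
#' @param spectrum an `emg_spectrum` (or list with `freqs`, `powers`).
#' @return Mean frequency in Hz.
#' @export
mean_frequency <- function(spectrum) {
  tot <- sum(spectrum$powers)
  if (tot <= 0) stop("zero total power", call. = FALSE)
  sum(spectrum$freqs * spectrum$powers) / tot
}

#' Median frequency of a spectrum
#'
#' The frequency below which half of the total spectral power lies, with
#' linear interpolation between bins.
#'
#' @inheritParams mean_frequency
#' @return Median frequency in Hz.
#' @export
median_frequency <- function(spectrum) {
  P <- spectrum$powers
  f <- spectrum$freqs
  tot <- sum(P)
  if (tot <= 0) stop("zero total power", call. = FALSE)
  cum <- cumsum(P)
  half <- tot / 2
  i <- which(cum >= half)[1]
  if (i == 1L) return(f[1])
  prev <- cum[i - 1L]
  f[i - 1L] + (f[i] - f[i - 1L]) * (half - prev) / (cum[i] - prev)
}

#' Instantaneous (framewise) mean and median frequency
#'
#' Short-time Hann spectra are computed at `stft_hop` spacing and the mean and
#' median frequency are evaluated per frame, tracing how the spectral content
#' evolves inside the window. Summaries are the time-mean and the
#' least-squares slope of each series.
#'
#' Naming note: following the terminology of the fatigue-EMG literature this
#' package targets, **IMDF** denotes the *instantaneous mean frequency* series
#' and **IMNF** the *instantaneous median frequency* series (the reverse of
#' the abbreviations' usual expansion elsewhere).
#'
#' @param window numeric vector long enough for at least 4 frames.
#' @param fs sampling rate, Hz.
#' @param config a [window_config()].
#' @return A list with the framewise series (`imdf`, `imnf`), frame centre
#'   times `t` (s), and summaries `imdf_mean`, `imnf_mean`, `imdf_slope`,
#'   `imnf_slope` (Hz and Hz/s).
#' @export
instantaneous_frequencies <- function(window, fs, config = window_config()) {
  fl <- config$stft_window
  hop <- config$stft_hop
  n <- length(window)
  if (n < fl + 3L * hop) stop("window too short for 4 STFT frames", call. = FALSE)
  starts <- seq(1L, n - fl + 1L, by = hop)
  win <- hann_window(fl)
  freqs <- (seq_len(fl %/% 2 + 1L) - 1) * fs / fl
  mf <- md <- numeric(length(starts))
  for (j in seq_along(starts)) {
    P <- segment_psd(window[starts[j]:(starts[j] + fl - 1L)], fs, win)
    sp <- list(freqs = freqs, powers = P)
    mf[j] <- mean_frequency(sp)
    md[j] <- median_frequency(sp)
  }
  t <- (starts - 1 + fl / 2) / fs
  list(imdf = mf, imnf = md, t = t,
       imdf_mean = mean(mf), imnf_mean = mean(md),
       imdf_slope = unname(stats::coef(stats::lm(mf ~ t))[2]),
       imnf_slope = unname(stats::coef(stats::lm(md ~ t))[2]))
}

#' Sample entropy
#'
#' `SampEn = -ln(A/B)` where `B` counts template pairs of length `m` within
#' Chebyshev distance `r` and `A` the pairs still matching at length `m + 1`,
#' self-matches excluded. Counting is exact (all pairs).
#'
#' @param series numeric vector, length > m + 1.
#' @param m template length.
#' @param r matching tolerance (absolute units).
#' @return Sample entropy in nats. Throws an `undefined_entropy` error when
#'   either count is zero.
#' @export
sample_entropy <- function(series, m = 2, r = 0.2 * stats::sd(series)) {
  n <- length(series)
  stopifnot(n > m + 1)
  nt <- n - m
  idx <- seq_len(nt)
  D <- matrix(0, nt, nt)
  for (d in 0:(m - 1L)) {
    v <- series[idx + d]
    D <- pmax(D, abs(outer(v, v, "-")))
  }
  B <- (sum(D <= r) - nt) / 2
  v <- series[idx + m]
  D <- pmax(D, abs(outer(v, v, "-")))
  A <- (sum(D <= r) - nt) / 2
  if (B == 0 || A == 0) {
    stop(structure(class = c("undefined_entropy", "error", "condition"),
                   list(message = "no template matches within tolerance r",
                        call = NULL)))
  }
  -log(A / B)
}

## Anis-Lloyd expected rescaled range of an i.i.d. series of length n; used
## to de-bias the small-scale behaviour of the R/S estimator.
expected_rs <- function(n) {
  i <- seq_len(n - 1)
  s <- sum(sqrt((n - i) / i))
  if (n <= 340) {
    pre <- exp(lgamma((n - 1) / 2) - lgamma(n / 2)) / sqrt(pi)
  } else {
    pre <- 1 / sqrt(n * pi / 2)
  }
  (n - 0.5) / n * pre * s
}

#' Hurst exponent by rescaled-range analysis
#'
#' For log-spaced block sizes the rescaled range R/S is averaged over
#' non-overlapping blocks; the exponent is the least-squares slope of
#' log(R/S) against log(scale). With `corrected = TRUE` (default) the
#' Anis-Lloyd finite-sample expectation is subtracted first
#' (`H = 0.5 + slope of log(R/S) - log(E[R/S])`), removing the well-known
#' upward bias of the raw statistic at small scales.
#'
#' @param series numeric vector, length >= 256, non-constant.
#' @param config a [window_config()] (supplies the scale grid).
#' @param corrected apply the Anis-Lloyd small-sample correction.
#' @return Estimated Hurst exponent (dimensionless).
#' @export
hurst_exponent <- function(series, config = window_config(), corrected = TRUE) {
  n <- length(series)
  if (n < 256) stop("series too short for R/S analysis (need >= 256)", call. = FALSE)
  if (stats::sd(series) == 0) stop("constant series has no R/S scaling", call. = FALSE)
  scales <- unique(round(exp(seq(log(config$hurst_min_scale), log(n %/% 4),
                                 length.out = config$hurst_n_scales))))
  rs <- vapply(scales, function(s) {
    nb <- n %/% s
    vals <- vapply(seq_len(nb), function(b) {
      z <- series[((b - 1) * s + 1):(b * s)]
      z <- z - mean(z)
      S <- stats::sd(z)
      if (S == 0) return(NA_real_)
      y <- cumsum(z)
      (max(y) - min(y)) / S
    }, numeric(1))
    mean(vals, na.rm = TRUE)
  }, numeric(1))
  ok <- is.finite(rs) & rs > 0
  lx <- log(scales[ok])
  ly <- log(rs[ok])
  if (corrected) {
    ly <- ly - log(vapply(scales[ok], expected_rs, numeric(1)))
    0.5 + unname(stats::coef(stats::lm(ly ~ lx))[2])
  } else {
    unname(stats::coef(stats::lm(ly ~ lx))[2])
  }
}

#' Simulate fractional Gaussian noise (synthetic validation fixture)
#'
#' Exact circulant-embedding (Davies-Harte) synthesis of stationary fGn with
#' Hurst exponent `H` and unit variance; used to validate the Hurst
#' estimator's parameter recovery.
#'
#' @param n series length.
#' @param H Hurst exponent in (0, 1).
#' @param seed integer seed.
#' @return Numeric vector of length `n`.
#' @export
fgn_simulate <- function(n, H, seed = 1L) {
  stopifnot(H > 0, H < 1, n >= 2)
  old <- .Random.seed_store()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  acf_fgn <- function(k) 0.5 * ((abs(k) + 1)^(2 * H) - 2 * abs(k)^(2 * H) +
                                  abs(abs(k) - 1)^(2 * H))
  m <- 2L * n
  row <- acf_fgn(c(0:n, (n - 1):1))
  lambda <- Re(stats::fft(row))
  lambda[lambda < 0] <- 0             # guard tiny negative round-off
  W <- complex(length.out = m)
  W[1] <- sqrt(lambda[1] / m) * stats::rnorm(1)
  W[n + 1] <- sqrt(lambda[n + 1] / m) * stats::rnorm(1)
  a <- stats::rnorm(n - 1)
  b <- stats::rnorm(n - 1)
  W[2:n] <- sqrt(lambda[2:n] / (2 * m)) * complex(real = a, imaginary = b)
  W[m:(n + 2)] <- Conj(W[2:n])
  Re(stats::fft(W))[seq_len(n)]
}

## Enumerate analysis windows of a record and attach labels; a window gets a
## label only when it lies entirely inside one labelled region.
enumerate_windows <- function(n, label_windows, config) {
  wl <- config$window_len
  hop <- max(1L, as.integer(round(wl * (1 - config$overlap))))
  if (wl > n) stop("window longer than record", call. = FALSE)
  starts <- seq(1L, n - wl + 1L, by = hop)
  lab <- rep(NA_character_, length(starts))
  for (j in seq_len(nrow(label_windows))) {
    inside <- starts >= label_windows$start_sample[j] &
      (starts + wl - 1L) <= label_windows$end_sample[j]
    lab[inside] <- label_windows$label[j]
  }
  data.frame(window = seq_along(starts), start = starts,
             end = starts + wl - 1L, label = lab, stringsAsFactors = FALSE)
}

## All nine features (plus instantaneous-frequency slopes) of one window.
window_features <- function(w, fs, config) {
  td <- time_domain_features(w)
  sp <- power_spectrum(w, fs, config)
  inst <- instantaneous_frequencies(w, fs, config)
  se <- tryCatch(
    sample_entropy(w, config$sampen_m, config$sampen_r_factor * stats::sd(w)),
    undefined_entropy = function(e) NA_real_)
  h <- tryCatch(hurst_exponent(w, config), error = function(e) NA_real_)
  c(MAV = unname(td["MAV"]), VAR = unname(td["VAR"]), RMS = unname(td["RMS"]),
    MF = mean_frequency(sp), MPF = median_frequency(sp),
    IMDF_mean = inst$imdf_mean, IMNF_mean = inst$imnf_mean,
    IMDF_slope = inst$imdf_slope, IMNF_slope = inst$imnf_slope,
    SampEn = se, H = h)
}

#' Extract the windowed feature table
#'
#' One row per (record, labelled window, source component). Sources are the
#' raw conditioned signal plus, when decompositions are supplied, the first
#' `k_keep` IMFs of each record. Unlabelled (mid-trial) windows are skipped.
#'
#' @param records named list of `emg_record` objects (all with the same `fs`).
#' @param decomps optional named list of `imf_set` objects parallel to
#'   `records` (same names).
#' @param config a [window_config()].
#' @param k_keep how many leading IMFs to include as sources (0 = raw only).
#' @return A data frame of class `feature_table`: keys (`subject`, `trial`,
#'   `channel`, `window`, `source`), eleven feature columns and `label`.
#' @export
extract_feature_table <- function(records, decomps = NULL,
                                  config = window_config(), k_keep = 0) {
  fs <- unique(vapply(records, `[[`, numeric(1), "fs"))
  if (length(fs) != 1) stop("records have inconsistent sampling rates", call. = FALSE)
  rows <- list()
  for (nm in names(records)) {
    rec <- records[[nm]]
    wins <- enumerate_windows(length(rec$samples), rec$label_windows, config)
    wins <- wins[!is.na(wins$label), , drop = FALSE]
    sources <- list(raw = rec$samples)
    if (k_keep > 0) {
      if (is.null(decomps[[nm]]))
        stop("no decomposition supplied for record ", nm, call. = FALSE)
      ims <- decomps[[nm]]$imfs
      for (k in seq_len(min(k_keep, length(ims))))
        sources[[paste0("imf", k)]] <- ims[[k]]
    }
    for (src in names(sources)) {
      x <- sources[[src]]
      for (i in seq_len(nrow(wins))) {
        w <- x[wins$start[i]:wins$end[i]]
        feats <- window_features(w, fs, config)
        rows[[length(rows) + 1L]] <- data.frame(
          subject = rec$subject_id, trial = rec$trial_id,
          channel = rec$channel_id, window = wins$window[i], source = src,
          t(feats), label = wins$label[i],
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("feature_table", "data.frame")
  out
}

feature_columns <- function() {
  c("MAV", "VAR", "RMS", "MF", "MPF", "IMDF_mean", "IMNF_mean",
    "IMDF_slope", "IMNF_slope", "SampEn", "H")
}

#' Write / read a feature table as CSV with a validated header
#'
#' @param table a `feature_table`.
#' @param path CSV path.
#' @return `write_feature_table()` returns `path` invisibly;
#'   `read_feature_table()` the validated `feature_table`.
#' @export
write_feature_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject", "trial", "channel", "window", "source",
            feature_columns(), "label")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("feature table missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  class(df) <- c("feature_table", "data.frame")
  df
}

#' Pivot the feature table to one wide row per window
#'
#' Combines the `raw` source with the first `k` IMF sources into a single
#' feature vector per (subject, trial, channel, window), column names
#' `<source>_<feature>`.
#'
#' @param table a `feature_table`.
#' @param k number of IMF sources to include (0 = raw only).
#' @return A data frame with key columns, wide feature columns and `label`.
#' @export
feature_table_wide <- function(table, k = 0) {
  keep <- c("raw", if (k > 0) paste0("imf", seq_len(k)))
  tab <- table[table$source %in% keep, , drop = FALSE]
  key <- interaction(tab$subject, tab$trial, tab$channel, tab$window, drop = TRUE)
  first <- !duplicated(key)
  out <- tab[first, c("subject", "trial", "channel", "window", "label")]
  for (src in keep) {
    sub <- tab[tab$source == src, , drop = FALSE]
    skey <- interaction(sub$subject, sub$trial, sub$channel, sub$window, drop = TRUE)
    m <- match(key[first], skey)
    for (fc in feature_columns()) {
      out[[paste0(src, "_", fc)]] <- sub[[fc]][m]
    }
  }
  rownames(out) <- NULL
  out
}
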