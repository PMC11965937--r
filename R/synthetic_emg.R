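#' Configuration for the synthetic fatiguing-EMG generator
#'
#' Builds and validates the parameter set describing a simulated isometric
#' contraction study: a grid of subjects, trials and channels, each trial a
#' nonstationary surface-EMG-like signal whose spectral content compresses
#' toward lower frequencies and whose amplitude grows as fatigue accumulates.
#'
#' The generated signal is band-limited Gaussian noise passed through a
#' time-varying 4th-order Butterworth band-pass shaper whose centre frequency
#' tracks a linear median-frequency (MDF) trajectory from `mdf_start` to
#' `mdf_end`, multiplied by a linear amplitude gain from 1 to `rms_gain_end`.
#' Optional artifacts emulate mains interference (a 50 Hz tone), slow baseline
#' drift (a sub-hertz sinusoid) and broadband sensor noise. The clean shaped
#' signal is normalised to unit RMS at trial start, so all artifact amplitudes
#' are expressed relative to the initial physiological RMS.
#'
#' @param n_subjects number of subjects in the study grid.
#' @param n_trials trials per subject.
#' @param n_channels channels (electrode sites) per trial.
#' @param duration trial length in seconds.
#' @param fs sampling rate in Hz.
#' @param mdf_start,mdf_end target median frequency (Hz) at trial start/end.
#' @param rms_gain_end amplitude gain at trial end, as a multiple of the
#'   initial RMS (>= 1).
#' @param bandwidth width (Hz) of the band-pass shaping filter.
#' @param powerline_amp amplitude of the 50 Hz mains tone (units of initial RMS).
#' @param drift_freq frequency (Hz) of the baseline-drift sinusoid.
#' @param drift_amp amplitude of the baseline drift (units of initial RMS).
#' @param sensor_noise_sd standard deviation of additive white sensor noise.
#' @param label_fraction fraction of each trial, at either end, whose windows
#'   are labelled `"easy"` (start) and `"difficult"` (end); the middle is left
#'   unlabelled.
#' @param subject_jitter multiplicative between-subject variation (+/- fraction)
#'   applied to the MDF endpoints and terminal gain.
#' @param master_seed integer seed from which every per-record stream is
#'   derived deterministically.
#'
#' @return An object of class `synth_config` (a validated list).
#' @export
synth_config <- function(n_subjects = 10, n_trials = 10, n_channels = 3,
                         duration = 60, fs = 1000,
                         mdf_start = 90, mdf_end = 60,
                         rms_gain_end = 1.8, bandwidth = 60,
                         powerline_amp = 0.1, drift_freq = 0.3,
                         drift_amp = 0.5, sensor_noise_sd = 0.05,
                         label_fraction = 1 / 3, subject_jitter = 0.1,
                         master_seed = 20260101L) {
  cfg <- list(
    n_subjects = as.integer(n_subjects), n_trials = as.integer(n_trials),
    n_channels = as.integer(n_channels), duration = duration, fs = fs,
    mdf_start = mdf_start, mdf_end = mdf_end,
    rms_gain_end = rms_gain_end, bandwidth = bandwidth,
    powerline_amp = powerline_amp, drift_freq = drift_freq,
    drift_amp = drift_amp, sensor_noise_sd = sensor_noise_sd,
    label_fraction = label_fraction, subject_jitter = subject_jitter,
    master_seed = as.integer(master_seed)
  )
  validate_synth_config(cfg)
  class(cfg) <- "synth_config"
  cfg
}

validate_synth_config <- function(cfg) {
  stopifnot(
    cfg$n_subjects >= 1, cfg$n_trials >= 1, cfg$n_channels >= 1
  )
  if (!is.finite(cfg$duration) || cfg$duration <= 0)
    stop("invalid config: duration must be positive", call. = FALSE)
  if (!is.finite(cfg$fs) || cfg$fs <= 0)
    stop("invalid config: fs must be positive", call. = FALSE)
  if (cfg$mdf_end <= 0 || cfg$mdf_end > cfg$mdf_start)
    stop("invalid config: need 0 < mdf_end <= mdf_start", call. = FALSE)
  if (cfg$rms_gain_end < 1)
    stop("invalid config: rms_gain_end must be >= 1", call. = FALSE)
  if (cfg$fs <= 2 * (cfg$mdf_start + cfg$bandwidth))
    stop("invalid config: fs must exceed 2*(mdf_start + bandwidth) (Nyquist)",
         call. = FALSE)
  if (cfg$label_fraction <= 0 || cfg$label_fraction > 0.5)
    stop("invalid config: label_fraction must lie in (0, 0.5]", call. = FALSE)
  invisible(cfg)
}

#' Per-sample fatigue trajectory
#'
#' Linear interpolation of the target median frequency from `mdf_start` to
#' `mdf_end` and of the amplitude gain from 1 to `rms_gain_end` across the
#' trial. The linear shape is the simplest monotone fatigue model; downstream
#' tests only rely on the slope sign.
#'
#' @param config a [synth_config()].
#' @return A list with numeric vectors `target_mdf` (Hz) and `target_gain`
#'   (dimensionless), each of length `duration * fs`.
#' @export
make_fatigue_trajectory <- function(config) {
  validate_synth_config(config)
  n <- round(config$duration * config$fs)
  u <- if (n == 1) 0 else seq(0, 1, length.out = n)
  list(
    target_mdf = config$mdf_start + u * (config$mdf_end - config$mdf_start),
    target_gain = 1 + u * (config$rms_gain_end - 1)
  )
}

## Deterministic per-record seed derived from the master seed and grid keys.
## Kept below 2^31 so it is a valid R integer seed.
derive_seed <- function(master_seed, subject_id, trial_id, channel_id) {
  h <- (as.double(master_seed) %% 2147483647)
  for (k in c(subject_id, trial_id, channel_id)) {
    h <- (h * 48271 + as.double(k) * 1009 + 7919) %% 2147483647
  }
  as.integer(h)
}

## Per-subject multiplicative jitter on the fatigue parameters, drawn from the
## master seed only, so subjects differ but the grid stays reproducible.
subject_jitter_table <- function(config) {
  old <- .Random.seed_store()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(config$master_seed, 0L, 0L, 0L))
  j <- config$subject_jitter
  data.frame(
    subject_id = seq_len(config$n_subjects),
    mdf_start_mult = stats::runif(config$n_subjects, 1 - j, 1 + j),
    mdf_end_mult = stats::runif(config$n_subjects, 1 - j, 1 + j),
    gain_mult = stats::runif(config$n_subjects, 1 - j, 1 + j)
  )
}

.Random.seed_store <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

## Squared magnitude response of an ARMA filter on a frequency grid.
filter_response2 <- function(b, a, w) {
  E <- exp(-1i * outer(w, seq_along(a) - 1))
  bb <- as.vector(E[, seq_along(b), drop = FALSE] %*% b)
  aa <- as.vector(E %*% a)
  Mod(bb / aa)^2
}

## Design a 4th-order Butterworth band-pass whose *output* median frequency
## (for white-noise input) equals the target. The digital band-pass magnitude
## is not symmetric about its arithmetic centre, so the design centre is
## adjusted by a few fixed-point steps against the response's actual median.
## Also returns the theoretical output RMS for unit-variance white input.
design_shaper <- function(f0, bandwidth, fs, n_grid = 256L) {
  nyq <- fs / 2
  w <- pi * (seq_len(n_grid) - 0.5) / n_grid
  f <- w / pi * nyq
  centre <- f0
  bf <- NULL
  H2 <- NULL
  for (it in 1:5) {
    lo <- max(centre - bandwidth / 2, 1) / nyq
    hi <- min(centre + bandwidth / 2, nyq - 1) / nyq
    bf <- signal::butter(2, c(lo, hi), type = "pass")
    H2 <- filter_response2(bf$b, bf$a, w)
    cum <- cumsum(H2)
    med <- stats::approx(cum, f, xout = cum[n_grid] / 2)$y
    if (abs(med - f0) < 0.2) break
    centre <- centre + (f0 - med)
  }
  list(filt = bf, rms = sqrt(mean(H2)))
}

## Time-varying band-pass shaping of white Gaussian noise. The trial is
## processed in 50%-overlapping Hann-weighted blocks (constant overlap-add);
## each block is filtered with a shaper tuned so its output median frequency
## equals the local target MDF, and normalised by the shaper's theoretical
## output RMS so the base signal has unit RMS throughout.
shaped_noise <- function(n, fs, target_mdf, bandwidth, block_len = 256L) {
  w <- stats::rnorm(n)
  hop <- block_len %/% 2L
  ## pad so every sample is covered by two blocks
  pad <- block_len
  wp <- c(stats::rnorm(pad), w, stats::rnorm(pad))
  np <- length(wp)
  out <- numeric(np)
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(block_len) / block_len)  # periodic Hann
  starts <- seq(1L, np - block_len + 1L, by = hop)
  mdf_pad <- c(rep(target_mdf[1], pad), target_mdf, rep(target_mdf[n], pad))
  cache <- new.env(parent = emptyenv())
  for (s in starts) {
    idx <- s:(s + block_len - 1L)
    f0 <- round(mdf_pad[s + hop] * 2) / 2   # 0.5 Hz design granularity
    key <- sprintf("f%.1f", f0)
    sh <- cache[[key]]
    if (is.null(sh)) {
      sh <- design_shaper(f0, bandwidth, fs)
      cache[[key]] <- sh
    }
    out[idx] <- out[idx] + win * signal::filter(sh$filt, wp[idx]) / sh$rms
  }
  out[(pad + 1):(pad + n)]
}

#' Generate one synthetic fatiguing-EMG trial
#'
#' Produces a single channel-trial record: shaped noise with a drifting
#' spectrum and growing amplitude, plus optional powerline, baseline-drift and
#' sensor-noise artifacts. The random stream is derived deterministically from
#' the configuration's master seed and the (subject, trial, channel) keys, so
#' identical calls are bit-identical.
#'
#' @param config a [synth_config()].
#' @param subject_id,trial_id,channel_id integer keys of the record.
#' @param seed optional explicit integer seed; by default derived from
#'   `config$master_seed` and the keys.
#' @return An `emg_record`: a list with `samples`, `fs`, the keys, and
#'   `label_windows` (data frame of sample ranges labelled `"easy"` /
#'   `"difficult"`).
#' @export
generate_trial <- function(config, subject_id = 1L, trial_id = 1L,
                           channel_id = 1L, seed = NULL) {
  validate_synth_config(config)
  if (is.null(seed))
    seed <- derive_seed(config$master_seed, subject_id, trial_id, channel_id)
  old <- .Random.seed_store()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))

  traj <- make_fatigue_trajectory(config)
  n <- length(traj$target_mdf)
  t <- (seq_len(n) - 1) / config$fs

  base <- shaped_noise(n, config$fs, traj$target_mdf, config$bandwidth)
  ## normalise so the trial *starts* at unit RMS, then apply the gain ramp
  rms0 <- sqrt(mean(base[seq_len(min(n, round(2 * config$fs)))]^2))
  base <- base / rms0 * traj$target_gain

  phi <- stats::runif(1, 0, 2 * pi)
  phi_d <- stats::runif(1, 0, 2 * pi)
  samples <- base +
    config$powerline_amp * sin(2 * pi * 50 * t + phi) +
    config$drift_amp * sin(2 * pi * config$drift_freq * t + phi_d) +
    config$sensor_noise_sd * stats::rnorm(n)

  lf <- config$label_fraction
  n_lab <- floor(n * lf)
  label_windows <- data.frame(
    start_sample = c(1L, n - n_lab + 1L),
    end_sample = c(n_lab, n),
    label = c("easy", "difficult"),
    stringsAsFactors = FALSE
  )

  structure(list(
    samples = samples, fs = config$fs,
    subject_id = as.integer(subject_id), trial_id = as.integer(trial_id),
    channel_id = as.integer(channel_id),
    label_windows = label_windows
  ), class = "emg_record")
}

#' Generate the full synthetic study dataset
#'
#' Generates one [generate_trial()] record for every cell of the
#' subject x trial x channel grid, with per-subject multiplicative jitter on
#' the median-frequency endpoints and terminal gain so that subjects differ.
#' The default 10 x 10 x 3 grid mirrors a ten-subject, ten-trial,
#' three-channel quadriceps study (300 records).
#'
#' @param config a [synth_config()].
#' @return A list of `emg_record` objects, named `s<subject>_t<trial>_c<channel>`.
#' @export
generate_dataset <- function(config) {
  validate_synth_config(config)
  jit <- subject_jitter_table(config)
  records <- list()
  for (s in seq_len(config$n_subjects)) {
    scfg <- config
    scfg$mdf_start <- config$mdf_start * jit$mdf_start_mult[s]
    scfg$mdf_end <- min(config$mdf_end * jit$mdf_end_mult[s], scfg$mdf_start)
    scfg$rms_gain_end <- max(1, config$rms_gain_end * jit$gain_mult[s])
    for (tr in seq_len(config$n_trials)) {
      for (ch in seq_len(config$n_channels)) {
        rec <- generate_trial(scfg, s, tr, ch,
                              seed = derive_seed(config$master_seed, s, tr, ch))
        records[[sprintf("s%d_t%d_c%d", s, tr, ch)]] <- rec
      }
    }
  }
  records
}

#' Write / read EMG records as delimited text with JSON sidecars
#'
#' Each record is stored as a two-column CSV (`time_s`, `amplitude`) next to a
#' JSON sidecar holding the sampling rate, grid keys and label windows; a
#' manifest CSV indexes all records in the directory.
#'
#' @param records list of `emg_record` objects.
#' @param dir output directory (created if needed).
#' @return `write_records()` returns the manifest data frame invisibly;
#'   `read_records()` returns a named list of `emg_record` objects.
#' @export
write_records <- function(records, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(names(records), function(nm) {
    rec <- records[[nm]]
    csv <- file.path(dir, paste0(nm, ".csv"))
    side <- file.path(dir, paste0(nm, ".json"))
    t <- (seq_along(rec$samples) - 1) / rec$fs
    utils::write.csv(data.frame(time_s = t, amplitude = rec$samples),
                     csv, row.names = FALSE)
    jsonlite::write_json(list(
      fs = rec$fs, subject_id = rec$subject_id, trial_id = rec$trial_id,
      channel_id = rec$channel_id, label_windows = rec$label_windows
    ), side, auto_unbox = TRUE, digits = NA)
    data.frame(record = nm, csv = basename(csv), sidecar = basename(side),
               n_samples = length(rec$samples), stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' @rdname write_records
#' @export
read_records <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  recs <- lapply(seq_len(nrow(manifest)), function(i) {
    dat <- utils::read.csv(file.path(dir, manifest$csv[i]))
    meta <- jsonlite::read_json(file.path(dir, manifest$sidecar[i]),
                                simplifyVector = TRUE)
    lw <- as.data.frame(meta$label_windows, stringsAsFactors = FALSE)
    structure(list(
      samples = dat$amplitude, fs = meta$fs,
      subject_id = as.integer(meta$subject_id),
      trial_id = as.integer(meta$trial_id),
      channel_id = as.integer(meta$channel_id),
      label_windows = lw
    ), class = "emg_record")
  })
  names(recs) <- manifest$record
  recs
}
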