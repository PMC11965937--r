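## Shared fixtures and independent oracles. Everything is generated in code;
## the expensive reduced study (records + ICEEMDAN decomposition + feature
## table) is built once per test run and cached.

fixture_env <- new.env(parent = emptyenv())

## Reduced evaluation study: 3 subjects x 2 trials x 1 channel, 12 s trials,
## all artifacts at their defaults, preprocessed, decomposed by ICEEMDAN
## (ensemble 30, up to 8 modes), features from raw + 4 IMFs.
fixture_study <- function() {
  if (is.null(fixture_env$study)) {
    cfg <- synth_config(n_subjects = 3, n_trials = 2, n_channels = 1,
                        duration = 12, master_seed = 101L)
    recs <- lapply(generate_dataset(cfg), preprocess_record)
    dp <- decomp_params(variant = "ICEEMDAN", ensemble_size = 30,
                        max_imfs = 8, seed = 101L)
    decomps <- lapply(recs, function(r) decompose(r$samples, dp))
    tab <- extract_feature_table(recs, decomps, window_config(), k_keep = 4)
    fixture_env$study <- list(config = cfg, records = recs,
                              decomps = decomps, table = tab)
  }
  fixture_env$study
}

rms <- function(x) sqrt(mean(x^2))

rel_recon_err <- function(d, x) sqrt(sum((reconstruct(d) - x)^2) / sum(x^2))

## Brute-force sample-entropy oracle: explicit double loop over template
## pairs, independent of the vectorised implementation.
sampen_oracle <- function(x, m, r) {
  n <- length(x)
  nt <- n - m
  A <- B <- 0L
  for (i in seq_len(nt - 1)) {
    for (j in (i + 1):nt) {
      if (max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)])) <= r) {
        B <- B + 1L
        if (abs(x[i + m] - x[j + m]) <= r) A <- A + 1L
      }
    }
  }
  list(A = A, B = B, sampen = -log(A / B))
}

## Direct double-sum KL oracle.
kl_oracle <- function(P, Q) {
  s <- 0
  for (i in seq_len(nrow(P))) for (j in seq_len(ncol(P))) {
    if (P[i, j] > 0) s <- s + P[i, j] * log(P[i, j] / Q[i, j])
  }
  s
}

## Zero-crossing count (zeros snapped to the positive side).
n_zero_crossings <- function(x) {
  s <- sign(x)
  s[s == 0] <- 1
  sum(diff(s) != 0)
}

count_extrema <- function(x) {
  ex <- find_extrema(x)
  length(ex$maxima) + length(ex$minima)
}

## Windowed median-frequency series of a trial (2 s windows, 50% overlap).
windowed_mdf <- function(x, fs) {
  wc <- window_config(window_len = 2000, welch_segment = 1024,
                      welch_overlap = 512)
  starts <- seq(1, length(x) - 2000 + 1, by = 1000)
  vapply(starts, function(s)
    median_frequency(power_spectrum(x[s:(s + 1999)], fs, wc)), numeric(1))
}

## Mode-mixing stimulus: a 5 Hz tone with two intermittent 120 Hz bursts.
mode_mix_signal <- function(seed, n = 2000, fs = 1000) {
  set.seed(seed)
  t <- (seq_len(n) - 1) / fs
  tone <- sin(2 * pi * 5 * t)
  burst <- numeric(n)
  for (c0 in c(400, 1200)) {
    idx <- (c0 - 75):(c0 + 75)
    burst[idx] <- burst[idx] + exp(-((idx - c0)^2) / (2 * 30^2))
  }
  list(x = tone + 0.4 * burst * sin(2 * pi * 120 * t) + 0.05 * rnorm(n),
       tone = tone)
}

best_tone_corr <- function(d, tone) {
  max(vapply(d$imfs, function(im) abs(stats::cor(im, tone)), numeric(1)),
      na.rm = TRUE)
}

## Two 30-point Gaussian clusters separated by 10 sigma in 9-D, embedded to
## 3-D; returns the mean silhouette width of the true labels.
cluster_silhouette <- function(seed) {
  set.seed(seed)
  X <- rbind(matrix(stats::rnorm(30 * 9), 30, 9),
             matrix(stats::rnorm(30 * 9) + 10, 30, 9))
  emb <- tsne_embed(scale(X), dims = 3, perplexity = 10, n_iter = 500,
                    seed = seed)
  mean(cluster::silhouette(rep(1:2, each = 30), stats::dist(emb$Y))[, 3])
}
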