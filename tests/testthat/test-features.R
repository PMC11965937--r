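test_that("time-domain features match their formulas and scale correctly", {
  expect_equal(unname(time_domain_features(c(1, -2, 3))["MAV"]), 2)
  td <- time_domain_features(rep(3, 10))
  expect_equal(unname(td), c(3, 0, 3))
  set.seed(5)
  x <- stats::rnorm(200)
  a <- -2.5
  t1 <- time_domain_features(x)
  t2 <- time_domain_features(a * x)
  expect_equal(unname(t2["MAV"]), abs(a) * unname(t1["MAV"]))
  expect_equal(unname(t2["RMS"]), abs(a) * unname(t1["RMS"]))
  expect_equal(unname(t2["VAR"]), a^2 * unname(t1["VAR"]))
  expect_equal(unname(t1["MAV"]), mean(abs(x)))
  expect_equal(unname(t1["VAR"]), mean((x - mean(x))^2))
  expect_equal(unname(t1["RMS"]), sqrt(mean(x^2)))
  expect_error(time_domain_features(numeric(0)), "empty")
})

test_that("Welch spectrum concentrates tones and preserves power", {
  fs <- 1000
  wc <- window_config()
  df <- fs / wc$welch_segment
  t <- seq(0, 0.999, by = 1 / fs)
  f0 <- 125                       # an exact bin centre (32 * 3.90625)
  sp <- power_spectrum(sin(2 * pi * f0 * t), fs, wc)
  peak <- sp$freqs[which.max(sp$powers)]
  expect_lt(abs(peak - f0), df)
  near <- abs(sp$freqs - f0) <= 2 * df
  expect_gt(sum(sp$powers[near]) / sum(sp$powers), 0.99)

  zero <- power_spectrum(numeric(1000), fs, wc)
  expect_true(all(zero$powers == 0))

  ratios <- sapply(1:10, function(s) {
    set.seed(s)
    x <- stats::rnorm(1000)
    sp <- power_spectrum(x, fs, wc)
    sum(sp$powers) * df / stats::var(x)
  })
  expect_true(all(ratios > 0.9 & ratios < 1.1))
})

test_that("mean and median frequency agree with analytic spectra", {
  fs <- 1000
  wc <- window_config()
  df <- fs / wc$welch_segment
  t <- seq(0, 0.999, by = 1 / fs)
  sp <- power_spectrum(sin(2 * pi * 100 * t), fs, wc)
  expect_lt(abs(mean_frequency(sp) - 100), df)
  expect_lt(abs(median_frequency(sp) - 100), df)

  two <- power_spectrum(sin(2 * pi * 50 * t) + sin(2 * pi * 150 * t), fs, wc)
  expect_lt(abs(mean_frequency(two) - 100), df)

  flat <- list(freqs = seq(0, 200, by = 1), powers = rep(1, 201))
  expect_equal(mean_frequency(flat), 100)
  expect_lt(abs(median_frequency(flat) - 100), 1)

  ## returned median splits cumulative power at one half (within one bin mass)
  cum <- cumsum(two$powers) / sum(two$powers)
  fm <- median_frequency(two)
  i <- findInterval(fm, two$freqs)
  expect_gte(cum[i + 1], 0.5)
  expect_lte(cum[max(i - 1, 1)], 0.5 + max(two$powers) / sum(two$powers))

  expect_error(mean_frequency(list(freqs = 1:3, powers = c(0, 0, 0))), "power")
  expect_error(median_frequency(list(freqs = 1:3, powers = c(0, 0, 0))), "power")
})

test_that("instantaneous frequency series track stationary and chirped tones", {
  fs <- 1000
  wc <- window_config()
  df <- fs / wc$stft_window
  t1 <- seq(0, 0.999, by = 1 / fs)
  inst <- instantaneous_frequencies(sin(2 * pi * 125 * t1), fs, wc)
  expect_true(all(abs(inst$imdf - 125) < df))
  expect_true(all(abs(inst$imnf - 125) < df))
  expect_lt(abs(inst$imdf_slope), 1)
  expect_lt(abs(inst$imnf_slope), 1)

  ## 4 s linear chirp 50 -> 150 Hz: instantaneous frequency 50 + 25 t
  t4 <- seq(0, 4 - 1 / fs, by = 1 / fs)
  ch <- sin(2 * pi * (50 * t4 + 12.5 * t4^2))
  ic <- instantaneous_frequencies(ch, fs, wc)
  expect_true(all(diff(ic$imdf) > -df))   # rising trend
  expect_lt(abs(ic$imdf[1] - 50), 10)
  expect_lt(abs(ic$imdf[length(ic$imdf)] - 150), 10)
  expect_gt(ic$imdf_slope, 20)
  expect_error(instantaneous_frequencies(stats::rnorm(100), fs, wc), "frames")
})

test_that("sample entropy matches the brute-force counting oracle", {
  expect_equal(sample_entropy(rep(3, 50), 2, 0), 0)
  expect_equal(sample_entropy(rep(c(1, 2), 50), 2, 0.1), 0)
  set.seed(6)
  for (i in 1:3) {
    x <- stats::rnorm(150)
    r <- 0.25 * stats::sd(x)
    expect_equal(sample_entropy(x, 2, r), sampen_oracle(x, 2, r)$sampen)
  }
  expect_error(sample_entropy(stats::rnorm(100), 2, 1e-12),
               class = "undefined_entropy")
})

test_that("sample entropy of white noise sits at the known level", {
  se <- vapply(1:20, function(s) {
    set.seed(s)
    x <- stats::rnorm(1000)
    sample_entropy(x, 2, 0.2 * stats::sd(x))
  }, numeric(1))
  expect_lt(abs(mean(se) - 2.2), 0.3)
})

test_that("a sine is more regular than its random permutation", {
  t <- seq(0, 0.999, by = 1e-3)
  s <- sin(2 * pi * 10 * t)
  r <- 0.2 * stats::sd(s)
  se_sine <- sample_entropy(s, 2, r)
  for (seed in 1:20) {
    set.seed(seed)
    expect_gt(sample_entropy(sample(s), 2, r), se_sine)
  }
})

test_that("rescaled-range analysis recovers known Hurst exponents", {
  hw <- vapply(1:20, function(s) {
    set.seed(s)
    hurst_exponent(stats::rnorm(4096))
  }, numeric(1))
  expect_lt(abs(mean(hw) - 0.5), 0.1)

  h8 <- vapply(1:20, function(s)
    hurst_exponent(fgn_simulate(4096, 0.8, s)), numeric(1))
  expect_lt(abs(mean(h8) - 0.8), 0.1)

  expect_error(hurst_exponent(rep(1, 1000)), "constant")
  expect_error(hurst_exponent(stats::rnorm(100)), "short")
})

test_that("fractional Gaussian noise generator has the right marginals", {
  x <- fgn_simulate(8192, 0.8, 1)
  expect_lt(abs(stats::sd(x) - 1), 0.1)
  expect_lt(abs(mean(x)), 0.1)
  expect_identical(fgn_simulate(512, 0.7, 3), fgn_simulate(512, 0.7, 3))
})

test_that("feature table rows match a brute-force window enumeration", {
  cfg <- synth_config(n_subjects = 1, n_trials = 1, n_channels = 1,
                      duration = 12, master_seed = 77L)
  rec <- generate_trial(cfg, 1, 1, 1)
  wc <- window_config()
  tab <- extract_feature_table(list(s1_t1_c1 = rec), config = wc, k_keep = 0)

  ## independent enumerator: count 1000-sample windows (hop 500) fully inside
  ## either labelled third of the 12000-sample trial
  n <- length(rec$samples)
  starts <- seq(1, n - 1000 + 1, by = 500)
  lw <- rec$label_windows
  expected <- sum(vapply(starts, function(s) {
    any(s >= lw$start_sample & (s + 999) <= lw$end_sample)
  }, logical(1)))
  expect_identical(nrow(tab), expected)
  expect_true(all(is.finite(as.matrix(tab[, feature_columns()]))))
  expect_setequal(unique(tab$label), c("easy", "difficult"))
})

test_that("IMF sources multiply rows and pivot into one wide row per window", {
  study <- fixture_study()
  tab <- study$table
  key <- paste(tab$subject, tab$trial, tab$channel, tab$window)
  per_window <- table(key)
  expect_true(all(per_window == 5))    # raw + 4 IMFs

  wide <- feature_table_wide(tab, 4)
  expect_identical(nrow(wide), length(unique(key)))
  expect_true(all(paste0("imf4_", feature_columns()) %in% names(wide)))
  raw_rows <- tab[tab$source == "raw", ]
  m <- match(paste(wide$subject, wide$trial, wide$channel, wide$window),
             paste(raw_rows$subject, raw_rows$trial, raw_rows$channel,
                   raw_rows$window))
  expect_equal(wide$raw_MF, raw_rows$MF[m])

  path <- file.path(withr::local_tempdir(), "features.csv")
  write_feature_table(tab, path)
  back <- read_feature_table(path)
  expect_equal(nrow(back), nrow(tab))
  expect_equal(back$MF, tab$MF, tolerance = 1e-10)
})
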