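test_that("fatigue trajectory interpolates linearly between endpoints", {
  cfg <- synth_config(n_subjects = 1, n_trials = 1, n_channels = 1,
                      duration = 2, mdf_start = 90, mdf_end = 60)
  tr <- make_fatigue_trajectory(cfg)
  expect_length(tr$target_mdf, 2000)
  expect_equal(tr$target_mdf[1], 90)
  expect_equal(tr$target_mdf[2000], 60)
  expect_true(all(diff(tr$target_mdf) <= 0))
  expect_equal(tr$target_gain[1], 1)
  expect_equal(tr$target_gain[2000], cfg$rms_gain_end)

  flat <- synth_config(n_subjects = 1, n_trials = 1, n_channels = 1,
                       duration = 1, mdf_start = 80, mdf_end = 80)
  expect_true(all(make_fatigue_trajectory(flat)$target_mdf == 80))
})

test_that("invalid configurations are rejected", {
  expect_error(synth_config(duration = -1), "duration")
  expect_error(synth_config(fs = 0), "fs")
  expect_error(synth_config(mdf_start = 60, mdf_end = 90), "mdf_end")
  expect_error(synth_config(rms_gain_end = 0.5), "rms_gain_end")
  expect_error(synth_config(fs = 200, mdf_start = 90, bandwidth = 60),
               "Nyquist")
  expect_error(synth_config(label_fraction = 0.7), "label_fraction")
})

test_that("trial generation is bit-identical under the same seed and keys", {
  cfg <- synth_config(n_subjects = 1, n_trials = 1, n_channels = 1,
                      duration = 3)
  a <- generate_trial(cfg, 1, 1, 1)
  b <- generate_trial(cfg, 1, 1, 1)
  expect_identical(a$samples, b$samples)
  expect_false(identical(a$samples, generate_trial(cfg, 1, 2, 1)$samples))
})

test_that("generated trials track the target median frequency and RMS gain", {
  cfg <- synth_config(n_subjects = 1, n_trials = 10, n_channels = 1,
                      duration = 20, powerline_amp = 0, drift_amp = 0,
                      sensor_noise_sd = 0)
  wc <- window_config(window_len = 2000, welch_segment = 1024,
                      welch_overlap = 512)
  mdf_first <- vapply(1:10, function(tr) {
    r <- generate_trial(cfg, 1, tr, 1)
    median_frequency(power_spectrum(r$samples[1:2000], cfg$fs, wc))
  }, numeric(1))
  ## single-window estimates scatter around the 90 Hz target; their mean is on it
  expect_lt(abs(mean(mdf_first) - 90), 5)
  expect_true(all(abs(mdf_first - 90) < 15))

  cfg2 <- synth_config(n_subjects = 1, n_trials = 10, n_channels = 1,
                       duration = 20, rms_gain_end = 2, powerline_amp = 0,
                       drift_amp = 0, sensor_noise_sd = 0)
  ratio <- vapply(1:10, function(tr) {
    x <- generate_trial(cfg2, 1, tr, 1)$samples
    rms(x[18001:20000]) / rms(x[1:2000])
  }, numeric(1))
  expect_lt(abs(mean(ratio) - 2), 0.2)
})

test_that("dataset layout matches the subject x trial x channel grid", {
  cfg <- synth_config(n_subjects = 2, n_trials = 3, n_channels = 2,
                      duration = 1)
  recs <- generate_dataset(cfg)
  expect_length(recs, 12)
  got <- sort(names(recs))
  want <- sort(as.vector(outer(
    outer(sprintf("s%d", 1:2), sprintf("_t%d", 1:3), paste0),
    sprintf("_c%d", 1:2), paste0)))
  expect_identical(got, want)

  one <- generate_dataset(synth_config(n_subjects = 1, n_trials = 1,
                                       n_channels = 1, duration = 1))
  expect_length(one, 1)
})

test_that("label windows balance easy and difficult up to rounding", {
  cfg <- synth_config(n_subjects = 1, n_trials = 1, n_channels = 1,
                      duration = 5, label_fraction = 1 / 3)
  rec <- generate_trial(cfg, 1, 1, 1)
  lw <- rec$label_windows
  expect_setequal(lw$label, c("easy", "difficult"))
  n_easy <- lw$end_sample[1] - lw$start_sample[1] + 1
  n_diff <- lw$end_sample[2] - lw$start_sample[2] + 1
  expect_lte(abs(n_easy - n_diff), 1)
  expect_true(all(lw$start_sample >= 1 & lw$end_sample <= length(rec$samples)))
  expect_lt(lw$end_sample[1], lw$start_sample[2])  # non-overlapping
})

test_that("windowed median frequency falls and RMS rises within trials", {
  cfg <- synth_config(n_subjects = 1, n_trials = 10, n_channels = 1,
                      duration = 20, powerline_amp = 0, drift_amp = 0,
                      sensor_noise_sd = 0)
  ok_mdf <- ok_rms <- logical(10)
  for (tr in 1:10) {
    x <- generate_trial(cfg, 1, tr, 1)$samples
    mdf <- windowed_mdf(x, cfg$fs)
    idx <- seq_along(mdf)
    fit <- stats::lm(mdf ~ idx)
    p_one <- stats::pt(stats::coef(summary(fit))[2, 3],
                       df = fit$df.residual)       # P(slope < 0)
    ok_mdf[tr] <- p_one < 0.01
    starts <- seq(1, length(x) - 1999, by = 1000)
    rmsv <- vapply(starts, function(s) rms(x[s:(s + 1999)]), numeric(1))
    ok_rms[tr] <- stats::coef(stats::lm(rmsv ~ starts))[2] > 0
  }
  expect_gte(mean(ok_mdf), 0.95)
  expect_gte(mean(ok_rms), 0.95)
})

test_that("records survive a CSV + sidecar round trip", {
  cfg <- synth_config(n_subjects = 1, n_trials = 2, n_channels = 1,
                      duration = 1)
  recs <- generate_dataset(cfg)
  dir <- withr::local_tempdir()
  write_records(recs, dir)
  back <- read_records(dir)
  expect_identical(names(back), names(recs))
  expect_equal(back[[1]]$samples, recs[[1]]$samples, tolerance = 1e-12)
  expect_identical(back[[1]]$label_windows$label,
                   recs[[1]]$label_windows$label)
  expect_identical(back[[2]]$trial_id, recs[[2]]$trial_id)
})
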