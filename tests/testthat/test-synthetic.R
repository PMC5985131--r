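test_that("regular rhythm places beats at exact RR spacing", {
  sim <- synth_ecg(fs = 1000, duration_s = 30, hr_bpm = 60, jitter_pct = 0)
  expect_equal(length(sim$beats), 30)
  expect_true(all(diff(sim$beats$samples) == 1000))
  expect_equal(length(sim$signal), 30000)
  # R amplitude is 1 at the annotated samples
  expect_equal(unname(sim$signal[sim$beats$samples[5]]), 1, tolerance = 0.02)
})

test_that("generator is reproducible and detectable", {
  a <- synth_ecg(fs = 500, duration_s = 20, hr_bpm = 75, jitter_pct = 6,
                 seed = 51)
  b <- synth_ecg(fs = 500, duration_s = 20, hr_bpm = 75, jitter_pct = 6,
                 seed = 51)
  expect_identical(a$signal, b$signal)
  expect_identical(a$beats$samples, b$beats$samples)

  det <- detect_rpeaks(a$signal, fs = 500)
  offs <- vapply(det$samples, function(d) min(abs(a$beats$samples - d)),
                 numeric(1))
  expect_lt(max(offs) / 500, 0.020)

  expect_error(synth_ecg(fs = 1000, duration_s = 20, hr_bpm = 400), "too high")
})

test_that("abdominal mixture respects the physiological amplitude ratio", {
  rec <- synth_abdominal(synth_config(duration_s = 15, seed = 52))
  pk_m <- diff(range(rec$sources["maternal", ]))
  pk_f <- diff(range(rec$sources["fetal", ]))
  ratio <- abs(rec$mixing[, 1]) * pk_m / (abs(rec$mixing[, 2]) * pk_f)
  expect_true(all(ratio >= 2 & ratio <= 10))
  # strongest maternal channel vs strongest fetal channel: the configured 4
  expect_equal(max(abs(rec$mixing[, 1])) * pk_m /
                 (max(abs(rec$mixing[, 2])) * pk_f), 4, tolerance = 1e-10)

  expect_error(synth_config(amplitude_ratio = 1.5), "amplitude_ratio")
  expect_error(synth_config(duration_s = 5), "duration_s")
  expect_error(synth_config(baseline_freq_hz = 0.7), "baseline_freq")
})

test_that("clean limit is an exact linear mixture and records reproduce", {
  cfg <- synth_config(duration_s = 12, noise_std = 0, baseline_amp = 0,
                      seed = 53)
  rec <- synth_abdominal(cfg)
  expect_equal(rec$recording$data, rec$mixing %*% rec$sources,
               tolerance = 1e-12, ignore_attr = TRUE)

  rec2 <- synth_abdominal(cfg)
  expect_identical(rec$recording$data, rec2$recording$data)
  expect_identical(rec$mixing, rec2$mixing)
})

test_that("separation recovers the clean abdominal mixture", {
  cfg <- synth_config(duration_s = 20, noise_std = 0, baseline_amp = 0,
                      muscle_std = 0.05, n_channels = 3, seed = 54)
  rec <- synth_abdominal(cfg)
  fit <- fastica(rec$recording, n.comp = 3, seed = 54)
  expect_lt(amari_index(coef(fit), rec$mixing), 0.05)
})

test_that("maternal and fetal rhythms stay mostly asynchronous", {
  rec <- synth_abdominal(synth_config(duration_s = 60, seed = 55))
  fs <- rec$recording$fs
  half <- round(0.05 * fs)
  overlap <- vapply(rec$fetal_beats$samples, function(b)
    min(abs(rec$maternal_beats$samples - b)) < 2 * half, logical(1))
  expect_lt(mean(overlap), 0.30)
})

test_that("Laplace mixture fixture has the advertised structure", {
  mx <- synth_mixture(3, 4000, seed = 56)
  expect_equal(dim(mx$X), c(3, 4000))
  expect_equal(mx$X, mx$A %*% mx$S, tolerance = 1e-12)
  # unit variance, positive excess kurtosis sources
  expect_equal(apply(mx$S, 1, stats::var), rep(1, 3), tolerance = 0.1)
  kurt <- apply(mx$S, 1, function(s) mean(s^4) / mean(s^2)^2 - 3)
  expect_true(all(kurt > 1))

  noisy <- synth_mixture(3, 4000, noise_db = 40, seed = 56)
  expect_equal(mean((noisy$X - noisy$A %*% noisy$S)^2) / mean(noisy$X^2),
               1e-4, tolerance = 0.2)
})
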